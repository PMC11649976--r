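test_that("canonical template loads with the documented geometry", {
  t <- tpl()
  expect_s3_class(t, "cyp_template")
  expect_identical(t$name, "CYP2J2")
  expect_equal(t$width_gauge, 1.5)
  expect_equal(t$rear_depth - t$facial_depth, t$width_gauge)
  numbered <- grep("^[0-9]+$", t$vertices$label, value = TRUE)
  expect_length(numbered, 54L)
  expect_setequal(numbered, as.character(1:54))
  expect_identical(t$heme_access, "rear")
  expect_length(validate_template(t), 0L)
})

test_that("every ring is a closed 6-cycle with uniform edge length", {
  t <- tpl()
  for (rl in names(t$rings))
    expect_length(ring_vertices(t, rl), 6L)
  xy <- as.matrix(t$vertices[, c("x", "y")])
  rownames(xy) <- t$vertices$label
  el <- sqrt(rowSums((xy[t$edges[, 1], ] - xy[t$edges[, 2], ])^2))
  expect_true(all(abs(el - 1 / sqrt(3)) < 1e-9))
})

test_that("named regions sit where the model says they sit", {
  t <- tpl()
  # site of oxidation: contiguous positions 2-4 on the bottom row
  expect_setequal(t$site_of_oxidation, c("2", "3", "4"))
  site <- t$vertices[t$vertices$label %in% t$site_of_oxidation, ]
  expect_true(all(site$y == min(t$vertices$y)))
  expect_identical(site$label[which.max(site$x)], "4")
  expect_true("in_site_of_oxidation" %in% region_membership(t, "3"))
  # shelf: right boundary at position 10, the junction of rings A and E
  shelf <- t$vertices[t$vertices$label %in% t$shelf$edge, ]
  expect_identical(shelf$label[which.max(shelf$x)], "10")
  expect_true("on_shelf_edge" %in% region_membership(t, "10"))
  i10 <- match("10", t$vertices$label)
  expect_true(all(c("A", "E") %in% t$vertices$member_rings[[i10]]))
  # entrance anchors
  expect_true("entrance_anchor" %in% region_membership(t, "54'"))
  expect_true("entrance_anchor" %in% region_membership(t, "49'"))
  # left-end runs up to the left side of ring S
  iS <- match("54'", t$vertices$label)
  expect_true("S" %in% t$vertices$member_rings[[iS]])
  expect_true("on_left_end" %in% region_membership(t, "54'"))
})

test_that("trigger path avoids ring A and runs right to left", {
  t <- tpl()
  expect_false("A" %in% t$trigger$path)
  cx <- vapply(t$trigger$path, function(rl) {
    qr <- t$cells[[rl]]; qr[1] + qr[2] / 2
  }, numeric(1))
  expect_true(all(diff(cx) < 0))
  expect_equal(t$trigger$pillar, c(0.5, 0.5, 3))
})

test_that("lookups fail cleanly on unknown labels", {
  t <- tpl()
  expect_error(ring_vertices(t, "Z"), "unknown ring")
  expect_error(region_membership(t, "potato"), "unknown vertex")
})

test_that("validator reports broken invariants as data", {
  t <- tpl()
  bad <- t
  bad$trigger$path <- c("eB", "C", "B", "A")
  v <- validate_template(bad)
  expect_true(any(vapply(v, `[[`, "", "invariant") == "trigger_path"))

  bad2 <- t
  bad2$rear_depth <- 2.0
  v2 <- validate_template(bad2)
  expect_true(any(vapply(v2, `[[`, "", "invariant") == "width_gauge"))

  bad3 <- t
  bad3$rings$A <- bad3$rings$A[1:5]
  v3 <- validate_template(bad3)
  expect_true(any(vapply(v3, `[[`, "", "invariant") == "ring_6_cycle"))
})

test_that("malformed definition documents raise parse/reference errors", {
  t <- tpl()
  def <- yaml::read_yaml(cyp2j2_template_path())
  def$rings$A <- def$rings$A[1:5]
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(def, f)
  expect_error(load_template(f), "rings")

  def2 <- yaml::read_yaml(cyp2j2_template_path())
  def2$rings$A[1] <- "999"
  yaml::write_yaml(def2, f)
  expect_error(load_template(f), "unknown vertex")

  def3 <- yaml::read_yaml(cyp2j2_template_path())
  def3$width_gauge <- NULL
  yaml::write_yaml(def3, f)
  expect_error(load_template(f), "missing field")
})

test_that("serialize/load round trip is identical", {
  t <- tpl()
  f <- tempfile(fileext = ".yaml")
  serialize_template(t, f)
  t2 <- load_template(f)
  t2$definition_path <- t$definition_path
  expect_identical(t, t2)
})
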