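test_that("embedding counts match the closed-form expectations", {
  t <- tpl()
  tt <- trim_template(t, c("A", "B", "D", "E"))
  nv <- nrow(tt$vertices)
  ne <- nrow(tt$edges)
  cfg <- search_config(expand_depth = TRUE)

  single <- carbon_chain(1)
  expect_length(enumerate_embeddings(single, tt, cfg), nv * 3L)

  two <- carbon_chain(2)
  expect_length(enumerate_embeddings(two, tt, cfg), 2L * ne * 9L)
})

test_that("benzene embeds exactly on the hexagonal faces", {
  t <- tpl()
  tt <- trim_template(t, c("A", "B", "D", "E"))
  hexring <- load_ligand("C1CCCCC1", name = "hexring")
  cfg <- search_config(expand_depth = FALSE)
  e <- enumerate_embeddings(hexring, tt, cfg)
  vsets <- unique(vapply(e, function(a)
    paste(sort(a$vertex), collapse = ","), ""))
  faces <- vapply(tt$rings, function(vs) paste(sort(vs), collapse = ","), "")
  expect_setequal(vsets, unname(faces))
  # five-membered rings cannot map bond-to-edge on a honeycomb
  ring5 <- load_ligand("C1CCCC1", name = "ring5")
  expect_length(enumerate_embeddings(ring5, tt, cfg), 0L)
})

test_that("enumeration equals the brute-force oracle on toy graphs", {
  t <- tpl()
  tt <- trim_template(t, c("A", "B", "D", "E"))
  toys <- generate_toy_ligands(12, seed = 3)
  toys <- toys[vapply(toys, function(g) nrow(g$atoms) <= 6L, TRUE)]
  for (g in toys) {
    cfg <- search_config(expand_depth = nrow(g$atoms) <= 3L)
    e <- enumerate_embeddings(g, tt, cfg)
    o <- brute_force_oracle(g, tt, cfg)
    expect_setequal(vapply(e, assignment_signature, ""),
                    vapply(o, assignment_signature, ""))
  }
})

test_that("enumeration is deterministic and capped", {
  t <- tpl()
  tt <- trim_template(t, c("A", "B", "D", "E"))
  g <- carbon_chain(3)
  cfg <- search_config(expand_depth = FALSE)
  e1 <- enumerate_embeddings(g, tt, cfg)
  e2 <- enumerate_embeddings(g, tt, cfg)
  expect_identical(e1, e2)
  cap <- search_config(expand_depth = FALSE, max_placements = 5L)
  expect_length(enumerate_embeddings(g, tt, cap), 5L)
  expect_error(enumerate_embeddings(carbon_chain(11), tt,
                                    search_config(atom_cap = 10L)),
               "size error")
  expect_error(brute_force_oracle(carbon_chain(7), tt), "size error")
})

test_that("predict ranks placements and classifies small ligands", {
  t <- tpl()
  g <- carbon_chain(4)
  pr <- predict_ligand(g, t, search_config(expand_depth = FALSE))
  expect_s3_class(pr, "prediction")
  expect_gt(length(pr$ranked), 0L)
  expect_false(pr$heuristic)
  sc <- vapply(pr$ranked, function(x) x$verdict$score, numeric(1))
  expect_true(all(diff(sc) <= 0))
  # deterministic under a fixed config
  pr2 <- predict_ligand(g, t, search_config(expand_depth = FALSE))
  expect_identical(assignment_signature(pr$ranked[[1]]$placement$assignment),
                   assignment_signature(pr2$ranked[[1]]$placement$assignment))
})

test_that("drug-sized ligands fall back to the off-corner beam search", {
  t <- tpl()
  rec <- fixture("Chlorzoxazone")
  pr <- predict_ligand(rec$ligand, t)
  expect_true(pr$heuristic)
  expect_gt(length(pr$ranked), 0L)
  best <- pr$ranked[[1]]
  expect_true(best$verdict$category %in%
                c("GOOD_SUBSTRATE", "POOR_SUBSTRATE", "INHIBITOR"))
  expect_length(validate_template(t), 0L)  # template untouched by search
})

test_that("the strain gate rejects unflattenable conformers", {
  t <- tpl()
  g <- carbon_chain(4)
  # grossly distorted coordinates fail the gate
  g$coords2d <- matrix(c(0, 0, 0.1, 0.05, 3, 0, 0, 4), ncol = 2,
                       byrow = TRUE)
  pr <- predict_ligand(g, t, search_config(strain_threshold = 0.1,
                                           expand_depth = FALSE))
  expect_identical(pr$best_category, "NON_LIGAND")
  expect_length(pr$ranked, 0L)
})

test_that("score_placement is linear in the contact weights", {
  t <- tpl()
  g <- carbon_chain(2)
  w <- rule_config()$weights
  p1 <- atom_placement(g, t, data.frame(atom = 1:2, vertex = c("30", "25"),
                                        depth = "mid"))
  v1 <- evaluate_placement(p1, t)
  expect_equal(score_placement(p1, v1), 0)
  p2 <- atom_placement(g, t, data.frame(atom = 1:2, vertex = c("30", "25"),
                                        depth = c("rear", "mid")))
  v2 <- evaluate_placement(p2, t)
  expect_equal(score_placement(p2, v2) - score_placement(p1, v1),
               w[["rear"]])
})
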