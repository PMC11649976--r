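# helper: a quick placement of a toy chain at chosen vertices/depths
chain_placement <- function(t, vertices, depths, n = length(vertices),
                            g = carbon_chain(n)) {
  atom_placement(g, t, data.frame(atom = seq_along(vertices),
                                  vertex = vertices, depth = depths,
                                  stringsAsFactors = FALSE))
}

test_that("placement construction enforces the grid invariants", {
  t <- tpl()
  g <- carbon_chain(3)
  expect_error(atom_placement(g, t, data.frame(atom = 1, vertex = "zzz",
                                               depth = "mid")),
               "unknown vertex")
  expect_error(atom_placement(g, t, data.frame(atom = 1, vertex = "eE.5",
                                               depth = "mid")),
               "under the Shelf")
  expect_error(atom_placement(g, t, data.frame(atom = c(1, 1),
                                               vertex = c("2", "3"),
                                               depth = "mid")),
               "more than one vertex")
  expect_error(atom_placement(g, t, data.frame(atom = 1:2,
                                               vertex = c("2", "54'"),
                                               depth = "mid")),
               "Ring-size apart")
  expect_error(atom_placement(g, t, data.frame(atom = 1, vertex = "2",
                                               depth = "sideways")),
               "depth bucket")
  # bonded atoms on adjacent corners and off-corner within tolerance pass
  p <- chain_placement(t, c("2", "6", "1"), c("rear", "rear", "mid"))
  expect_s3_class(p, "atom_placement")
})

test_that("width rule flags atoms outside the slab", {
  t <- tpl()
  p <- chain_placement(t, c("2", "6"), c("rear", "mid"))
  expect_true(check_width(p, t)$passed)
  p_out <- chain_placement(t, c("2", "6"), c("rear", "out"))
  r <- check_width(p_out, t)
  expect_false(r$passed)
  expect_equal(r$evidence$atom, 2L)
  expect_identical(evaluate_placement(p_out, t)$category, "NON_LIGAND")
})

test_that("plural rear contact needs two non-lactone rear atoms", {
  t <- tpl()
  expect_true(check_plural_rear_contact(
    chain_placement(t, c("2", "6"), c("rear", "rear")), t)$passed)
  expect_false(check_plural_rear_contact(
    chain_placement(t, c("2", "6"), c("rear", "mid")), t)$passed)
  # lactone-tagged rear atoms do not count
  gbl <- load_ligand("O=C1CCCO1", name = "butyrolactone")
  p <- atom_placement(gbl, t, data.frame(atom = c(3L, 5L),
                                         vertex = c("2", "6"),
                                         depth = "rear"))
  expect_false(check_plural_rear_contact(p, t)$passed)
  expect_false(check_lactone(p, t)$passed)
})

test_that("ring B occupancy counts junction corners", {
  t <- tpl()
  # vertex 7 is the lower junction of rings A and B
  expect_true(check_ring_b(chain_placement(t, "7", "mid", g = carbon_chain(1)),
                           t)$passed)
  expect_false(check_ring_b(chain_placement(t, "2", "mid",
                                            g = carbon_chain(1)), t)$passed)
  empty <- atom_placement(carbon_chain(1), t,
                          data.frame(atom = integer(0),
                                     vertex = character(0),
                                     depth = character(0)))
  expect_false(check_ring_b(empty, t)$passed)
})

test_that("site rule requires an oxidizable atom between positions 2 and 4", {
  t <- tpl()
  p <- chain_placement(t, "3", "rear", g = carbon_chain(1))
  r <- check_site_occupancy(p, t)
  expect_true(r$passed)
  expect_equal(r$evidence$atom, 1L)
  # a fluorine at the site is not oxidizable
  fg <- load_ligand("FC", name = "fluoromethane")
  pf <- atom_placement(fg, t, data.frame(atom = 1L, vertex = "3",
                                         depth = "rear"))
  expect_false(check_site_occupancy(pf, t)$passed)
  # an oxidizable atom elsewhere does not fire the rule
  expect_false(check_site_occupancy(
    chain_placement(t, "20", "mid", g = carbon_chain(1)), t)$passed)
})

test_that("left-end, shelf and descent behave as border rules", {
  t <- tpl()
  p <- chain_placement(t, c("11'", "14"), c("mid", "rear"))
  expect_true(check_left_end(p, t)$passed)
  r <- check_shelf(p, t)
  expect_true(r$passed)
  expect_equal(r$evidence$atom, 1L)     # shelf contact as evidence
  expect_true(check_descent(p, t)$passed)
  p2 <- chain_placement(t, c("3", "7"), c("rear", "mid"))
  expect_false(check_left_end(p2, t)$passed)
  expect_true(check_shelf(p2, t)$passed)
  expect_equal(nrow(check_shelf(p2, t)$evidence), 0L)
})

test_that("lactone atoms may not be trigger-contacted", {
  t <- tpl()
  gbl <- load_ligand("O=C1CCCO1", name = "butyrolactone")
  # lactone carbon at ring B, mid depth: trigger never fastens on it
  p <- atom_placement(gbl, t, data.frame(atom = 3L, vertex = "3",
                                         depth = "mid"))
  ts <- simulate_trigger(p, t)
  expect_false(ts$fastened)
  expect_true(check_lactone(p, t, ts)$passed)
  # force a contaminated trigger state: the rule must reject it
  fake <- ts
  fake$contacted_atoms <- 3L
  expect_false(check_lactone(p, t, fake)$passed)
})

test_that("verdict invariants hold and rules are order-independent", {
  t <- tpl()
  rec <- fixture("Chlorzoxazone")
  p <- fixture_placement(rec, t)
  v <- evaluate_placement(p, t)
  expect_identical(v$category, "GOOD_SUBSTRATE")
  expect_gt(length(v$predicted_sites), 0L)
  for (id in c("R_RING_B", "R_SITE", "R_PLURAL_REAR", "R_WIDTH"))
    expect_true(v$rule_results[[id]]$passed, info = id)
  # each rule depends only on placement + template: recomputing any rule in
  # isolation reproduces the result embedded in the verdict
  expect_identical(check_ring_b(p, t), v$rule_results$R_RING_B)
  expect_identical(check_site_occupancy(p, t), v$rule_results$R_SITE)
  expect_identical(check_width(p, t), v$rule_results$R_WIDTH)
  expect_identical(check_left_end(p, t), v$rule_results$R_LEFT_END)
})

test_that("verdict monotonicity: rear contacts never demote, ring B loss demotes", {
  t <- tpl()
  rec <- fixture("Chlorzoxazone")
  p <- fixture_placement(rec, t)
  v <- evaluate_placement(p, t)
  expect_identical(v$category, "GOOD_SUBSTRATE")

  # add one more rear contact: still good, score increases by the rear weight
  a2 <- rbind(p$assignment[, c("atom", "vertex", "depth")],
              data.frame(atom = 3L, vertex = "7", depth = "rear"))
  p2 <- atom_placement(rec$ligand, t, a2)
  v2 <- evaluate_placement(p2, t)
  expect_identical(v2$category, "GOOD_SUBSTRATE")
  expect_gt(v2$score, v$score)

  # strip the ring-B atoms: good flips to poor
  keep <- !p$assignment$vertex %in% ring_vertices(t, "B")
  p3 <- atom_placement(rec$ligand, t,
                       p$assignment[keep, c("atom", "vertex", "depth")])
  v3 <- evaluate_placement(p3, t)
  expect_identical(v3$category, "POOR_SUBSTRATE")
  expect_true("R_RING_B" %in% v3$failed_rules)
})

test_that("score is the documented weighted contact count", {
  t <- tpl()
  cfg <- rule_config()
  g <- carbon_chain(1)
  p0 <- atom_placement(g, t, data.frame(atom = 1L, vertex = "23",
                                        depth = "mid"))
  v0 <- evaluate_placement(p0, t)
  expect_equal(v0$score, cfg$weights[["pillar"]])  # vertex 23 sits in ring J
  p1 <- atom_placement(g, t, data.frame(atom = 1L, vertex = "30",
                                        depth = "mid"))
  expect_equal(evaluate_placement(p1, t)$score, 0)
  p2 <- atom_placement(g, t, data.frame(atom = 1L, vertex = "30",
                                        depth = "rear"))
  expect_equal(evaluate_placement(p2, t)$score, cfg$weights[["rear"]])
})

test_that("evaluation demands a placement bound to the same template", {
  t <- tpl()
  p <- chain_placement(t, c("2", "6"), c("rear", "rear"))
  other <- t
  other$name <- "CYP0X0"
  expect_error(evaluate_placement(p, other), "state error")
  expect_error(check_width(p, other), "state error")
})
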