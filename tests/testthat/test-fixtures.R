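test_that("the fixture file loads with schema-level validation", {
  fx <- fixtures()
  expect_gt(length(fx), 30L)
  for (rec in fx) {
    expect_s3_class(rec, "fixture_record")
    expect_true(nzchar(rec$provenance), info = rec$name)
    expect_s3_class(rec$ligand, "ligand_graph")
    if (!is.null(rec$notation))
      expect_s3_class(rec$ring_path, "ring_path")
  }
})

test_that("fixture placements are admissible and strain-gated", {
  t <- tpl()
  cfg <- search_config()
  for (rec in fixtures()) {
    if (is.null(rec$assignment)) next
    p <- fixture_placement(rec, t)
    expect_s3_class(p, "atom_placement")
    expect_true(check_width(p, t)$passed, info = rec$name)
    expect_true(check_descent(p, t)$passed, info = rec$name)
    expect_lte(flatten_conformer(rec$ligand)$strain_proxy,
               cfg$strain_threshold)
  }
})

test_that("a small fixture-style placement is reachable by the enumeration", {
  # the partial drug fixtures are figure-resolution; completeness of the
  # search is instead exercised end-to-end on a fully-assigned toy: every
  # admissible sitting of a 3-chain must appear in the enumeration
  t <- tpl()
  tt <- trim_template(t, c("A", "B", "C", "E"))
  g <- carbon_chain(3)
  hand <- data.frame(atom = 1:3, vertex = c("2", "6", "1"), depth = "mid")
  cfg <- search_config(expand_depth = FALSE)
  sigs <- vapply(enumerate_embeddings(g, tt, cfg), assignment_signature, "")
  expect_true(assignment_signature(hand) %in% sigs)
})

test_that("the suite report accounts for every evaluated record", {
  t <- tpl()
  rep <- run_fixture_suite(t, fixtures())
  with_exp <- sum(vapply(fixtures(), function(r)
    !is.null(r$assignment) && !is.null(r$expected_category), TRUE))
  expect_equal(nrow(rep), with_exp)
  expect_true(all(rep$observed %in% c("GOOD_SUBSTRATE", "POOR_SUBSTRATE",
                                      "INHIBITOR", "NON_LIGAND")))
  expect_equal(sum(rep$concordant) + sum(!rep$concordant), nrow(rep))
})

test_that("toy ligand generation is deterministic and loadable", {
  a <- generate_toy_ligands(9, seed = 11)
  b <- generate_toy_ligands(9, seed = 11)
  expect_identical(a, b)
  expect_length(a, 9L)
  sizes <- vapply(a, function(g) nrow(g$atoms), 1L)
  expect_true(all(sizes >= 2L & sizes <= 8L))
  for (g in a) {
    expect_s3_class(tag_functional_groups(g), "ligand_graph")
    expect_true(all(vapply(g$annotations, function(ann)
      all(ann >= 1L & ann <= nrow(g$atoms)), TRUE)))
  }
  # the smallest family member is a 2-atom chain
  one <- generate_toy_ligands(1, seed = 0)
  expect_equal(nrow(one[[1]]$atoms), 2L)
  expect_equal(nrow(one[[1]]$bonds), 1L)
})

test_that("verdict and ligand reports serialize to JSON/TSV", {
  t <- tpl()
  rec <- fixture("Danazol")
  p <- fixture_placement(rec, t)
  v <- evaluate_placement(p, t)
  js <- write_verdict_json(v, ligand_name = rec$name)
  parsed <- jsonlite::fromJSON(js)
  expect_identical(parsed$category, "INHIBITOR")
  expect_identical(parsed$trigger$final_ring, v$trigger$final_ring)
  f <- tempfile(fileext = ".tsv")
  write_rule_matrix_tsv(v, f)
  tab <- utils::read.delim(f)
  expect_equal(nrow(tab), length(v$rule_results))
  gjson <- jsonlite::fromJSON(write_ligand_json(rec$ligand))
  expect_equal(nrow(gjson$atoms), nrow(rec$ligand$atoms))
})
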