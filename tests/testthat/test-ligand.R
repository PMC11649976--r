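test_that("SMILES load to hydrogen-free graphs in input atom order", {
  b <- load_ligand("c1ccccc1", name = "benzene")
  expect_equal(nrow(b$atoms), 6L)
  expect_equal(nrow(b$bonds), 6L)
  expect_true(all(b$atoms$aromatic))
  expect_true(all(b$atoms$in_ring))
  expect_length(unique(b$atoms$rigid_block), 1L)

  e <- load_ligand("CC", name = "ethane")
  expect_equal(nrow(e$atoms), 2L)
  expect_equal(nrow(e$bonds), 1L)
  expect_equal(e$atoms$implicit_h, c(3L, 3L))

  chz <- load_ligand("Clc1ccc2[nH]c(=O)oc2c1", name = "chlorzoxazone")
  expect_identical(chz$atoms$element[1], "Cl")
  expect_equal(sum(chz$atoms$in_ring), 9L)   # fused bicyclic system
  expect_length(unique(chz$atoms$rigid_block[chz$atoms$in_ring]), 1L)

  m <- load_ligand("C", name = "methane-analog")
  expect_equal(m$annotations$candidate_oxidation_site, 1L)
  expect_length(m$annotations$heme_ligating_heteroatom, 0L)
})

test_that("multi-fragment input is rejected", {
  expect_error(load_ligand("CC.CC"), "multi-fragment")
})

test_that("SDF files read back to the same graph as their SMILES", {
  sdf <- ChemmineR::smiles2sdf("CCO")
  f <- tempfile(fileext = ".sdf")
  ChemmineR::write.SDF(sdf, f)
  g1 <- load_ligand(f, name = "ethanol")
  g2 <- load_ligand("CCO", name = "ethanol")
  expect_identical(g1$atoms$element, g2$atoms$element)
  expect_identical(g1$bonds, g2$bonds)
})

test_that("functional-group tagging finds lactone-like rings", {
  thal <- load_ligand("O=C1CCC(N2C(=O)c3ccccc3C2=O)C(=O)N1",
                      name = "thalidomide")
  lact <- thal$annotations$lactone_ring_atom
  # both cyclic imide rings are tagged; the benzo ring carbons bearing H
  # are not
  expect_true(all(c(2L, 5L, 17L, 19L) %in% lact))     # glutarimide
  expect_true(all(c(6L, 7L, 15L) %in% lact))          # phthalimide core
  expect_false(any(c(10L, 11L, 12L, 13L) %in% lact))  # benzo CH
  # a true lactone ring
  gbl <- load_ligand("O=C1CCCO1", name = "butyrolactone")
  expect_setequal(gbl$annotations$lactone_ring_atom, 2:6)
  # benzene has none
  expect_length(load_ligand("c1ccccc1")$annotations$lactone_ring_atom, 0L)
})

test_that("heme-ligating and oxidizable atoms separate as documented", {
  dan <- load_ligand("CC#CC1(O)CCC2C3CCC4=Cc5oncc5CC4(C)C3CCC21C",
                     name = "danazol")
  heme <- dan$annotations$heme_ligating_heteroatom
  expect_length(heme, 1L)
  expect_identical(dan$atoms$element[heme], "N")     # isoxazole N only

  nor <- load_ligand("CCn1cc(C(=O)O)c(=O)c2cc(N3CCNCC3)c(F)cc21",
                     name = "norfloxacin")
  heme_n <- nor$annotations$heme_ligating_heteroatom
  expect_length(heme_n, 1L)
  expect_equal(nor$atoms$implicit_h[heme_n], 1L)     # terminal piperazine NH

  # thioether S is oxidizable, not heme-ligating
  thi <- load_ligand("CSc1ccccc1", name = "thioanisole")
  expect_true(2L %in% thi$annotations$candidate_oxidation_site)
  expect_false(2L %in% thi$annotations$heme_ligating_heteroatom)

  # tertiary amines are oxidizable (N-oxidation), secondary amines ligate
  t3 <- load_ligand("CN(C)C", name = "trimethylamine")
  expect_true(2L %in% t3$annotations$candidate_oxidation_site)
  t2 <- load_ligand("CNC", name = "dimethylamine")
  expect_true(2L %in% t2$annotations$heme_ligating_heteroatom)
  # amide N is neither
  am <- load_ligand("CC(=O)NC", name = "N-methylacetamide")
  expect_false(4L %in% am$annotations$heme_ligating_heteroatom)
  expect_false(4L %in% am$annotations$candidate_oxidation_site)
})

test_that("flattening is deterministic with a non-negative strain proxy", {
  b <- load_ligand("c1ccccc1")
  fc <- flatten_conformer(b)
  expect_lt(fc$strain_proxy, 1e-6)   # rigid planar hexagon
  fc2 <- flatten_conformer(b)
  expect_identical(fc$coords, fc2$coords)
  for (smi in c("CCO", "CC(=O)NC", "Clc1ccc2[nH]c(=O)oc2c1"))
    expect_gte(flatten_conformer(load_ligand(smi))$strain_proxy, 0)
})

test_that("3D coordinates are projected onto their best-fit plane", {
  g <- carbon_chain(4)
  coords3d <- cbind(x = c(0, 1, 2, 3), y = c(0, 1, 0, 1), z = rep(5, 4))
  fc <- flatten_conformer(g, coords3d = coords3d)
  expect_equal(dim(fc$coords), c(4L, 3L))
  expect_true(all(is.finite(fc$coords)))
})

test_that("annotations never reference out-of-range atoms", {
  for (rec in fixtures()) {
    n <- nrow(rec$ligand$atoms)
    for (ann in rec$ligand$annotations)
      if (length(ann)) expect_true(all(ann >= 1L & ann <= n),
                                   info = rec$name)
  }
})
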