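#' Load the packaged worked-placement fixtures
#'
#' The package ships a machine-readable transcription of the worked CYP2J2
#' ligand placements: the 24-reaction construction set plus the extended
#' group of ligands placed afterwards (inhibitors, slender and bent
#' ligands, endobiotics, the bi-molecule partners).  Each record carries
#' the ligand structure (SMILES transcription of the published 2D
#' drawing), the hyphen-linked placement notation, a provenance locator,
#' and -- where the figure could be read at atom resolution -- a partial
#' atom-to-vertex assignment with the expected category and expected
#' oxidation-site atoms.
#'
#' Every notation string is parsed and every SMILES is loaded at this
#' point, so a malformed fixture fails fast.
#'
#' @param path fixture YAML; defaults to the packaged file
#' @param template a `cyp_template` used to validate ring labels
#' @return list of `fixture_record` objects
#' @export
load_fixture_set <- function(path = cyp2j2_fixture_path(),
                             template = load_template()) {
  if (!file.exists(path)) stop("fixture file not found: ", path)
  raw <- yaml::read_yaml(path)
  stopifnot(is.list(raw$records))
  lapply(raw$records, function(r) {
    for (f in c("name", "group", "reaction", "smiles", "provenance"))
      if (is.null(r[[f]]) || !nzchar(r[[f]]))
        stop("fixture record missing field '", f, "' (",
             r$name %||% "?", ")")
    ringpath <- NULL
    if (!is.null(r$notation)) {
      ringpath <- parse_placement(r$notation)
      rings_occupied(ringpath, template)
    }
    g <- load_ligand(r$smiles, name = r$name)
    assignment <- NULL
    if (!is.null(r$assignment)) {
      parts <- strsplit(unlist(r$assignment), "\\s+")
      bad <- vapply(parts, length, 1L) != 4L
      if (any(bad))
        stop("fixture '", r$name, "': assignment entries must be ",
             "'atom element vertex depth'")
      assignment <- data.frame(
        atom = as.integer(vapply(parts, `[[`, "", 1L)),
        element = vapply(parts, `[[`, "", 2L),
        vertex = vapply(parts, `[[`, "", 3L),
        depth = vapply(parts, `[[`, "", 4L),
        stringsAsFactors = FALSE)
      el <- g$atoms$element[assignment$atom]
      if (!identical(el, assignment$element))
        stop("fixture '", r$name, "': assignment element mismatch at ",
             "atom(s) ", paste(assignment$atom[el != assignment$element],
                               collapse = ", "),
             " (expected ", paste(assignment$element[el != assignment$element],
                                  collapse = ","),
             ", structure has ", paste(el[el != assignment$element],
                                       collapse = ","), ")")
    }
    structure(list(name = r$name, group = r$group, reaction = r$reaction,
                   smiles = r$smiles, smiles_note = r$smiles_note,
                   notation = r$notation, ring_path = ringpath,
                   annotation = r$annotation,
                   expected_category = r$expected_category,
                   expected_sites = as.integer(unlist(r$expected_sites)),
                   expected_heme = as.integer(unlist(r$expected_heme)),
                   assignment = assignment,
                   provenance = r$provenance,
                   ligand = g),
              class = "fixture_record")
  })
}

#' Path of the packaged fixture file
#' @return file path (character scalar)
#' @export
cyp2j2_fixture_path <- function() {
  system.file("extdata", "cyp2j2_fixtures.yaml", package = "cyptemplate",
              mustWork = TRUE)
}

#' Build the atom placement of a fixture record
#'
#' @param rec a `fixture_record` with an atom-level assignment
#' @param t a `cyp_template`
#' @param tol adjacency tolerance passed to [atom_placement()]
#' @return an `atom_placement`
#' @export
fixture_placement <- function(rec, t, tol = 1.2) {
  stopifnot(inherits(rec, "fixture_record"))
  if (is.null(rec$assignment))
    stop("fixture '", rec$name, "' carries no atom-level assignment")
  atom_placement(rec$ligand, t,
                 rec$assignment[, c("atom", "vertex", "depth")], tol = tol)
}

#' Replay the fixture suite and report concordance
#'
#' Every record carrying an atom-level assignment and an expected category
#' is evaluated with the full rule engine; the report lists, per record,
#' the expected and observed category, the expected and predicted
#' oxidation-site atoms, and whether the record is concordant (category
#' match, plus a site match when sites were transcribed: at least one
#' expected site atom among the predictions, and for inhibitors the
#' expected heme-interacting atom among the placed heme contacts at the
#' site region).
#'
#' @param t a `cyp_template`
#' @param fixtures list of `fixture_record`s; defaults to the packaged set
#' @param config a [rule_config()]; pass an ablated config (e.g.
#'   `rule_config(disable = "ring_b")`) for negative-control runs
#' @return data frame, one row per evaluated record
#' @export
run_fixture_suite <- function(t, fixtures = load_fixture_set(template = t),
                              config = rule_config()) {
  rows <- list()
  for (rec in fixtures) {
    if (is.null(rec$assignment) || is.null(rec$expected_category)) next
    p <- fixture_placement(rec, t)
    ts <- simulate_trigger(p, t)
    v <- evaluate_placement(p, t, ts, config)
    cat_ok <- identical(v$category, rec$expected_category)
    site_ok <- TRUE
    if (length(rec$expected_sites) && rec$expected_category == "GOOD_SUBSTRATE")
      site_ok <- length(intersect(rec$expected_sites, v$predicted_sites)) > 0L
    heme_ok <- TRUE
    if (length(rec$expected_heme) && rec$expected_category == "INHIBITOR") {
      heme <- rec$ligand$annotations$heme_ligating_heteroatom
      at_site <- .atoms_with_feature(p, t, "in_site_of_oxidation")
      heme_ok <- all(rec$expected_heme %in% intersect(heme, at_site))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      name = rec$name, reaction = rec$reaction, group = rec$group,
      expected = rec$expected_category, observed = v$category,
      expected_sites = paste(rec$expected_sites, collapse = ","),
      predicted_sites = paste(v$predicted_sites, collapse = ","),
      trigger_ring = v$trigger$final_ring,
      fastened = v$trigger$fastened,
      score = v$score,
      concordant = cat_ok && site_ok && heme_ok,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows) %||%
    data.frame(name = character(0), concordant = logical(0))
}

#' Generate deterministic toy ligands for property tests
#'
#' A reproducible family of small heavy-atom graphs: simple chains (2--6
#' atoms), single rings (5--6 atoms) and a ring with a short tail, with
#' occasional heteroatom substitutions.  Useful as inputs for the
#' search-oracle equivalence and rule-invariance property tests.
#'
#' @param n number of graphs
#' @param seed RNG seed
#' @return list of `ligand_graph`s
#' @export
generate_toy_ligands <- function(n, seed = 0L) {
  stopifnot(n >= 1L)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    kind <- c("chain", "ring", "ring_tail")[1L + (i - 1L) %% 3L]
    if (kind == "chain") {
      m <- sample(2:6, 1L)
      bonds <- data.frame(a1 = seq_len(m - 1L), a2 = 2:m, order = 1L)
      in_ring <- rep(FALSE, m)
      rings <- list()
    } else if (kind == "ring") {
      m <- sample(5:6, 1L)
      bonds <- data.frame(a1 = seq_len(m), a2 = c(2:m, 1L), order = 1L)
      in_ring <- rep(TRUE, m)
      rings <- list(seq_len(m))
    } else {
      rs <- sample(5:6, 1L)
      tail_len <- sample(1:2, 1L)
      m <- rs + tail_len
      bonds <- rbind(
        data.frame(a1 = seq_len(rs), a2 = c(2:rs, 1L), order = 1L),
        data.frame(a1 = c(rs, if (tail_len > 1L) rs + 1L),
                   a2 = rs + seq_len(tail_len), order = 1L)[seq_len(tail_len), ])
      in_ring <- c(rep(TRUE, rs), rep(FALSE, tail_len))
      rings <- list(seq_len(rs))
    }
    elem <- rep("C", m)
    k <- sample(0:2, 1L)
    if (k > 0L) {
      pos <- sample(m, k)
      elem[pos] <- sample(c("N", "O", "S"), k, replace = TRUE)
    }
    atoms <- data.frame(element = elem, charge = 0L, aromatic = FALSE,
                        in_ring = in_ring,
                        rigid_block = ifelse(in_ring, 1L, 0L),
                        implicit_h = 0L, stringsAsFactors = FALSE)
    atoms$implicit_h <- .implicit_h(elem, atoms$charge, bonds, m)
    g <- ligand_graph(sprintf("toy-%03d-%s", i, kind), atoms, bonds)
    g$rings <- rings
    out[[i]] <- tag_functional_groups(g)
  }
  out
}
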