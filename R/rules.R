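#' Rule-engine configuration
#'
#' Collects the tunable parts of the placement rule engine: score weights
#' for the stabilizing contacts, the set of mandatory gates a good
#' substrate must pass, and rules disabled for ablation experiments.
#'
#' Mandatory gates default to the Width-gauge, simultaneous plural
#' Rear-wall contact, Ring B occupancy, Site-of-oxidation occupancy,
#' Trigger fastening and the lactone restriction; Left-end fixation and
#' the descent test are also mandatory by default but may be relaxed.
#' Facial-wall and Shelf contacts are stabilizing evidence only (they feed
#' the score), since good substrates without them are documented.
#'
#' Disabling `"ring_b"` removes both the Ring-B occupancy gate and the
#' Trigger-fastening gate: the two express one mechanism (the residue can
#' migrate only as far as Ring B, so fastening requires Ring-B sitting).
#'
#' @param weights named numeric: score weights per contact class
#' @param mandatory rule ids that gate the good-substrate verdict
#' @param relax rule ids to drop from `mandatory`
#' @param disable rule ids evaluated but ignored entirely (short names
#'   `"ring_b"` etc. or full ids `"R_RING_B"`)
#' @param good_bonus score added when every mandatory gate passes, so that
#'   good placements always outrank poor ones for the same ligand
#' @return a `rule_config` list
#' @export
rule_config <- function(weights = c(rear = 2, facial = 1, shelf = 1,
                                    left_end = 2, site = 3, pillar = 1),
                        mandatory = c("R_WIDTH", "R_PLURAL_REAR", "R_RING_B",
                                      "R_SITE", "R_TRIGGER", "R_LACTONE",
                                      "R_LEFT_END", "R_DESCENT"),
                        relax = character(0),
                        disable = character(0),
                        good_bonus = 100) {
  norm <- function(x) {
    x <- toupper(x)
    x <- ifelse(grepl("^R_", x), x, paste0("R_", x))
    x
  }
  disable <- norm(disable)
  if ("R_RING_B" %in% disable) disable <- union(disable, "R_TRIGGER")
  mandatory <- setdiff(norm(mandatory), c(norm(relax), disable))
  structure(list(weights = weights, mandatory = mandatory,
                 disable = disable, good_bonus = good_bonus),
            class = "rule_config")
}

.rule_result <- function(rule_id, passed, atoms = integer(0),
                         vertices = character(0), note = "") {
  structure(list(rule_id = rule_id, passed = passed,
                 evidence = data.frame(atom = atoms,
                                       vertex = as.character(vertices),
                                       stringsAsFactors = FALSE),
                 note = note),
            class = "rule_result")
}

.assigned_vertices <- function(p, atoms) {
  p$assignment$vertex[match(atoms, p$assignment$atom)]
}

#' Width-gauge rule
#'
#' Every atom of the flattened structure must be kept between the Facial-
#' and Rear-walls: each assigned atom carries one of the slab depth
#' buckets.  Atoms marked `"out"` (oversized sittings) fail the rule and
#' are reported as evidence.
#'
#' @param p an `atom_placement`
#' @param t the bound `cyp_template`
#' @return a `rule_result` with id `R_WIDTH`
#' @export
check_width <- function(p, t) {
  .check_bound(p, t)
  out <- p$assignment$atom[p$assignment$depth == "out"]
  .rule_result("R_WIDTH", length(out) == 0L, out,
               .assigned_vertices(p, out),
               if (length(out)) "atom(s) outside the Width-gauge slab"
               else "all atoms within Facial- and Rear-walls")
}

#' Simultaneous plural Rear-wall contact rule
#'
#' Ligand interaction starts with simultaneous contact of two or more
#' points with the Rear-wall.  Ionizable lactone-like ring atoms are not
#' allowed into Rear-wall contact and are excluded from the count.
#'
#' @inheritParams check_width
#' @return a `rule_result` with id `R_PLURAL_REAR`
#' @export
check_plural_rear_contact <- function(p, t) {
  .check_bound(p, t)
  lact <- p$ligand$annotations$lactone_ring_atom %||% integer(0)
  rear <- setdiff(p$assignment$atom[p$assignment$depth == "rear"], lact)
  .rule_result("R_PLURAL_REAR", length(rear) >= 2L, rear,
               .assigned_vertices(p, rear),
               paste0(length(rear), " non-lactone Rear-wall contact(s)"))
}

#' Ring B occupancy rule
#'
#' Ligands need to sit on Ring B to be metabolized: the Trigger-residue
#' migrates maximally to the Ring B region, so fastening requires
#' occupancy at Ring B (any of its vertices, junction corners included).
#'
#' @inheritParams check_width
#' @return a `rule_result` with id `R_RING_B`
#' @export
check_ring_b <- function(p, t) {
  .check_bound(p, t)
  atoms <- .atoms_in_ring(p, t, "B")
  .rule_result("R_RING_B", length(atoms) > 0L, atoms,
               .assigned_vertices(p, atoms),
               if (length(atoms)) "Ring B occupied" else "no Ring B occupancy")
}

#' Site-of-oxidation occupancy rule
#'
#' At least one candidate oxidation site (a C--H carbon, thioether S or
#' tertiary amine N) must occupy the confined bottom region between
#' Positions 2 and 4 where the heme-bound oxygen attacks.  The evidence
#' atoms become the predicted sites of oxidation.
#'
#' @inheritParams check_width
#' @return a `rule_result` with id `R_SITE`
#' @export
check_site_occupancy <- function(p, t) {
  .check_bound(p, t)
  cand <- p$ligand$annotations$candidate_oxidation_site %||% integer(0)
  at_site <- .atoms_with_feature(p, t, "in_site_of_oxidation")
  hit <- intersect(at_site, cand)
  .rule_result("R_SITE", length(hit) > 0L, hit, .assigned_vertices(p, hit),
               if (length(hit)) "oxidizable atom(s) at Site of oxidation"
               else "no oxidizable atom at Site of oxidation")
}

#' Left-end fixation rule
#'
#' Good CYP2J2 ligands are fixed with the Left-end: at least one atom must
#' sit on the left border polyline.
#'
#' @inheritParams check_width
#' @return a `rule_result` with id `R_LEFT_END`
#' @export
check_left_end <- function(p, t) {
  .check_bound(p, t)
  atoms <- .atoms_with_feature(p, t, "on_left_end")
  .rule_result("R_LEFT_END", length(atoms) > 0L, atoms,
               .assigned_vertices(p, atoms),
               if (length(atoms)) "Left-end contact" else "no Left-end contact")
}

#' Shelf rule
#'
#' No atom may sit in the closed space under the Shelf (this is also
#' enforced when the placement is constructed).  Atoms on the Shelf top
#' edge are recorded as stabilizing evidence; Shelf contact itself is not
#' mandatory.
#'
#' @inheritParams check_width
#' @return a `rule_result` with id `R_SHELF`
#' @export
check_shelf <- function(p, t) {
  .check_bound(p, t)
  mi <- match(p$assignment$vertex, t$vertices$label)
  under <- p$assignment$atom[vapply(t$vertices$features[mi], function(f)
    "under_shelf" %in% f, logical(1))]
  on_edge <- .atoms_with_feature(p, t, "on_shelf_edge")
  if (length(under))
    .rule_result("R_SHELF", FALSE, under, .assigned_vertices(p, under),
                 "atom(s) under the Shelf")
  else
    .rule_result("R_SHELF", TRUE, on_edge, .assigned_vertices(p, on_edge),
                 paste0(length(on_edge), " Shelf contact(s) (stabilizing)"))
}

#' Lactone restriction rule
#'
#' Ionizable lactone-like ring atoms (cyclic esters and cyclic imides) are
#' not allowed into contact with the Rear-wall or with the Trigger-residue.
#'
#' @inheritParams check_width
#' @param trigger_state optionally, the `trigger_state` of the placement,
#'   to verify no lactone atom was trigger-contacted
#' @return a `rule_result` with id `R_LACTONE`
#' @export
check_lactone <- function(p, t, trigger_state = NULL) {
  .check_bound(p, t)
  lact <- p$ligand$annotations$lactone_ring_atom %||% integer(0)
  bad <- intersect(p$assignment$atom[p$assignment$depth == "rear"], lact)
  if (!is.null(trigger_state))
    bad <- union(bad, intersect(trigger_state$contacted_atoms, lact))
  .rule_result("R_LACTONE", length(bad) == 0L, bad,
               .assigned_vertices(p, bad),
               if (length(bad)) "lactone-like atom(s) at Rear-wall/Trigger"
               else "lactone restriction satisfied")
}

#' Descent rule
#'
#' Ligands migrate from the Entrance down to the Site of oxidation without
#' changing conformation.  Under a straight vertical translation the only
#' obstructions on the way are the static half-plane barriers (the closed
#' space under the Shelf and the region beyond the Left-end), so the test
#' reduces to checking that the placement respects those barriers; a
#' conformation thicker than the slab is caught by the width rule instead.
#'
#' @inheritParams check_width
#' @return a `rule_result` with id `R_DESCENT`
#' @export
check_descent <- function(p, t) {
  .check_bound(p, t)
  mi <- match(p$assignment$vertex, t$vertices$label)
  under <- p$assignment$atom[vapply(t$vertices$features[mi], function(f)
    "under_shelf" %in% f, logical(1))]
  .rule_result("R_DESCENT", length(under) == 0L, under,
               .assigned_vertices(p, under),
               if (length(under)) "descent blocked by the Shelf"
               else "vertical descent from Entrance unobstructed")
}

.check_bound <- function(p, t) {
  if (!inherits(p, "atom_placement"))
    stop("state error: not an atom_placement")
  if (!inherits(t, "cyp_template"))
    stop("state error: placement not bound to a template")
  if (!identical(p$template_name, t$name))
    stop("state error: placement bound to template '", p$template_name,
         "', not '", t$name, "'")
  invisible(TRUE)
}

#' Evaluate a placement against all CYP2J2 interaction rules
#'
#' Runs every rule, classifies the placement and reports the per-rule
#' evidence.  Categories:
#'
#' * `GOOD_SUBSTRATE` -- every mandatory gate passes and at least one
#'   oxidizable atom sits at the Site of oxidation (those atoms are the
#'   predicted sites).
#' * `INHIBITOR` -- a heme-ligating heteroatom occupies the
#'   Site-of-oxidation region and no other oxidizable atom shares it, so
#'   the heteroatom coordinates the heme iron instead of being oxidized.
#'   This takes precedence over the substrate verdict.
#' * `POOR_SUBSTRATE` -- the placement is admissible but a mandatory gate
#'   fails (e.g. no Ring B occupancy, so the Trigger-residue cannot fasten
#'   the molecule).
#' * `NON_LIGAND` -- the structure cannot be kept within the Width-gauge.
#'
#' The score is the weighted contact count (Rear-wall, Facial-wall, Shelf,
#' Left-end, Site occupancies and pillar support) plus a fixed bonus when
#' all mandatory gates pass.
#'
#' @param p an `atom_placement`
#' @param t the bound `cyp_template`
#' @param trigger_state a `trigger_state` from [simulate_trigger()];
#'   computed on the fly when omitted
#' @param config a [rule_config()]
#' @return a `verdict`: list with `category`, `rule_results`,
#'   `predicted_sites`, `score`, `trigger`
#' @export
evaluate_placement <- function(p, t, trigger_state = NULL,
                               config = rule_config()) {
  .check_bound(p, t)
  if (is.null(trigger_state)) trigger_state <- simulate_trigger(p, t)

  rr <- list(
    R_WIDTH = check_width(p, t),
    R_PLURAL_REAR = check_plural_rear_contact(p, t),
    R_RING_B = check_ring_b(p, t),
    R_SITE = check_site_occupancy(p, t),
    R_LEFT_END = check_left_end(p, t),
    R_SHELF = check_shelf(p, t),
    R_LACTONE = check_lactone(p, t, trigger_state),
    R_DESCENT = check_descent(p, t),
    R_TRIGGER = .rule_result("R_TRIGGER", trigger_state$fastened,
                             trigger_state$contacted_atoms,
                             .assigned_vertices(p, trigger_state$contacted_atoms),
                             paste0("trigger residue ",
                                    if (trigger_state$fastened) "fastened at ring "
                                    else "not fastened; reached ring ",
                                    trigger_state$final_ring))
  )

  gates <- setdiff(config$mandatory, config$disable)
  gates_pass <- all(vapply(gates, function(id) rr[[id]]$passed, logical(1)))

  heme <- p$ligand$annotations$heme_ligating_heteroatom %||% integer(0)
  cand <- p$ligand$annotations$candidate_oxidation_site %||% integer(0)
  at_site <- .atoms_with_feature(p, t, "in_site_of_oxidation")
  heme_at_site <- intersect(at_site, heme)
  other_ox_at_site <- setdiff(intersect(at_site, cand), heme)

  category <-
    if (!rr$R_WIDTH$passed) "NON_LIGAND"
    else if (length(heme_at_site) && !length(other_ox_at_site)) "INHIBITOR"
    else if (gates_pass && rr$R_SITE$passed) "GOOD_SUBSTRATE"
    else "POOR_SUBSTRATE"

  predicted <- if (category == "GOOD_SUBSTRATE") rr$R_SITE$evidence$atom
               else integer(0)

  w <- config$weights
  lact <- p$ligand$annotations$lactone_ring_atom %||% integer(0)
  n_rear <- length(setdiff(p$assignment$atom[p$assignment$depth == "rear"],
                           lact))
  n_facial <- sum(p$assignment$depth == "facial")
  score <- n_rear * w[["rear"]] +
    n_facial * w[["facial"]] +
    nrow(rr$R_SHELF$evidence) * w[["shelf"]] *
      as.numeric(rr$R_SHELF$passed) +
    nrow(rr$R_LEFT_END$evidence) * w[["left_end"]] +
    nrow(rr$R_SITE$evidence) * w[["site"]] +
    as.numeric(trigger_state$pillar_support) * w[["pillar"]] +
    if (category == "GOOD_SUBSTRATE") config$good_bonus else 0

  structure(list(category = category, rule_results = rr,
                 predicted_sites = sort(unique(predicted)),
                 score = unname(score), trigger = trigger_state,
                 failed_rules = names(rr)[!vapply(rr, `[[`, TRUE, "passed")]),
            class = "verdict")
}

#' @export
print.verdict <- function(x, ...) {
  cat("<verdict> ", x$category, " (score ", signif(x$score, 4), ")\n",
      sep = "")
  for (r in x$rule_results)
    cat("  ", formatC(r$rule_id, width = -14),
        if (r$passed) "pass " else "FAIL ", r$note, "\n", sep = "")
  if (length(x$predicted_sites))
    cat("  predicted oxidation site atom(s): ",
        paste(x$predicted_sites, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Tabulate a verdict's rule matrix
#'
#' @param v a `verdict`
#' @return data frame with one row per rule: `rule`, `passed`, `n_evidence`,
#'   `note`
#' @export
verdict_table <- function(v) {
  stopifnot(inherits(v, "verdict"))
  data.frame(rule = vapply(v$rule_results, `[[`, "", "rule_id"),
             passed = vapply(v$rule_results, `[[`, TRUE, "passed"),
             n_evidence = vapply(v$rule_results, function(r)
               nrow(r$evidence), 1L),
             note = vapply(v$rule_results, `[[`, "", "note"),
             row.names = NULL, stringsAsFactors = FALSE)
}
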