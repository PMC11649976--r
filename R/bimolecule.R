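#' Evaluate a bi-molecule (pro-metabolized + trigger molecule) co-placement
#'
#' A few CYP2J2 phenomena are explained by two non-identical ligands bound
#' at once: the pro-metabolized molecule sits at the Site of oxidation and
#' is metabolized; the trigger molecule is not oxidized but modulates the
#' reaction.  The two need a slight overlap on the 2D Template while the
#' trigger molecule is situated behind (at a different depth bucket at
#' every shared vertex); a trigger molecule reaching into the
#' Site-of-oxidation region always invalidates the complex.
#'
#' Effects:
#' * `STABILIZING` -- the complex is valid and the overlap sits in (or
#'   adjacent to) the stabilizing region near the pro ligand's Left-end /
#'   upper-part contacts, so the trigger molecule holds the pro molecule
#'   and enhances its sitting stability.
#' * `COMPETING` -- the complex is not valid, but the trigger molecule's
#'   2D footprint intersects an alternative placement of the pro ligand
#'   (supplied via `alternatives`), so the trigger molecule competes with
#'   that sitting and reduces the corresponding reaction.
#' * `NONE` -- disjoint footprints with no competing alternative.
#'
#' @param pro `atom_placement` of the pro-metabolized molecule
#' @param trig `atom_placement` of the trigger molecule
#' @param t the bound `cyp_template`
#' @param alternatives list of alternative `atom_placement`s of the pro
#'   ligand (other good sittings whose footprint the trigger molecule
#'   might block)
#' @param stabilizing_rings ring labels defining the stabilizing overlap
#'   region (left border and upper support region by default)
#' @return a `bimolecule_result`: list with `valid`, `overlap_points`,
#'   `effect`, `notes`
#' @export
evaluate_bimolecule <- function(pro, trig, t, alternatives = list(),
                                stabilizing_rings = c("eL", "L", "M", "eR",
                                                      "R", "S", "K", "J",
                                                      "O")) {
  .check_bound(pro, t); .check_bound(trig, t)
  if (identical(pro$ligand$name, trig$ligand$name))
    stop("usage error: pro-metabolized and trigger molecule must be ",
         "distinct ligands")

  pv <- pro$assignment$vertex
  tv <- trig$assignment$vertex
  overlap <- intersect(pv, tv)

  trig_site <- .atoms_with_feature(trig, t, "in_site_of_oxidation")
  depth_sep <- length(overlap) > 0L &&
    all(vapply(overlap, function(v) {
      dp <- pro$assignment$depth[pro$assignment$vertex == v]
      dt <- trig$assignment$depth[trig$assignment$vertex == v]
      !any(dp %in% dt)
    }, logical(1)))

  valid <- length(overlap) > 0L && depth_sep && !length(trig_site)

  notes <- character(0)
  if (length(trig_site))
    notes <- c(notes, "trigger molecule occupies the Site of oxidation")
  if (length(overlap) && !depth_sep)
    notes <- c(notes, "no depth separation at shared vertices")

  effect <- "NONE"
  if (valid) {
    vt <- t$vertices
    in_stab <- vapply(overlap, function(v) {
      i <- match(v, vt$label)
      length(intersect(vt$member_rings[[i]], stabilizing_rings)) > 0L ||
        "on_left_end" %in% vt$features[[i]]
    }, logical(1))
    if (any(in_stab)) {
      effect <- "STABILIZING"
      notes <- c(notes, "overlap holds the pro-metabolized molecule near ",
                 "its Left-end/upper-part contacts")
    }
  } else if (length(alternatives)) {
    for (alt in alternatives) {
      .check_bound(alt, t)
      if (length(intersect(tv, alt$assignment$vertex))) {
        effect <- "COMPETING"
        notes <- c(notes,
                   "trigger molecule footprint blocks an alternative ",
                   "placement of the pro-metabolized ligand")
        break
      }
    }
  }

  structure(list(valid = valid, overlap_points = sort(overlap),
                 effect = effect, notes = paste(notes, collapse = "")),
            class = "bimolecule_result")
}

#' @export
print.bimolecule_result <- function(x, ...) {
  cat("<bimolecule_result> ", if (x$valid) "valid" else "invalid",
      " complex; effect: ", x$effect,
      if (length(x$overlap_points))
        paste0("; overlap at ", paste(x$overlap_points, collapse = " "))
      else "", "\n", sep = "")
  if (nzchar(x$notes)) cat("  ", x$notes, "\n", sep = "")
  invisible(x)
}
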