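#' Simulate the Trigger-residue
#'
#' The Trigger-residue is a modelled mobile element that sits behind the
#' Rear-wall near the eB region, appears inside the Width-gauge once a
#' ligand has descended, and migrates leftward along a rear-side path of
#' Rings -- maximally to Ring B, never entering Ring A.  It halts at the
#' first (rightmost) path Ring where a non-lactone ligand atom is sitting;
#' that contact fastens the ligand for catalysis.  Ionizable lactone-like
#' ring atoms are transparent to the residue (they are not allowed into
#' Trigger contact) and cannot fasten.
#'
#' @param p an `atom_placement`
#' @param t the bound `cyp_template`
#' @return a `trigger_state`: list with `final_ring`, `contacted_atoms`,
#'   `fastened`, `pillar_support`, `path_taken`
#' @export
simulate_trigger <- function(p, t) {
  stopifnot(inherits(p, "atom_placement"), inherits(t, "cyp_template"))
  path <- t$trigger$path
  lact <- p$ligand$annotations$lactone_ring_atom %||% integer(0)
  taken <- character(0)
  final <- path[length(path)]
  contacted <- integer(0)
  fastened <- FALSE
  for (ring in path) {
    taken <- c(taken, ring)
    hit <- setdiff(.atoms_in_ring(p, t, ring), lact)
    if (length(hit)) {
      final <- ring
      contacted <- hit
      fastened <- TRUE
      break
    }
  }
  structure(list(final_ring = final,
                 contacted_atoms = sort(contacted),
                 fastened = fastened,
                 pillar_support = pillar_support(p, t),
                 path_taken = taken),
            class = "trigger_state")
}

#' Pillar support of a bent ligand's upper part
#'
#' Long CYP2J2 ligands turn right after the Left-end contact; their bent
#' upper parts sit just above the Position the Trigger-residue approaches.
#' The residue is modelled as a pillar of 0.5 x 0.5 x 3 Ring-size
#' (horizontal, vertical, height diameters) that props such upper parts.
#' Support holds when at least one ligand atom occupies the designated
#' support region (Rings K/J, optionally O, per the template definition).
#'
#' @param p an `atom_placement`
#' @param t the bound `cyp_template`
#' @return `TRUE` iff an atom occupies the support region
#' @export
pillar_support <- function(p, t) {
  stopifnot(inherits(p, "atom_placement"), inherits(t, "cyp_template"))
  any(vapply(t$trigger$support_rings, function(rl)
    length(.atoms_in_ring(p, t, rl)) > 0L, logical(1)))
}

#' @export
print.trigger_state <- function(x, ...) {
  cat("<trigger_state> ", if (x$fastened) "fastened" else "not fastened",
      " at ring ", x$final_ring,
      if (length(x$contacted_atoms))
        paste0(" (atoms ", paste(x$contacted_atoms, collapse = " "), ")")
      else "",
      "; pillar support: ", x$pillar_support, "\n", sep = "")
  invisible(x)
}
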