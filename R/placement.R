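#' Bind a ligand placement to the Template
#'
#' An atom placement maps ligand heavy atoms to Template vertices plus a
#' depth bucket within the Width-gauge slab.  The assignment may be
#' partial: atoms drawn off-corner in a figure-resolution transcription
#' are simply left unassigned and do not enter the rule evaluation.
#'
#' Depth buckets discretise the slab between the walls: `"facial"`
#' (Facial-wall contact), `"mid"`, `"rear"` (Rear-wall contact).  The
#' special bucket `"out"` marks an atom that cannot be kept inside the
#' Width-gauge at all (an inadmissible, oversized sitting); it fails the
#' width rule.
#'
#' @param ligand a `ligand_graph`
#' @param template a `cyp_template`
#' @param assignment data frame with columns `atom` (1-based index),
#'   `vertex` (vertex label) and `depth` (`"facial"`, `"mid"`, `"rear"`,
#'   `"out"`)
#' @param tol adjacency tolerance, in Ring-size units, for pairs of bonded
#'   atoms that are both assigned.  The lattice edge is `1/sqrt(3)`
#'   (about 0.577); the default 1.2 accepts same-ring sittings, matching
#'   the convention that atoms placed not exactly at a corner are accepted.
#' @return an `atom_placement`
#' @export
atom_placement <- function(ligand, template, assignment,
                           tol = 1.2) {
  stopifnot(inherits(ligand, "ligand_graph"),
            inherits(template, "cyp_template"),
            is.data.frame(assignment))
  need <- c("atom", "vertex", "depth")
  if (!all(need %in% names(assignment)))
    stop("assignment needs columns atom, vertex, depth")
  n <- nrow(ligand$atoms)
  a <- assignment
  a$atom <- as.integer(a$atom)
  if (nrow(a) && (any(a$atom < 1L | a$atom > n)))
    stop("assignment references atoms outside 1..", n)
  if (anyDuplicated(a$atom))
    stop("assignment maps an atom to more than one vertex")
  bad_depth <- setdiff(a$depth, c("facial", "mid", "rear", "out"))
  if (length(bad_depth))
    stop("unknown depth bucket(s): ", paste(bad_depth, collapse = ", "))
  vt <- template$vertices
  mi <- match(a$vertex, vt$label)
  if (anyNA(mi))
    stop("assignment references unknown vertex label(s): ",
         paste(unique(a$vertex[is.na(mi)]), collapse = ", "))
  under <- vapply(vt$features[mi], function(f) "under_shelf" %in% f,
                  logical(1))
  if (any(under))
    stop("assignment places atom(s) under the Shelf: ",
         paste(a$vertex[under], collapse = ", "))

  # bonded atoms that are both assigned must sit within tolerance
  if (nrow(ligand$bonds) && nrow(a) > 1L) {
    pos <- setNames(seq_len(nrow(a)), a$atom)
    xy <- cbind(vt$x[mi], vt$y[mi])
    for (i in seq_len(nrow(ligand$bonds))) {
      p1 <- pos[as.character(ligand$bonds$a1[i])]
      p2 <- pos[as.character(ligand$bonds$a2[i])]
      if (is.na(p1) || is.na(p2)) next
      d <- sqrt(sum((xy[p1, ] - xy[p2, ])^2))
      if (d > tol + 1e-9)
        stop("bonded atoms ", ligand$bonds$a1[i], " and ",
             ligand$bonds$a2[i], " are ", signif(d, 3),
             " Ring-size apart (tolerance ", tol, ")")
    }
  }

  structure(list(ligand = ligand, template_name = template$name,
                 assignment = a, tol = tol),
            class = "atom_placement")
}

#' Ring occupancy of a placement
#'
#' @param p an `atom_placement`
#' @param t the bound `cyp_template`
#' @return character vector of occupied ring labels
#' @export
placement_rings <- function(p, t) {
  stopifnot(inherits(p, "atom_placement"), inherits(t, "cyp_template"))
  mi <- match(p$assignment$vertex, t$vertices$label)
  sort(unique(unlist(t$vertices$member_rings[mi])))
}

#' Derive display notation from a placement
#'
#' Orders the occupied rings right-to-left, top-to-bottom and joins them
#' hyphen-linked.  This is a display convenience: an atom placement
#' carries strictly more information than a ring path.
#'
#' @param p an `atom_placement`
#' @param t the bound `cyp_template`
#' @return a `ring_path`
#' @export
placement_notation <- function(p, t) {
  occ <- placement_rings(p, t)
  if (!length(occ)) return(parse_placement("?"))
  cx <- vapply(occ, function(rl) {
    qr <- t$cells[[rl]]; qr[1] + qr[2] / 2
  }, numeric(1))
  cy <- vapply(occ, function(rl) t$cells[[rl]][2], numeric(1))
  parse_placement(paste(occ[order(cy, -cx)], collapse = "-"))
}

# atoms assigned to any vertex of the given ring
.atoms_in_ring <- function(p, t, ring) {
  mi <- match(p$assignment$vertex, t$vertices$label)
  hit <- vapply(t$vertices$member_rings[mi], function(rs) ring %in% rs,
                logical(1))
  p$assignment$atom[hit]
}

# atoms assigned to vertices carrying a given feature flag
.atoms_with_feature <- function(p, t, feature) {
  mi <- match(p$assignment$vertex, t$vertices$label)
  hit <- vapply(t$vertices$features[mi], function(f) feature %in% f,
                logical(1))
  p$assignment$atom[hit]
}

#' @export
print.atom_placement <- function(x, ...) {
  cat("<atom_placement> ", x$ligand$name, " on ", x$template_name, ": ",
      nrow(x$assignment), "/", nrow(x$ligand$atoms),
      " atoms assigned\n", sep = "")
  invisible(x)
}
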