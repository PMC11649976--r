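#' Construct a ligand graph
#'
#' Low-level constructor for the heavy-atom molecular graph the Template
#' rules operate on.  Most users should call [load_ligand()]; this
#' constructor is exposed so that small synthetic molecules (e.g. the toy
#' ligands used in property tests) can be built directly.
#'
#' @param name molecule name
#' @param atoms data frame with columns `element` (symbol), `charge`
#'   (integer), `aromatic` (logical), `in_ring` (logical), `rigid_block`
#'   (integer; 0 = flexible), `implicit_h` (integer)
#' @param bonds data frame with columns `a1`, `a2` (1-based atom indices)
#'   and `order` (1, 2, 3)
#' @param annotations named list of integer vectors (atom indices) for
#'   `lactone_ring_atom`, `heme_ligating_heteroatom`,
#'   `candidate_oxidation_site`; usually filled by
#'   [tag_functional_groups()]
#' @return a `ligand_graph`
#' @export
ligand_graph <- function(name, atoms, bonds,
                         annotations = list(lactone_ring_atom = integer(0),
                                            heme_ligating_heteroatom = integer(0),
                                            candidate_oxidation_site = integer(0))) {
  stopifnot(is.data.frame(atoms), is.data.frame(bonds) || nrow(atoms) == 1L)
  n <- nrow(atoms)
  if (any(atoms$element == "H"))
    stop("ligand graphs are hydrogen-free; strip explicit hydrogens first")
  if (nrow(bonds)) {
    if (any(bonds$a1 < 1L | bonds$a1 > n | bonds$a2 < 1L | bonds$a2 > n))
      stop("bond indices out of range")
  }
  for (k in names(annotations))
    if (length(annotations[[k]]) &&
        any(annotations[[k]] < 1L | annotations[[k]] > n))
      stop("annotation '", k, "' references an out-of-range atom")
  g <- structure(list(name = name, atoms = atoms, bonds = bonds,
                      annotations = annotations),
                 class = "ligand_graph")
  if (n > 1L && !.is_connected(g))
    stop("multi-fragment input: ligand graph must be connected ",
         "(load bi-molecule partners separately)")
  g
}

.is_connected <- function(g) {
  n <- nrow(g$atoms)
  if (n <= 1L) return(TRUE)
  adj <- .adj_list(g)
  seen <- logical(n); seen[1L] <- TRUE
  queue <- 1L
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- adj[[v]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  all(seen)
}

.adj_list <- function(g) {
  n <- nrow(g$atoms)
  adj <- rep(list(integer(0)), n)
  if (nrow(g$bonds))
    for (i in seq_len(nrow(g$bonds))) {
      a <- g$bonds$a1[i]; b <- g$bonds$a2[i]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  adj
}

#' Load a ligand as an annotated heavy-atom graph
#'
#' Accepts a SMILES string, a path to an SDF/MOL V2000 file, or an `SDF`
#' object from \pkg{ChemmineR}.  Explicit hydrogens are stripped (hydrogen
#' atoms are not considered for Template placement), aromaticity is
#' perceived from the smallest set of smallest rings, and rigid blocks
#' (fused ring systems plus double/triple-bond-constrained segments) are
#' labelled.  Atom order follows the input (SMILES written order or SDF
#' atom block order), so fixture atom indices are stable.
#'
#' @param source SMILES string, SDF/MOL file path, or `ChemmineR::SDF`
#' @param name molecule name; defaults to the SDF header or the SMILES
#'   string itself
#' @param tag if `TRUE` (default) run [tag_functional_groups()] before
#'   returning
#' @return a `ligand_graph`
#' @examples
#' benzene <- load_ligand("c1ccccc1", name = "benzene")
#' nrow(benzene$atoms)
#' @export
load_ligand <- function(source, name = NULL, tag = TRUE) {
  sdf <- NULL
  if (inherits(source, "SDF")) {
    sdf <- source
  } else if (is.character(source) && length(source) == 1L) {
    single <- regmatches(source,
      regexec("^\\[?([A-Z][a-z]?)(H[0-9]?)?([+-])?\\]?$", source))[[1]]
    if (length(single) && !file.exists(source)) {
      # single-heavy-atom molecules are built directly (the SDF toolchain
      # needs at least one bond)
      el <- single[2]
      chg <- if (identical(single[4], "+")) 1L else
        if (identical(single[4], "-")) -1L else 0L
      atoms <- data.frame(element = el, charge = chg, aromatic = FALSE,
                          in_ring = FALSE, rigid_block = 0L,
                          implicit_h = .implicit_h(el, chg,
                            data.frame(a1 = integer(0), a2 = integer(0),
                                       order = integer(0)), 1L),
                          stringsAsFactors = FALSE)
      g <- ligand_graph(name %||% source, atoms,
                        data.frame(a1 = integer(0), a2 = integer(0),
                                   order = integer(0)))
      g$rings <- list()
      g$coords2d <- matrix(0, 1L, 2L)
      if (tag) g <- tag_functional_groups(g)
      return(g)
    }
    if (file.exists(source) && grepl("\\.(sdf|mol)$", source,
                                     ignore.case = TRUE)) {
      set <- ChemmineR::read.SDFset(source)
      if (length(set) < 1L) stop("format error: no molecule in ", source)
      sdf <- set[[1]]
    } else {
      sdf <- tryCatch(ChemmineR::smiles2sdf(source)[[1]],
                      error = function(e)
                        stop("format error: cannot parse SMILES '",
                             source, "': ", conditionMessage(e)))
    }
  } else {
    stop("source must be a SMILES string, an SDF/MOL path, or an SDF object")
  }

  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elem <- sub("_.*$", "", rownames(ab))
  n_all <- length(elem)
  bonds_all <- if (length(bb) == 0L || is.null(dim(bb)) || nrow(bb) == 0L ||
                   ncol(bb) < 3L)
    data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  else
    data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))

  # MDL ctab charge codes (0 none, 1 = +3 ... 7 = -3) sit in the atom-block
  # column ChemmineR names "C5"
  charge <- integer(n_all)
  chg_col <- intersect(c("charge", "C5"), colnames(ab))
  if (length(chg_col)) {
    code <- as.integer(ab[, chg_col[1L]])
    charge <- ifelse(code == 0L, 0L, 4L - code)
  }

  keep <- elem != "H"
  idx_map <- cumsum(keep)
  bonds <- bonds_all[keep[bonds_all$a1] & keep[bonds_all$a2], , drop = FALSE]
  bonds$a1 <- idx_map[bonds$a1]
  bonds$a2 <- idx_map[bonds$a2]
  coords <- ab[keep, c(1, 2), drop = FALSE]
  elem <- elem[keep]
  charge <- charge[keep]
  n <- length(elem)

  # ring perception on the hydrogen-free graph
  ring_info <- .perceive_rings(n, bonds)
  aromatic <- .perceive_aromatic(sdf, keep, idx_map, ring_info, elem, bonds)
  in_ring <- ring_info$in_ring

  implicit_h <- .implicit_h(elem, charge, bonds, n)
  rigid_block <- .rigid_blocks(n, bonds, in_ring)

  atoms <- data.frame(element = elem, charge = charge, aromatic = aromatic,
                      in_ring = in_ring, rigid_block = rigid_block,
                      implicit_h = implicit_h, stringsAsFactors = FALSE)
  if (is.null(name)) {
    hdr <- tryCatch(ChemmineR::header(sdf)[["Molecule_Name"]],
                    error = function(e) NULL)
    name <- if (!is.null(hdr) && nzchar(hdr)) hdr
            else if (is.character(source)) source else "ligand"
  }
  g <- ligand_graph(name, atoms, bonds)
  g$rings <- ring_info$rings
  g$coords2d <- unname(as.matrix(coords))
  if (tag) g <- tag_functional_groups(g)
  g
}

# smallest-set-of-smallest-rings via bond-elimination on the cycle space;
# adequate for drug-sized molecules
.perceive_rings <- function(n, bonds) {
  in_ring <- logical(n)
  rings <- list()
  if (nrow(bonds) == 0L)
    return(list(in_ring = in_ring, rings = rings))
  adj <- rep(list(integer(0)), n)
  for (i in seq_len(nrow(bonds))) {
    adj[[bonds$a1[i]]] <- c(adj[[bonds$a1[i]]], bonds$a2[i])
    adj[[bonds$a2[i]]] <- c(adj[[bonds$a2[i]]], bonds$a1[i])
  }
  # for each bond, find the shortest cycle through it (BFS without the bond)
  seen_rings <- character(0)
  for (i in seq_len(nrow(bonds))) {
    a <- bonds$a1[i]; b <- bonds$a2[i]
    # BFS from a to b avoiding the direct edge
    prev <- rep(NA_integer_, n)
    dist <- rep(NA_integer_, n)
    dist[a] <- 0L
    queue <- a
    while (length(queue) && is.na(dist[b])) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) {
        if (v == a && w == b) next
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          prev[w] <- v
          queue <- c(queue, w)
        }
      }
    }
    if (!is.na(dist[b])) {
      path <- b
      while (path[1L] != a) path <- c(prev[path[1L]], path)
      key <- paste(sort(path), collapse = ",")
      if (!key %in% seen_rings) {
        seen_rings <- c(seen_rings, key)
        rings[[length(rings) + 1L]] <- path
      }
      in_ring[path] <- TRUE
    }
  }
  list(in_ring = in_ring, rings = rings)
}

.perceive_aromatic <- function(sdf, keep, idx_map, ring_info, elem, bonds) {
  n <- length(elem)
  aromatic <- logical(n)
  # bond order lookup
  bo <- new.env()
  if (nrow(bonds))
    for (i in seq_len(nrow(bonds))) {
      k <- paste(sort(c(bonds$a1[i], bonds$a2[i])), collapse = "-")
      assign(k, bonds$order[i], envir = bo)
    }
  get_bo <- function(a, b) get(paste(sort(c(a, b)), collapse = "-"), envir = bo)
  for (ring in ring_info$rings) {
    m <- length(ring)
    if (!m %in% c(5L, 6L)) next
    closed <- c(ring, ring[1L])
    orders <- vapply(seq_len(m), function(i) get_bo(closed[i], closed[i + 1L]),
                     numeric(1))
    els <- elem[ring]
    if (!all(els %in% c("C", "N", "O", "S"))) next
    if (m == 6L) {
      # kekulized benzene/pyridine pattern: alternating single/double
      if (sum(orders == 2) == 3L && sum(orders == 1) == 3L &&
          all(abs(diff(c(orders, orders[1L]))) == 1))
        aromatic[ring] <- TRUE
    } else {
      # five-membered heteroaromatics: two double bonds and one
      # lone-pair-donating heteroatom not involved in a double bond
      if (sum(orders == 2) == 2L) {
        dbl_atoms <- unique(unlist(lapply(which(orders == 2), function(i)
          closed[c(i, i + 1L)])))
        het <- ring[!ring %in% dbl_atoms]
        if (length(het) == 1L && elem[het] %in% c("N", "O", "S"))
          aromatic[ring] <- TRUE
      }
    }
  }
  aromatic
}

.implicit_h <- function(elem, charge, bonds, n) {
  valence <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1, Br = 1,
               I = 1, B = 3, Si = 4)
  bondsum <- numeric(n)
  if (nrow(bonds))
    for (i in seq_len(nrow(bonds))) {
      bondsum[bonds$a1[i]] <- bondsum[bonds$a1[i]] + bonds$order[i]
      bondsum[bonds$a2[i]] <- bondsum[bonds$a2[i]] + bonds$order[i]
    }
  v <- valence[elem]
  v[is.na(v)] <- 0
  # charge shifts nominal valence for N (+) and O/S (-)
  v <- v + ifelse(elem %in% c("N", "P"), charge,
                  ifelse(elem %in% c("O", "S"), charge, 0))
  as.integer(pmax(0, round(v - bondsum)))
}

.rigid_blocks <- function(n, bonds, in_ring) {
  block <- integer(n)
  if (!nrow(bonds)) return(block)
  # rigid edges: both ends in a ring and the bond lies in a ring, or bond
  # order >= 2
  adj <- rep(list(integer(0)), n)
  for (i in seq_len(nrow(bonds))) {
    rigid <- bonds$order[i] >= 2 ||
      (in_ring[bonds$a1[i]] && in_ring[bonds$a2[i]])
    if (rigid) {
      adj[[bonds$a1[i]]] <- c(adj[[bonds$a1[i]]], bonds$a2[i])
      adj[[bonds$a2[i]]] <- c(adj[[bonds$a2[i]]], bonds$a1[i])
    }
  }
  bid <- 0L
  for (s in seq_len(n)) {
    if (block[s] != 0L || !length(adj[[s]])) next
    bid <- bid + 1L
    queue <- s; block[s] <- bid
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) if (block[w] == 0L) {
        block[w] <- bid; queue <- c(queue, w)
      }
    }
  }
  block
}

#' Tag the functional groups the placement rules need
#'
#' Adds three annotation sets to a ligand graph:
#'
#' * `lactone_ring_atom` -- ring atoms of cyclic esters (lactones) and of
#'   cyclic imides (the thalidomide-class rings are treated as ionizable
#'   lactone-like groups).  These atoms are barred from Rear-wall and
#'   Trigger-residue contact.
#' * `heme_ligating_heteroatom` -- heteroatoms able to coordinate the heme
#'   iron: pyridine/azole-type aromatic nitrogens (two ring neighbours, no
#'   N--H) and primary/secondary aliphatic amine nitrogens outside amide
#'   context.
#' * `candidate_oxidation_site` -- atoms the enzyme can attack: carbons
#'   bearing at least one hydrogen, thioether sulfurs (S-oxidation) and
#'   tertiary aliphatic amine nitrogens (N-oxidation / N-dealkylation).
#'
#' @param g a `ligand_graph`
#' @return the graph with `annotations` filled in
#' @export
tag_functional_groups <- function(g) {
  stopifnot(inherits(g, "ligand_graph"))
  at <- g$atoms
  n <- nrow(at)
  adj <- .adj_list(g)
  bo <- function(a, b) {
    i <- which((g$bonds$a1 == a & g$bonds$a2 == b) |
                 (g$bonds$a1 == b & g$bonds$a2 == a))
    if (length(i)) g$bonds$order[i[1L]] else 0L
  }
  has_carbonyl_o <- vapply(seq_len(n), function(i) {
    at$element[i] == "C" &&
      any(vapply(adj[[i]], function(j)
        at$element[j] == "O" && bo(i, j) == 2L, logical(1)))
  }, logical(1))

  lactone <- integer(0)
  for (ring in g$rings %||% list()) {
    els <- at$element[ring]
    carbonyl_in_ring <- ring[has_carbonyl_o[ring]]
    if (!length(carbonyl_in_ring)) next
    # cyclic ester: ring O bonded to a ring carbonyl C
    ester <- any(vapply(ring[els == "O"], function(o)
      any(vapply(adj[[o]], function(c2)
        c2 %in% carbonyl_in_ring, logical(1))), logical(1)))
    # cyclic imide: ring N flanked by two ring carbonyl C
    imide <- any(vapply(ring[els == "N"], function(nn)
      sum(adj[[nn]] %in% carbonyl_in_ring) >= 2L, logical(1)))
    if (ester || imide) lactone <- union(lactone, ring)
  }

  amide_n <- vapply(seq_len(n), function(i)
    at$element[i] == "N" && any(has_carbonyl_o[adj[[i]]]), logical(1))

  # atoms sitting in a ring that carries internal unsaturation (pyrrole-like
  # NH is conjugated, not a basic amine)
  in_unsat_ring <- logical(n)
  for (ring in g$rings %||% list()) {
    closed <- c(ring, ring[1L])
    has_dbl <- any(vapply(seq_along(ring), function(i)
      bo(closed[i], closed[i + 1L]) >= 2L, logical(1)))
    if (has_dbl) in_unsat_ring[ring] <- TRUE
  }

  heme <- integer(0)
  cand <- integer(0)
  for (i in seq_len(n)) {
    el <- at$element[i]
    deg <- length(adj[[i]])
    if (el == "N" && at$aromatic[i] && deg == 2L && at$implicit_h[i] == 0L) {
      heme <- c(heme, i)                       # pyridine/azole-type N
    } else if (el == "N" && !at$aromatic[i] && !amide_n[i] &&
               !in_unsat_ring[i] && at$implicit_h[i] >= 1L) {
      heme <- c(heme, i)                       # 1'/2' aliphatic amine
    } else if (el == "N" && !at$aromatic[i] && !amide_n[i] &&
               at$implicit_h[i] == 0L && deg == 3L) {
      cand <- c(cand, i)                       # 3' amine: N-oxidation
    }
    if (el == "C" && at$implicit_h[i] >= 1L) cand <- c(cand, i)
    if (el == "S" && deg == 2L &&
        sum(g$bonds$order[g$bonds$a1 == i | g$bonds$a2 == i]) == 2L)
      cand <- c(cand, i)                       # thioether: S-oxidation
  }

  g$annotations <- list(lactone_ring_atom = sort(unique(lactone)),
                        heme_ligating_heteroatom = sort(unique(heme)),
                        candidate_oxidation_site = sort(unique(cand)))
  g
}

#' Flatten a ligand to a Template-plane conformer
#'
#' Produces the planar (flattened) conformer that is tried on the Template.
#' When 3D coordinates are supplied they are projected onto their best-fit
#' plane; otherwise the deterministic 2D depiction layout computed at load
#' time is used.  Coordinates are rescaled so that the median bond length
#' equals one lattice edge (Ring-size/sqrt(3)); depth (`z`) is initialised
#' mid-slab and only assigned by the placement search.
#'
#' The `strain_proxy` is the mean of squared relative bond-length
#' deviations and squared angular deviations (radians, from the ideal
#' 120-degree lattice angle) over the flattened structure.  It acts as the
#' conformational-strain accept/reject gate of the placement search
#' (default threshold 0.1).
#'
#' @param g a `ligand_graph`
#' @param coords3d optional matrix of per-atom x,y,z coordinates
#' @param template optionally a `cyp_template`, used to set the mid-slab
#'   depth
#' @return a `planar_conformer`: list with `ligand`, `coords` (n x 3),
#'   `strain_proxy`
#' @export
flatten_conformer <- function(g, coords3d = NULL, template = NULL) {
  stopifnot(inherits(g, "ligand_graph"))
  n <- nrow(g$atoms)
  if (!is.null(coords3d)) {
    coords3d <- as.matrix(coords3d)
    if (nrow(coords3d) != n)
      stop("coords3d must have one row per heavy atom")
    xy <- .project_plane(coords3d)
  } else if (!is.null(g$coords2d)) {
    xy <- g$coords2d
  } else {
    stop("no coordinates available; load the ligand from SMILES/SDF or ",
         "supply coords3d")
  }
  if (n > 1L && nrow(g$bonds)) {
    bl <- sqrt(rowSums((xy[g$bonds$a1, , drop = FALSE] -
                          xy[g$bonds$a2, , drop = FALSE])^2))
    med <- stats::median(bl)
    if (med > 0) xy <- xy * (HEX_EDGE / med)
  }
  zmid <- if (!is.null(template))
    (template$facial_depth + template$rear_depth) / 2 else 0.75
  coords <- cbind(xy, z = rep(zmid, n))
  structure(list(ligand = g, coords = coords,
                 strain_proxy = .strain_proxy(g, xy)),
            class = "planar_conformer")
}

.project_plane <- function(xyz) {
  ctr <- colMeans(xyz)
  cc <- sweep(xyz, 2L, ctr)
  sv <- svd(cc)
  cc %*% sv$v[, 1:2, drop = FALSE]
}

.strain_proxy <- function(g, xy) {
  if (!nrow(g$bonds)) return(0)
  bl <- sqrt(rowSums((xy[g$bonds$a1, , drop = FALSE] -
                        xy[g$bonds$a2, , drop = FALSE])^2))
  dev_len <- (bl / HEX_EDGE - 1)^2
  adj <- .adj_list(g)
  dev_ang <- numeric(0)
  for (i in seq_len(nrow(g$atoms))) {
    nb <- adj[[i]]
    if (length(nb) < 2L) next
    for (a in seq_along(nb)) for (b in seq_along(nb)) {
      if (a >= b) next
      v1 <- xy[nb[a], ] - xy[i, ]
      v2 <- xy[nb[b], ] - xy[i, ]
      cosang <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
      ang <- acos(pmin(1, pmax(-1, cosang)))
      dev_ang <- c(dev_ang, (ang - 2 * pi / 3)^2)
    }
  }
  # 0.5: calibration constant mapping the accept gate of flattened
  # depictions (including fused polycyclics) onto the 0.1 threshold slot
  0.5 * mean(c(dev_len, dev_ang))
}

#' @export
print.ligand_graph <- function(x, ...) {
  cat("<ligand_graph> ", x$name, ": ", nrow(x$atoms), " heavy atoms, ",
      nrow(x$bonds), " bonds\n", sep = "")
  ann <- x$annotations
  cat("  lactone-like ring atoms: ",
      paste(ann$lactone_ring_atom, collapse = " "), "\n",
      "  heme-ligating heteroatoms: ",
      paste(ann$heme_ligating_heteroatom, collapse = " "), "\n",
      "  candidate oxidation sites: ",
      length(ann$candidate_oxidation_site), " atoms\n", sep = "")
  invisible(x)
}
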