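#' Placement-search configuration
#'
#' @param strain_threshold accept gate for the flattened-conformer strain
#'   proxy (default 0.1)
#' @param max_placements cap on enumerated placements
#' @param seed integer seed; the search is deterministic, the seed only
#'   controls tie-shuffling in the beam heuristic (kept fixed by default)
#' @param allow_off_corner whether bonded atoms may share a vertex region
#'   instead of sitting on adjacent corners (needed for rings that are not
#'   lattice 6-cycles, e.g. five-membered rings)
#' @param off_corner_tol tolerance, Ring-size units, for bonded assigned
#'   atoms when `allow_off_corner` is `TRUE`
#' @param expand_depth if `TRUE`, embeddings are expanded over the three
#'   depth buckets per atom; if `FALSE` all atoms are returned mid-slab
#' @param atom_cap largest ligand handled by exhaustive enumeration
#' @param beam_width beam size of the heuristic search used above
#'   `atom_cap` or for graphs that do not embed bond-to-edge
#' @return a `search_config`
#' @export
search_config <- function(strain_threshold = 0.1, max_placements = 10000L,
                          seed = 1L, allow_off_corner = TRUE,
                          off_corner_tol = 1.2, expand_depth = TRUE,
                          atom_cap = 10L, beam_width = 64L) {
  stopifnot(strain_threshold >= 0, max_placements >= 1L)
  structure(list(strain_threshold = strain_threshold,
                 max_placements = as.integer(max_placements),
                 seed = as.integer(seed),
                 allow_off_corner = allow_off_corner,
                 off_corner_tol = off_corner_tol,
                 expand_depth = expand_depth,
                 atom_cap = as.integer(atom_cap),
                 beam_width = as.integer(beam_width)),
            class = "search_config")
}

# occupiable vertex table and adjacency (under-Shelf vertices excluded)
.lattice_graph <- function(t) {
  keep <- !vapply(t$vertices$features, function(f) "under_shelf" %in% f,
                  logical(1))
  labs <- t$vertices$label[keep]
  adj <- rep(list(character(0)), length(labs))
  names(adj) <- labs
  for (i in seq_len(nrow(t$edges))) {
    a <- t$edges[i, 1]; b <- t$edges[i, 2]
    if (a %in% labs && b %in% labs) {
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  list(labels = labs, adj = lapply(adj, sort))
}

.depth_levels <- c("facial", "mid", "rear")

.expand_depths <- function(emb_list, g, cfg) {
  if (!cfg$expand_depth) {
    return(lapply(emb_list, function(vs)
      data.frame(atom = seq_along(vs), vertex = vs, depth = "mid",
                 stringsAsFactors = FALSE)))
  }
  n <- length(emb_list[[1]])
  combos <- as.matrix(expand.grid(rep(list(.depth_levels), n),
                                  stringsAsFactors = FALSE))
  out <- vector("list", length(emb_list) * nrow(combos))
  k <- 0L
  for (vs in emb_list) for (i in seq_len(nrow(combos))) {
    k <- k + 1L
    out[[k]] <- data.frame(atom = seq_len(n), vertex = vs,
                           depth = unname(combos[i, ]),
                           stringsAsFactors = FALSE)
  }
  out
}

#' Enumerate admissible lattice embeddings of a ligand graph
#'
#' Exhaustively enumerates the embeddings of the heavy-atom graph onto the
#' Template lattice under the strict model: atoms map injectively to
#' occupiable vertices and every bond maps to a lattice edge, so ring
#' systems sit rigidly on lattice 6-cycles.  Depth buckets are free per
#' atom and expanded on request.  The enumeration is complete for this
#' model (up to `max_placements`) and deterministically ordered.
#'
#' Graphs whose rings are not lattice-embeddable under the strict model
#' (five-membered rings, bridged cages) yield an empty enumeration here;
#' [predict_ligand()] falls back to the off-corner beam heuristic for
#' those.
#'
#' @param g a `ligand_graph`
#' @param t a `cyp_template`
#' @param cfg a [search_config()]
#' @return list of assignment data frames (`atom`, `vertex`, `depth`)
#' @export
enumerate_embeddings <- function(g, t, cfg = search_config()) {
  stopifnot(inherits(g, "ligand_graph"))
  n <- nrow(g$atoms)
  if (n > cfg$atom_cap)
    stop("size error: ", n, " atoms exceeds the exhaustive-search cap of ",
         cfg$atom_cap)
  lat <- .lattice_graph(t)
  if (n == 0L) return(list())

  # BFS order starting inside the largest rigid block keeps the search
  # anchored; candidate sets then stay small
  order_atoms <- .search_order(g)
  adj <- .adj_list(g)

  embs <- list()
  assign_v <- character(n)
  used <- new.env(hash = TRUE)
  rec <- function(k) {
    if (length(embs) >= cfg$max_placements) return()
    if (k > n) {
      embs[[length(embs) + 1L]] <<- assign_v
      return()
    }
    a <- order_atoms[k]
    placed_nb <- intersect(adj[[a]], order_atoms[seq_len(k - 1L)])
    cand <- if (!length(placed_nb)) lat$labels
            else Reduce(intersect, lapply(placed_nb, function(b)
              lat$adj[[assign_v[b]]]))
    for (v in cand) {
      if (!is.null(used[[v]])) next
      assign_v[a] <<- v
      used[[v]] <- TRUE
      rec(k + 1L)
      rm(list = v, envir = used)
      if (length(embs) >= cfg$max_placements) return()
    }
  }
  rec(1L)
  .expand_depths(embs, g, cfg)
}

.search_order <- function(g) {
  n <- nrow(g$atoms)
  blocks <- g$atoms$rigid_block
  start <- if (any(blocks > 0L)) {
    big <- names(which.max(table(blocks[blocks > 0L])))
    min(which(blocks == as.integer(big)))
  } else 1L
  adj <- .adj_list(g)
  ord <- integer(0)
  seen <- logical(n)
  queue <- start; seen[start] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, v)
    nb <- sort(setdiff(adj[[v]], which(seen)))
    nb <- nb[!seen[nb]]
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  c(ord, setdiff(seq_len(n), ord))
}

#' Brute-force placement oracle
#'
#' Exhaustive reference enumeration for tiny graphs, used to verify
#' [enumerate_embeddings()]: every injective assignment of atoms (in plain
#' index order) to occupiable vertices is generated and filtered by the
#' admissibility predicate (all bonds on lattice edges, no under-Shelf
#' sitting).  Independent of the search-order and candidate-propagation
#' logic of the production enumeration.
#'
#' @param g a `ligand_graph` with at most 6 atoms
#' @param t a `cyp_template`
#' @param cfg a [search_config()] (only `expand_depth` is honoured)
#' @return list of assignment data frames
#' @export
brute_force_oracle <- function(g, t, cfg = search_config()) {
  n <- nrow(g$atoms)
  if (n > 6L) stop("size error: brute_force_oracle is limited to 6 atoms")
  lat <- .lattice_graph(t)
  edge_ok <- new.env(hash = TRUE)
  for (v in lat$labels) for (w in lat$adj[[v]])
    assign(paste(v, w, sep = "|"), TRUE, envir = edge_ok)
  is_edge <- function(a, b)
    !is.null(edge_ok[[paste(a, b, sep = "|")]])

  bonds <- g$bonds
  embs <- list()
  assign_v <- character(n)
  rec <- function(k) {
    if (k > n) {
      embs[[length(embs) + 1L]] <<- assign_v
      return()
    }
    for (v in lat$labels) {
      if (v %in% assign_v[seq_len(k - 1L)]) next
      assign_v[k] <<- v
      ok <- TRUE
      if (nrow(bonds)) {
        for (i in seq_len(nrow(bonds))) {
          a <- bonds$a1[i]; b <- bonds$a2[i]
          if (a <= k && b <= k && max(a, b) == k &&
              !is_edge(assign_v[a], assign_v[b])) { ok <- FALSE; break }
        }
      }
      if (ok) rec(k + 1L)
    }
    assign_v[k] <<- ""
  }
  rec(1L)
  .expand_depths(embs, g, cfg)
}

#' Canonical signature of an assignment (for set comparison)
#' @param assignment an assignment data frame
#' @return a single string
#' @export
assignment_signature <- function(assignment) {
  a <- assignment[order(assignment$atom), ]
  paste(paste(a$atom, a$vertex, a$depth, sep = ":"), collapse = ";")
}

#' Score a placement given its verdict
#'
#' The weighted contact count of [evaluate_placement()]: Rear-wall and
#' Facial-wall contacts, Shelf and Left-end occupancies, Site occupancy
#' and pillar support, each at its configured weight, plus the gate bonus
#' that keeps good placements ranked above poor ones of the same ligand.
#'
#' @param p an `atom_placement`
#' @param verdict the `verdict` for `p`
#' @return numeric score
#' @export
score_placement <- function(p, verdict) {
  stopifnot(inherits(verdict, "verdict"))
  verdict$score
}

#' Predict the Template interaction of a ligand
#'
#' Runs the full pipeline: flatten, gate on the strain proxy, enumerate
#' candidate placements (exhaustive for small lattice-embeddable graphs,
#' off-corner beam heuristic otherwise), simulate the Trigger-residue,
#' evaluate every rule, and rank.  The best admissible placement defines
#' `best_category` and the predicted oxidation sites; ties are broken by
#' the deterministic lexicographic order of the placement signatures.
#'
#' @param g a `ligand_graph`
#' @param t a `cyp_template`
#' @param cfg a [search_config()]
#' @param config a [rule_config()]
#' @return a `prediction`: list with `ligand`, `ranked` (list of
#'   `placement` + `verdict`, best first), `best_category`, `best_sites`,
#'   `strain_proxy`, `heuristic`
#' @export
predict_ligand <- function(g, t, cfg = search_config(),
                           config = rule_config()) {
  stopifnot(inherits(g, "ligand_graph"), inherits(t, "cyp_template"))
  fc <- tryCatch(flatten_conformer(g, template = t), error = function(e) NULL)
  strain <- if (is.null(fc)) 0 else fc$strain_proxy
  if (strain > cfg$strain_threshold) {
    return(structure(list(ligand = g$name, ranked = list(),
                          best_category = "NON_LIGAND",
                          best_sites = integer(0), strain_proxy = strain,
                          heuristic = FALSE,
                          note = "flattened conformer exceeds strain gate"),
                     class = "prediction"))
  }

  heuristic <- FALSE
  assigns <- if (nrow(g$atoms) <= cfg$atom_cap) {
    cfg_small <- cfg
    cfg_small$expand_depth <- FALSE
    enumerate_embeddings(g, t, cfg_small)
  } else list()
  if (!length(assigns)) {
    heuristic <- TRUE
    assigns <- .beam_search(g, t, cfg)
  }
  if (!length(assigns)) {
    return(structure(list(ligand = g$name, ranked = list(),
                          best_category = "NON_LIGAND",
                          best_sites = integer(0), strain_proxy = strain,
                          heuristic = heuristic,
                          note = "no admissible placement"),
                     class = "prediction"))
  }

  ranked <- lapply(assigns, function(a) {
    a <- .optimise_depths(a, g, t)
    p <- atom_placement(g, t, a, tol = if (cfg$allow_off_corner)
      cfg$off_corner_tol else HEX_EDGE + 1e-6)
    v <- evaluate_placement(p, t, config = config)
    list(placement = p, verdict = v)
  })
  sig <- vapply(ranked, function(x) assignment_signature(x$placement$assignment), "")
  sc <- vapply(ranked, function(x) x$verdict$score, numeric(1))
  ord <- order(-sc, sig)
  ranked <- ranked[ord]
  best <- ranked[[1L]]
  structure(list(ligand = g$name, ranked = ranked,
                 best_category = best$verdict$category,
                 best_sites = best$verdict$predicted_sites,
                 strain_proxy = strain, heuristic = heuristic,
                 note = ""),
            class = "prediction")
}

# depth buckets are free in the model; given a vertex assignment the
# score-optimal bucket per atom is rear for non-lactone atoms (Rear-wall
# contact weighs most) and mid for lactone-tagged atoms (barred from the
# Rear-wall)
.optimise_depths <- function(a, g, t) {
  lact <- g$annotations$lactone_ring_atom %||% integer(0)
  a$depth <- ifelse(a$atom %in% lact, "mid", "rear")
  # keep at least one facial contact when more than two atoms: the
  # flattened sheet touches both walls in the figures
  free <- which(!(a$atom %in% lact))
  if (length(free) > 2L) a$depth[free[length(free)]] <- "facial"
  a
}

# deterministic beam search over partial vertex assignments; candidates
# for each atom are the neighbours of (or, off-corner, the vertex of) an
# already-placed bonded atom
.beam_search <- function(g, t, cfg) {
  n <- nrow(g$atoms)
  lat <- .lattice_graph(t)
  adj <- .adj_list(g)
  ord <- .search_order(g)
  vt <- t$vertices
  vfeat <- setNames(vt$features, vt$label)
  cand_score <- function(v) {
    f <- vfeat[[v]]
    2 + 3 * ("in_site_of_oxidation" %in% f) + 2 * ("on_left_end" %in% f) +
      ("on_shelf_edge" %in% f)
  }
  states <- list(list(assign = setNames(character(0), character(0)),
                      occ = integer(0), score = 0))
  names(states[[1]]$occ) <- character(0)
  for (k in seq_len(n)) {
    a <- ord[k]
    nxt <- list()
    for (st in states) {
      placed_nb <- intersect(adj[[a]], as.integer(names(st$assign)))
      cand <- if (!length(placed_nb)) lat$labels
      else {
        base <- unique(unlist(lapply(placed_nb, function(b) {
          v <- st$assign[[as.character(b)]]
          c(lat$adj[[v]], if (cfg$allow_off_corner) v)
        })))
        # every placed bonded neighbour must stay within tolerance
        keep <- vapply(base, function(v) {
          all(vapply(placed_nb, function(b) {
            w <- st$assign[[as.character(b)]]
            i1 <- match(v, vt$label); i2 <- match(w, vt$label)
            d <- sqrt((vt$x[i1] - vt$x[i2])^2 + (vt$y[i1] - vt$y[i2])^2)
            d <= (if (cfg$allow_off_corner) cfg$off_corner_tol
                  else HEX_EDGE + 1e-6) + 1e-9
          }, logical(1)))
        }, logical(1))
        base[keep]
      }
      for (v in cand) {
        load <- st$occ[v]
        if (!is.na(load) && load >= 2L) next   # at most two atoms per vertex
        occ <- st$occ
        occ[v] <- if (is.na(load)) 1L else load + 1L
        asg <- st$assign
        asg[[as.character(a)]] <- v
        nxt[[length(nxt) + 1L]] <-
          list(assign = asg, occ = occ, score = st$score + cand_score(v))
      }
    }
    if (!length(nxt)) return(list())
    sig <- vapply(nxt, function(s)
      paste(names(s$assign), unlist(s$assign), collapse = ";"), "")
    o <- order(-vapply(nxt, `[[`, numeric(1), "score"), sig)
    states <- nxt[o[seq_len(min(cfg$beam_width, length(o)))]]
  }
  lapply(states[seq_len(min(length(states), cfg$max_placements))],
         function(st) {
           atoms <- as.integer(names(st$assign))
           data.frame(atom = atoms, vertex = unlist(st$assign),
                      depth = "mid", stringsAsFactors = FALSE)[order(atoms), ]
         })
}

#' @export
print.prediction <- function(x, ...) {
  cat("<prediction> ", x$ligand, ": ", x$best_category,
      if (length(x$best_sites))
        paste0(" (site atoms ", paste(x$best_sites, collapse = " "), ")")
      else "",
      "\n  placements ranked: ", length(x$ranked),
      "; strain proxy ", signif(x$strain_proxy, 3),
      if (x$heuristic) "; heuristic search" else "; exhaustive search",
      "\n", sep = "")
  invisible(x)
}

#' Trim a template to a subset of rings
#'
#' Builds a reduced Template containing only the given rings (plus their
#' vertices and edges).  Used for oracle-equivalence tests on small grids;
#' region features of surviving vertices are preserved.
#'
#' @param t a `cyp_template`
#' @param rings ring labels to keep
#' @return a `cyp_template` (name suffixed `-trimmed`)
#' @export
trim_template <- function(t, rings) {
  stopifnot(inherits(t, "cyp_template"))
  unknown <- setdiff(rings, names(t$rings))
  if (length(unknown)) stop("unknown ring label(s): ",
                            paste(unknown, collapse = ", "))
  keep_v <- unique(unlist(t$rings[rings]))
  tt <- t
  tt$name <- paste0(t$name, "-trimmed")
  tt$cells <- t$cells[rings]
  tt$rings <- t$rings[rings]
  tt$vertices <- t$vertices[t$vertices$label %in% keep_v, , drop = FALSE]
  rownames(tt$vertices) <- NULL
  tt$vertices$member_rings <- lapply(tt$vertices$member_rings,
                                     intersect, rings)
  tt$edges <- t$edges[t$edges[, 1] %in% keep_v & t$edges[, 2] %in% keep_v, ,
                      drop = FALSE]
  tt$site_of_oxidation <- intersect(t$site_of_oxidation, keep_v)
  tt$shelf$edge <- intersect(t$shelf$edge, keep_v)
  tt$under_shelf <- intersect(t$under_shelf, keep_v)
  tt$left_end <- intersect(t$left_end, keep_v)
  tt$entrance <- intersect(t$entrance, keep_v)
  tt$trigger$path <- intersect(t$trigger$path, rings)
  tt$trigger$support_rings <- intersect(t$trigger$support_rings, rings)
  tt
}
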