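#' Load a Template grid definition
#'
#' Reads a structured-text (YAML) Template definition and builds a validated
#' `cyp_template` object.  The package ships one canonical definition, the
#' CYP2J2 Template: a fused honeycomb of 21 core Rings (`A`--`U`) plus nine
#' extension regions (`eB`, `eC`, `eE`, `eJ`, `eL`, `eO`, `eP`, `eR`, `eU`),
#' with 54 numbered Positions, primed border anchors, the Shelf and Left-end
#' borders, the Entrance line, the Site of oxidation (Positions 2--4) and the
#' Trigger-residue path.
#'
#' Geometry convention: Ring-size (distance between opposite hexagon edges)
#' is the unit of length; hexagon edge length is therefore `1/sqrt(3)`.
#' The depth axis runs from the Facial-wall (`z = 0`) to the Rear-wall
#' (`z = width_gauge = 1.5` for CYP2J2).
#'
#' @param path path to a YAML Template definition.  Defaults to the packaged
#'   canonical CYP2J2 definition.
#' @return an object of class `cyp_template`; see Details for fields.
#' @details The returned list carries: `name`, `width_gauge`, `facial_depth`,
#'   `rear_depth`, `heme_access`, `vertices` (data frame: `label`, `kx`,
#'   `ky`, `x`, `y`, `member_rings`, `features`), `rings` (label -> 6 vertex
#'   labels, clockwise from top-left), `cells` (label -> axial coordinates),
#'   `edges` (two-column matrix of vertex labels), `site_of_oxidation`,
#'   `shelf` (edge labels + barrier), `left_end`, `entrance`, `trigger`
#'   (`path`, `pillar`, `support_rings`), and `definition_path`.
#' @seealso [validate_template()], [ring_vertices()], [region_membership()]
#' @examples
#' t2j2 <- load_template()
#' t2j2$width_gauge
#' length(grep("^[0-9]+$", t2j2$vertices$label))
#' @export
load_template <- function(path = cyp2j2_template_path()) {
  if (!file.exists(path)) stop("template definition not found: ", path)
  def <- yaml::read_yaml(path)

  required <- c("name", "width_gauge", "facial_depth", "rear_depth",
                "cells", "positions", "rings", "site_of_oxidation",
                "shelf", "left_end", "entrance", "trigger")
  missing <- setdiff(required, names(def))
  if (length(missing))
    stop("malformed template definition; missing field(s): ",
         paste(missing, collapse = ", "))

  labs <- names(def$positions)
  if (anyDuplicated(labs))
    stop("malformed template definition; duplicated vertex label(s): ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  keys <- do.call(rbind, lapply(def$positions, as.integer))
  if (ncol(keys) != 2L)
    stop("malformed template definition; field 'positions' must map labels ",
         "to integer [kx, ky] pairs")

  ring_tab <- def$rings
  bad_len <- names(ring_tab)[vapply(ring_tab, length, 1L) != 6L]
  if (length(bad_len))
    stop("reference error in field 'rings': ring(s) not listing 6 vertices: ",
         paste(bad_len, collapse = ", "))
  ring_labs <- unique(unlist(ring_tab))
  dangling <- setdiff(ring_labs, labs)
  if (length(dangling))
    stop("reference error in field 'rings': unknown vertex label(s): ",
         paste(dangling, collapse = ", "))
  for (f in c("site_of_oxidation", "left_end"))
    if (length(setdiff(unlist(def[[f]]), labs)))
      stop("reference error in field '", f, "': unknown vertex label(s): ",
           paste(setdiff(unlist(def[[f]]), labs), collapse = ", "))
  if (length(setdiff(unlist(def$shelf$edge), labs)))
    stop("reference error in field 'shelf': unknown vertex label(s): ",
         paste(setdiff(unlist(def$shelf$edge), labs), collapse = ", "))
  if (length(setdiff(unlist(def$entrance), labs)))
    stop("reference error in field 'entrance': unknown vertex label(s): ",
         paste(setdiff(unlist(def$entrance), labs), collapse = ", "))
  if (length(setdiff(unlist(def$trigger$path), names(ring_tab))))
    stop("reference error in field 'trigger': unknown ring label(s): ",
         paste(setdiff(unlist(def$trigger$path), names(ring_tab)),
               collapse = ", "))

  xy <- vertex_xy(keys[, 1], keys[, 2])
  member_rings <- rep(list(character(0)), length(labs))
  names(member_rings) <- labs
  for (rl in names(ring_tab))
    for (vl in ring_tab[[rl]])
      member_rings[[vl]] <- c(member_rings[[vl]], rl)

  under_shelf <- as.character(unlist(def$under_shelf))
  features <- lapply(labs, function(vl) {
    fs <- character(0)
    if (vl %in% unlist(def$shelf$edge)) fs <- c(fs, "on_shelf_edge")
    if (vl %in% unlist(def$left_end)) fs <- c(fs, "on_left_end")
    if (vl %in% unlist(def$site_of_oxidation)) fs <- c(fs, "in_site_of_oxidation")
    if (vl %in% unlist(def$entrance)) fs <- c(fs, "entrance_anchor")
    if (vl %in% under_shelf) fs <- c(fs, "under_shelf")
    fs
  })
  names(features) <- labs

  vertices <- data.frame(label = labs, kx = keys[, 1], ky = keys[, 2],
                         x = xy[, "x"], y = xy[, "y"],
                         stringsAsFactors = FALSE)
  vertices$member_rings <- unname(member_rings)
  vertices$features <- unname(features)

  # edge set from ring boundaries (consecutive corners, closed)
  epairs <- do.call(rbind, lapply(ring_tab, function(vs) {
    cbind(vs, c(vs[-1], vs[1]))
  }))
  esort <- t(apply(epairs, 1L, sort))
  edges <- unique(esort)
  colnames(edges) <- c("v1", "v2")

  t <- structure(list(
    name = def$name,
    width_gauge = as.numeric(def$width_gauge),
    facial_depth = as.numeric(def$facial_depth),
    rear_depth = as.numeric(def$rear_depth),
    heme_access = def$heme_access,
    cells = lapply(def$cells, as.integer),
    vertices = vertices,
    rings = lapply(ring_tab, as.character),
    edges = edges,
    site_of_oxidation = as.character(unlist(def$site_of_oxidation)),
    shelf = list(edge = as.character(unlist(def$shelf$edge)),
                 barrier = lapply(def$shelf$barrier, as.integer)),
    under_shelf = under_shelf,
    left_end = as.character(unlist(def$left_end)),
    entrance = as.character(unlist(def$entrance)),
    trigger = list(path = as.character(unlist(def$trigger$path)),
                   pillar = as.numeric(unlist(def$trigger$pillar)),
                   support_rings = as.character(unlist(def$trigger$support_rings))),
    definition_path = path
  ), class = "cyp_template")

  viol <- validate_template(t)
  if (length(viol))
    stop("template definition fails validation:\n  ",
         paste(vapply(viol, `[[`, "", "message"), collapse = "\n  "))
  t
}

#' Path of the packaged canonical CYP2J2 Template definition
#' @return file path (character scalar)
#' @export
cyp2j2_template_path <- function() {
  system.file("extdata", "cyp2j2_template.yaml", package = "cyptemplate",
              mustWork = TRUE)
}

#' Validate a Template grid
#'
#' Checks the structural invariants of a `cyp_template`:
#' * `rear_depth - facial_depth` equals `width_gauge` exactly;
#' * every ring is a closed 6-cycle of lattice-adjacent vertices with equal
#'   edge lengths;
#' * the Trigger path names existing rings and never contains Ring `A`;
#' * Site-of-oxidation, Shelf and Left-end labels all resolve;
#' * the Trigger path runs strictly right-to-left.
#'
#' Violations are returned as data, not raised as conditions.
#'
#' @param t a `cyp_template`
#' @return a list of violation descriptors (each a list with `invariant`,
#'   `element`, `message`); empty iff the template is valid.
#' @export
validate_template <- function(t) {
  stopifnot(inherits(t, "cyp_template"))
  viol <- list()
  add <- function(invariant, element, message)
    viol[[length(viol) + 1L]] <<- list(invariant = invariant,
                                       element = element, message = message)

  if (abs((t$rear_depth - t$facial_depth) - t$width_gauge) > 0)
    add("width_gauge", t$name,
        "rear_depth - facial_depth must equal width_gauge exactly")

  vtab <- t$vertices
  rownames(vtab) <- vtab$label
  for (rl in names(t$rings)) {
    vs <- t$rings[[rl]]
    if (length(vs) != 6L || anyDuplicated(vs)) {
      add("ring_6_cycle", rl, paste0("ring ", rl, " is not a 6-cycle"))
      next
    }
    kk <- as.matrix(vtab[vs, c("kx", "ky")])
    closed <- rbind(kk, kk[1, , drop = FALSE])
    for (i in seq_len(6)) {
      if (!keys_adjacent(closed[i, ], closed[i + 1L, ])) {
        add("ring_6_cycle", rl,
            paste0("ring ", rl, ": vertices ", vs[i], " and ",
                   vs[c(2:6, 1)[i]], " are not lattice-adjacent"))
      }
    }
  }

  tp <- t$trigger$path
  if ("A" %in% tp)
    add("trigger_path", "A", "ring A must not appear in trigger_path")
  unknown <- setdiff(tp, names(t$rings))
  if (length(unknown))
    add("trigger_path", unknown[1],
        paste0("trigger_path names unknown ring(s): ",
               paste(unknown, collapse = ", ")))
  if (!length(unknown) && length(tp) > 1L) {
    cx <- vapply(tp, function(rl) {
      qr <- t$cells[[rl]]; qr[1] + qr[2] / 2
    }, numeric(1))
    if (any(diff(cx) >= 0))
      add("trigger_path", paste(tp, collapse = "-"),
          "trigger_path must run strictly right-to-left")
  }

  for (vl in c(t$site_of_oxidation, t$shelf$edge, t$left_end, t$entrance))
    if (!vl %in% vtab$label)
      add("labels_resolve", vl, paste0("unknown vertex label: ", vl))
  if (!all(t$site_of_oxidation %in% grep("^[0-9]+$", vtab$label, value = TRUE)))
    add("site_numbered", paste(t$site_of_oxidation, collapse = ","),
        "site_of_oxidation must be numbered positions")

  # equal edge length across the grid
  xy <- as.matrix(vtab[, c("x", "y")])
  rownames(xy) <- vtab$label
  el <- sqrt(rowSums((xy[t$edges[, 1], , drop = FALSE] -
                        xy[t$edges[, 2], , drop = FALSE])^2))
  if (any(abs(el - HEX_EDGE) > 1e-9))
    add("edge_length", t$edges[which.max(abs(el - HEX_EDGE)), 1],
        "lattice edges must all be one hexagon edge length")

  viol
}

#' Ordered vertex labels of one Ring
#'
#' @param t a `cyp_template`
#' @param ring ring label, e.g. `"A"` or `"eL"`
#' @return the 6 vertex labels of the ring, clockwise from top-left
#' @export
ring_vertices <- function(t, ring) {
  stopifnot(inherits(t, "cyp_template"))
  if (!ring %in% names(t$rings))
    stop("unknown ring label: ", ring)
  t$rings[[ring]]
}

#' Region features of one vertex
#'
#' @param t a `cyp_template`
#' @param vertex a vertex label (numbered position such as `"3"`, primed
#'   anchor such as `"54'"`, or extension corner such as `"eE.1"`)
#' @return character vector of feature flags drawn from `on_shelf_edge`,
#'   `on_left_end`, `in_site_of_oxidation`, `entrance_anchor`, `under_shelf`
#' @export
region_membership <- function(t, vertex) {
  stopifnot(inherits(t, "cyp_template"))
  i <- match(vertex, t$vertices$label)
  if (is.na(i)) stop("unknown vertex label: ", vertex)
  t$vertices$features[[i]]
}

#' Serialize a Template grid back to its definition document
#'
#' Writes a YAML document that [load_template()] reads back to an identical
#' `cyp_template` (label-exact round trip).
#'
#' @param t a `cyp_template`
#' @param path output file path
#' @return `path`, invisibly
#' @export
serialize_template <- function(t, path) {
  stopifnot(inherits(t, "cyp_template"))
  positions <- lapply(seq_len(nrow(t$vertices)), function(i)
    c(t$vertices$kx[i], t$vertices$ky[i]))
  names(positions) <- t$vertices$label
  def <- list(
    name = t$name,
    units = "ring_size",
    width_gauge = t$width_gauge,
    facial_depth = t$facial_depth,
    rear_depth = t$rear_depth,
    heme_access = t$heme_access,
    cells = t$cells,
    positions = positions,
    rings = t$rings,
    site_of_oxidation = t$site_of_oxidation,
    shelf = list(edge = t$shelf$edge, barrier = t$shelf$barrier),
    under_shelf = as.list(t$under_shelf),
    left_end = as.list(t$left_end),
    entrance = t$entrance,
    trigger = t$trigger
  )
  yaml::write_yaml(def, path, precision = 12)
  invisible(path)
}

#' @export
print.cyp_template <- function(x, ...) {
  cat("<cyp_template> ", x$name, "\n", sep = "")
  cat("  rings: ", length(x$rings), " (",
      sum(!grepl("^e", names(x$rings))), " core + ",
      sum(grepl("^e", names(x$rings))), " extension)\n", sep = "")
  cat("  vertices: ", nrow(x$vertices), " (",
      length(grep("^[0-9]+$", x$vertices$label)), " numbered positions)\n",
      sep = "")
  cat("  width gauge: ", x$width_gauge, " Ring-size; heme access: ",
      x$heme_access, "\n", sep = "")
  cat("  site of oxidation: positions ",
      paste(x$site_of_oxidation, collapse = ", "), "\n", sep = "")
  cat("  trigger path: ", paste(x$trigger$path, collapse = " -> "),
      "; pillar ", paste(x$trigger$pillar, collapse = " x "),
      " Ring-size\n", sep = "")
  invisible(x)
}

#' Draw the Template grid
#'
#' Renders the hexagonal grid with ring labels, numbered positions and the
#' named regions highlighted.  Purely illustrative; no computation depends
#' on the rendering.
#'
#' @param x a `cyp_template`
#' @param cex_pos label size for position numbers
#' @param ... passed to [graphics::plot()]
#' @export
plot.cyp_template <- function(x, cex_pos = 0.5, ...) {
  v <- x$vertices
  graphics::plot(v$x, v$y, type = "n", asp = 1, xlab = "x (Ring-size)",
                 ylab = "y (Ring-size)", main = x$name, ...)
  xy <- as.matrix(v[, c("x", "y")])
  rownames(xy) <- v$label
  graphics::segments(xy[x$edges[, 1], 1], xy[x$edges[, 1], 2],
                     xy[x$edges[, 2], 1], xy[x$edges[, 2], 2],
                     col = "grey70")
  site <- v$label %in% x$site_of_oxidation
  graphics::points(v$x[site], v$y[site], pch = 19, col = "firebrick")
  le <- v$label %in% x$left_end
  graphics::points(v$x[le], v$y[le], pch = 19, col = "steelblue")
  sh <- v$label %in% x$shelf$edge
  graphics::points(v$x[sh], v$y[sh], pch = 19, col = "darkorange")
  graphics::text(v$x, v$y, v$label, cex = cex_pos, pos = 3, offset = 0.15)
  for (rl in names(x$rings)) {
    qr <- x$cells[[rl]]
    cx <- qr[1] + qr[2] / 2
    cy <- qr[2] * 1.5 * HEX_EDGE
    graphics::text(cx, cy, rl, cex = 0.9,
                   col = if (grepl("^e", rl)) "grey40" else "black")
  }
  invisible(x)
}
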