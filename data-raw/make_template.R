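# One-off generator for the canonical CYP2J2 template definition.
# Writes inst/extdata/cyp2j2_template.yaml.  Run from repo root:
#   Rscript data-raw/make_template.R
source("R/lattice.R")

core_cells <- list(
  A = c(0L, 0L),  B = c(1L, 0L),  C = c(2L, 0L),  D = c(0L, 1L),
  E = c(-1L, 0L), F = c(-2L, 1L), G = c(-1L, 1L), H = c(1L, 1L),
  I = c(2L, 1L),  J = c(0L, 2L),  K = c(-1L, 2L), L = c(-2L, 2L),
  M = c(-3L, 3L), N = c(-2L, 3L), O = c(-1L, 3L), P = c(-1L, 4L),
  Q = c(-2L, 4L), R = c(-3L, 4L), S = c(-4L, 5L), T = c(-3L, 5L),
  U = c(-2L, 5L)
)
ext_cells <- list(
  eB = c(3L, 0L),  eC = c(3L, 1L),  eE = c(-2L, 0L), eJ = c(1L, 2L),
  eL = c(-3L, 2L), eO = c(0L, 3L),  eP = c(0L, 4L),  eR = c(-4L, 4L),
  eU = c(-1L, 5L)
)
cells <- c(core_cells, ext_cells)
core_labels <- names(core_cells)

# vertex key -> set of cells touching it
corner_map <- list()
for (cl in names(cells)) {
  ck <- cell_corner_keys(cells[[cl]][1], cells[[cl]][2])
  for (i in seq_len(6)) {
    key <- vertex_key_chr(ck[i, 1], ck[i, 2])
    corner_map[[key]] <- c(corner_map[[key]], cl)
  }
}
keys_mat <- do.call(rbind, lapply(strsplit(names(corner_map), ","), as.integer))
rownames(keys_mat) <- names(corner_map)

is_core_corner <- vapply(corner_map, function(cs) any(cs %in% core_labels), logical(1))
cat("total vertices:", nrow(keys_mat), " core corners:", sum(is_core_corner), "\n")

primed <- list(
  "11'" = c(-3L, 1L),
  "48'" = c(2L, 16L), "49'" = c(1L, 17L), "50'" = c(0L, 16L),
  "51'" = c(-1L, 17L), "52'" = c(-2L, 16L), "53'" = c(-3L, 17L),
  "54'" = c(-4L, 16L)
)
primed_keys <- vapply(primed, function(k) vertex_key_chr(k[1], k[2]), character(1))
stopifnot(all(primed_keys %in% rownames(keys_mat)[is_core_corner]))

# numbered positions: core corners minus primed, swept bottom-to-top then
# left-to-right
num_keys <- setdiff(rownames(keys_mat)[is_core_corner], primed_keys)
ord <- order(keys_mat[num_keys, 2], keys_mat[num_keys, 1])
num_keys <- num_keys[ord]
cat("numbered positions:", length(num_keys), "\n")
stopifnot(length(num_keys) == 54L)

labels <- character(nrow(keys_mat))
names(labels) <- rownames(keys_mat)
labels[num_keys] <- as.character(seq_along(num_keys))
labels[primed_keys] <- names(primed)

# extension-only corners: label <cell>.<corner-index>, corner order
# clockwise from top-left (NW=1 .. SW=6); ties to the alphabetically first
# extension cell
ext_only <- rownames(keys_mat)[!is_core_corner]
for (cl in sort(names(ext_cells))) {
  ck <- cell_corner_keys(ext_cells[[cl]][1], ext_cells[[cl]][2])
  for (i in seq_len(6)) {
    key <- vertex_key_chr(ck[i, 1], ck[i, 2])
    if (key %in% ext_only && labels[key] == "")
      labels[key] <- paste0(cl, ".", i)
  }
}
stopifnot(all(labels != ""))

# report a few pinned anchors
show <- function(kx, ky) labels[vertex_key_chr(kx, ky)]
cat("A-tip:", show(0, -2), " B-tip:", show(2, -2), " C-tip:", show(4, -2),
    " E-tip:", show(-2, -2), "\n")
cat("A/E upper junction:", show(-1, 1), " (want 10)\n")
cat("A/B lower junction:", show(1, -1), " B/C lower:", show(3, -1), "\n")

rings <- lapply(cells, function(qr) {
  ck <- cell_corner_keys(qr[1], qr[2])
  unname(labels[vertex_key_chr(ck[, 1], ck[, 2])])
})

positions <- lapply(rownames(keys_mat), function(k) unname(keys_mat[k, ]))
names(positions) <- labels[rownames(keys_mat)]
# order: numbered, primed, extension
positions <- positions[c(as.character(1:54), names(primed),
                         sort(setdiff(names(positions),
                                      c(as.character(1:54), names(primed)))))]

under_shelf <- names(positions)[vapply(positions, function(k)
  k[1] < -3L && k[2] < 1L, logical(1))]
cat("under-shelf vertices:", paste(under_shelf, collapse = " "), "\n")

left_end_keys <- list(c(-3L, 1L), c(-4L, 2L), c(-4L, 4L), c(-5L, 5L),
                      c(-5L, 7L), c(-4L, 8L), c(-4L, 10L), c(-5L, 11L),
                      c(-5L, 13L), c(-4L, 14L), c(-4L, 16L))
left_end <- vapply(left_end_keys, function(k) unname(labels[vertex_key_chr(k[1], k[2])]),
                   character(1))
cat("left-end polyline:", paste(left_end, collapse = " "), "\n")

shelf_edge <- unname(c(labels[vertex_key_chr(-5L, 1L)], "11'", "10"))

def <- list(
  name = "CYP2J2",
  units = "ring_size",
  width_gauge = 1.5,
  facial_depth = 0.0,
  rear_depth = 1.5,
  heme_access = "rear",
  cells = lapply(cells, as.integer),
  positions = positions,
  rings = rings,
  site_of_oxidation = c("2", "3", "4"),
  shelf = list(edge = shelf_edge,
               barrier = list(kx_max = -3L, ky_level = 1L)),
  under_shelf = as.list(under_shelf),
  left_end = as.list(left_end),
  entrance = c("49'", "54'"),
  trigger = list(path = c("eB", "C", "B"),
                 pillar = c(0.5, 0.5, 3.0),
                 support_rings = c("K", "J", "O"))
)

yaml::write_yaml(def, "inst/extdata/cyp2j2_template.yaml", precision = 12)
cat("written inst/extdata/cyp2j2_template.yaml\n")
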