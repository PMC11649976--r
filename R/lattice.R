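# Internal hexagonal-lattice helpers.
#
# The Template plane is a honeycomb of pointy-top hexagonal cells ("Rings").
# Ring-size (the distance between two opposite hexagon edges) is the unit of
# length, so the hexagon edge length is 1/sqrt(3).  Cells are addressed by
# axial coordinates (q, r); the centre of cell (q, r) sits at
# x = q + r/2, y = r * 3 * s / 2 with s = 1/sqrt(3).
#
# Vertices are addressed by exact integer keys (kx, ky) with
# x = kx / 2 and y = ky * s / 2, which makes vertex identity across fused
# cells exact (no floating-point comparisons).

HEX_EDGE <- 1 / sqrt(3)

# corner order is clockwise from top-left: NW, top, NE, SE, bottom, SW
.corner_offsets <- function() {
  rbind(
    NW     = c(-1L,  1L),
    top    = c( 0L,  2L),
    NE     = c( 1L,  1L),
    SE     = c( 1L, -1L),
    bottom = c( 0L, -2L),
    SW     = c(-1L, -1L)
  )
}

cell_center_key <- function(q, r) c(2L * q + r, 3L * r)

cell_corner_keys <- function(q, r) {
  ctr <- cell_center_key(q, r)
  off <- .corner_offsets()
  keys <- sweep(off, 2L, ctr, `+`)
  rownames(keys) <- rownames(off)
  keys
}

vertex_key_chr <- function(kx, ky) paste(kx, ky, sep = ",")

vertex_xy <- function(kx, ky) {
  cbind(x = kx / 2, y = ky * HEX_EDGE / 2)
}

# two vertices are lattice-adjacent iff they are one hexagon edge apart:
# either |dkx| = 0, |dky| = 2 (vertical edge of the key lattice is not a
# honeycomb edge, so this is excluded) -- honeycomb edges connect keys at
# (|dkx|, |dky|) == (1, 1) or (0, 2).  In the pointy-top honeycomb only the
# (1, 1) and the (0, 2) steps that belong to a cell boundary exist; since we
# always derive edges from cell boundaries this predicate is only used on
# such pairs.
keys_adjacent <- function(k1, k2) {
  d <- abs(k1 - k2)
  (d[1] == 1L && d[2] == 1L) || (d[1] == 0L && d[2] == 2L)
}

vertex_dist <- function(xy1, xy2) {
  sqrt(sum((xy1 - xy2)^2))
}
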