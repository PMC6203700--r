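# Vectorized array interpolation at fractional voxel positions.
# Positions are 1-based R voxel coordinates; sampling outside the grid
# clamps to the border (replicate padding), which keeps displacement-field
# composition stable at the edges.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

interp_nearest <- function(arr, pts) {
  d <- dim(arr)
  i <- clamp(round(pts[, 1]), 1, d[1])
  j <- clamp(round(pts[, 2]), 1, d[2])
  k <- clamp(round(pts[, 3]), 1, d[3])
  arr[cbind(i, j, k)]
}

interp_trilinear <- function(arr, pts) {
  d <- dim(arr)
  x <- clamp(pts[, 1], 1, d[1])
  y <- clamp(pts[, 2], 1, d[2])
  z <- clamp(pts[, 3], 1, d[3])
  x0 <- clamp(floor(x), 1, d[1] - 1L); x1 <- x0 + 1
  y0 <- clamp(floor(y), 1, d[2] - 1L); y1 <- y0 + 1
  z0 <- clamp(floor(z), 1, d[3] - 1L); z1 <- z0 + 1
  if (d[1] == 1L) { x0 <- x1 <- rep(1, length(x)) }
  if (d[2] == 1L) { y0 <- y1 <- rep(1, length(y)) }
  if (d[3] == 1L) { z0 <- z1 <- rep(1, length(z)) }
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  n1 <- d[1]; n12 <- d[1] * d[2]
  lin <- function(i, j, k) arr[i + (j - 1) * n1 + (k - 1) * n12]
  c000 <- lin(x0, y0, z0); c100 <- lin(x1, y0, z0)
  c010 <- lin(x0, y1, z0); c110 <- lin(x1, y1, z0)
  c001 <- lin(x0, y0, z1); c101 <- lin(x1, y0, z1)
  c011 <- lin(x0, y1, z1); c111 <- lin(x1, y1, z1)
  c00 <- c000 * (1 - fx) + c100 * fx
  c10 <- c010 * (1 - fx) + c110 * fx
  c01 <- c001 * (1 - fx) + c101 * fx
  c11 <- c011 * (1 - fx) + c111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  c0 * (1 - fz) + c1 * fz
}

# shift an array by an integer offset, filling exposed voxels
shift_array <- function(arr, offset, fill = 0) {
  d <- dim(arr)
  out <- array(fill, dim = d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    o <- offset[ax]
    if (o >= d[ax] || -o >= d[ax]) return(out)
    if (o >= 0) {
      dst[[ax]] <- seq.int(1 + o, d[ax])
      src[[ax]] <- seq.int(1, d[ax] - o)
    } else {
      dst[[ax]] <- seq.int(1, d[ax] + o)
      src[[ax]] <- seq.int(1 - o, d[ax])
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

face_offsets <- rbind(
  c(1, 0, 0), c(-1, 0, 0),
  c(0, 1, 0), c(0, -1, 0),
  c(0, 0, 1), c(0, 0, -1))
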