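# Independent brute-force oracles, deliberately kept separate from the
# package's regular-grid machinery.

# Monte-Carlo intersection fraction: uniform random points inside the voxel.
mc_cut_fraction <- function(r_norm, center_offset, voxel, n_points = 2e5) {
  pts <- matrix(runif(3 * n_points, -0.5, 0.5), ncol = 3)
  d <- voxel - center_offset
  mean((pts[, 1] + d[1])^2 + (pts[, 2] + d[2])^2 +
         (pts[, 3] + d[3])^2 < r_norm^2)
}

# Dense-point classification: "inside" if all of n^3 regular points fall in
# the sphere, "outside" if none do, "cut" otherwise. Written without reusing
# package internals.
brute_classify <- function(r_norm, center_offset, voxel, n = 51) {
  g <- (seq_len(n) - (n + 1) / 2) / n
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  d <- voxel - center_offset
  inside <- (pts[, 1] + d[1])^2 + (pts[, 2] + d[2])^2 +
    (pts[, 3] + d[3])^2 < r_norm^2
  k <- sum(inside)
  if (k == nrow(pts)) "inside" else if (k == 0) "outside" else "cut"
}

# Exact closest-approach distance from a cube centered at integer index v
# (unit edge) to a point s; used to confirm sliver cut voxels analytically.
cube_min_dist <- function(v, s) sqrt(sum(pmax(0, abs(v - s) - 0.5)^2))
cube_max_dist <- function(v, s) sqrt(sum((abs(v - s) + 0.5)^2))
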