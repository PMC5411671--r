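# Independent brute-force oracles used to cross-check the implementation.

# Partition of the TRUE voxels of a 3-D logical array into 26-connected
# components by boolean transitive closure of the pairwise adjacency matrix
# (repeated matrix squaring until fixpoint) — deliberately different from the
# package's BFS labelling. Returns an integer array, components numbered in
# ascending order of their minimal (x, y, z)-lexicographic voxel.
closure_label_oracle <- function(cancer) {
  d <- dim(cancer)
  idx <- which(cancer)
  out <- array(0L, d)
  if (!length(idx)) return(out)
  ijk <- arrayInd(idx, d)
  ord <- order(ijk[, 1], ijk[, 2], ijk[, 3])
  idx <- idx[ord]; ijk <- ijk[ord, , drop = FALSE]
  m <- length(idx)
  A <- (abs(outer(ijk[, 1], ijk[, 1], "-")) <= 1) &
       (abs(outer(ijk[, 2], ijk[, 2], "-")) <= 1) &
       (abs(outer(ijk[, 3], ijk[, 3], "-")) <= 1)
  R <- A | diag(m) > 0
  repeat {
    R2 <- (R %*% R) > 0
    if (identical(R2, R)) break
    R <- R2
  }
  comp <- integer(m)
  nid <- 0L
  for (i in seq_len(m)) {
    if (comp[i] == 0L) {
      nid <- nid + 1L
      comp[R[i, ]] <- nid
    }
  }
  out[idx] <- comp
  out
}

# direct trilinear interpolation of a 3-D array sampled at `nodes` (list of
# per-axis coordinates), evaluated at a single point by the 8-corner formula
trilinear_oracle <- function(A, nodes, p) {
  w <- function(ax, q) {
    nd <- nodes[[ax]]
    if (q < nd[1] || q > nd[length(nd)]) return(NULL)
    j <- max(1, min(findInterval(q, nd), length(nd) - 1))
    t <- (q - nd[j]) / (nd[j + 1] - nd[j])
    list(j = j, t = t)
  }
  wx <- w(1, p[1]); wy <- w(2, p[2]); wz <- w(3, p[3])
  if (is.null(wx) || is.null(wy) || is.null(wz)) return(0)
  v <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    cw <- (if (dx) wx$t else 1 - wx$t) * (if (dy) wy$t else 1 - wy$t) *
      (if (dz) wz$t else 1 - wz$t)
    v <- v + cw * A[wx$j + dx, wy$j + dy, wz$j + dz]
  }
  v
}

# direct (non-separable) Gaussian convolution of a 3-D array at one voxel,
# kernel sampled at voxel centres, truncated at 4 sigma, unit mass, zero
# padding
gauss_oracle <- function(A, i, j, k, sigma, res) {
  K <- max(1L, ceiling(4 * sigma / res))
  off <- -K:K
  g1 <- exp(-(off * res)^2 / (2 * sigma^2))
  g1 <- g1 / sum(g1)
  d <- dim(A)
  v <- 0
  for (a in off) for (b in off) for (cc in off) {
    ii <- i + a; jj <- j + b; kk <- k + cc
    if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] &&
        kk >= 1 && kk <= d[3])
      v <- v + g1[a + K + 1] * g1[b + K + 1] * g1[cc + K + 1] * A[ii, jj, kk]
  }
  v
}

# type-7 quantile recomputed from its definition: h = (n - 1) p + 1, linear
# interpolation between the floor(h)-th and next order statistics
quantile7_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- min(lo + 1, n)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# expected coarse z profile (1-based voxel -> pair code) of a needle at
# template site (ix, iy), re-derived from the lesion specs: a 1 mm voxel is
# cancer iff at least one of its two 0.5 mm sample centres falls inside a
# lesion (the >= 50% overlap rule), and carries the run's recombined pair.
site_profile_oracle <- function(lesions, ix, iy, grid = grid_spec()) {
  x <- (ix + 0.5) * grid$spacing
  y <- (iy + 0.5) * grid$spacing
  nz <- grid$coarse_dim[3]
  prof <- integer(nz)
  for (iz in seq_len(nz)) {
    for (zc in c(iz - 0.75, iz - 0.25)) {
      for (ls in lesions) {
        u <- ((x - ls$center[1]) / ls$radii[1])^2 +
          ((y - ls$center[2]) / ls$radii[2])^2 +
          ((zc - ls$center[3]) / ls$radii[3])^2
        if (u <= 1) prof[iz] <- ls$base_score
      }
    }
  }
  prof
}

# quick constructor for a hand-built fine map (0.5 mm grid starting at the
# origin) for hotspot tests: `label` is a 0/3/4/5 integer array, `lesion` an
# id array of the same dimensions
fake_fine_map <- function(label, lesion, res = 0.5) {
  d <- dim(label)
  structure(list(
    fields = list(presence = (label > 0) * 1,
                  g3 = (label == 3) * 1, g4 = (label == 4) * 1,
                  g5 = (label == 5) * 1),
    centers = list(x = (seq_len(d[1]) - 0.5) * res,
                   y = (seq_len(d[2]) - 0.5) * res,
                   z = (seq_len(d[3]) - 0.5) * res),
    res = res, grid = grid_spec(), origin = c(0L, 0L, 0L),
    sigma = 0, label = label, lesion_id = lesion,
    lesions = list(labels = lesion, n_lesions = max(lesion),
                   voxels = lapply(seq_len(max(lesion)), function(id)
                     which(lesion == id, arr.ind = TRUE)))
  ), class = "fine_map")
}
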