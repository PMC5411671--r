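# ---- separable linear algebra helpers -------------------------------------

# Apply matrix M (m x n) along `axis` of 3-D array A (size n on that axis).
apply_axis <- function(A, M, axis) {
  d <- dim(A)
  if (axis == 1L) {
    out <- M %*% matrix(A, nrow = d[1L])
    dim(out) <- c(nrow(M), d[2L], d[3L])
    out
  } else if (axis == 3L) {
    out <- matrix(A, ncol = d[3L]) %*% t(M)
    dim(out) <- c(d[1L], d[2L], nrow(M))
    out
  } else {
    B <- aperm(A, c(2L, 1L, 3L))
    out <- M %*% matrix(B, nrow = d[2L])
    dim(out) <- c(nrow(M), d[1L], d[3L])
    aperm(out, c(2L, 1L, 3L))
  }
}

apply_separable <- function(A, Mx, My, Mz) {
  apply_axis(apply_axis(apply_axis(A, Mx, 1L), My, 2L), Mz, 3L)
}

# Hat-function (piecewise linear) interpolation weights from `nodes` (sorted,
# strictly increasing) to query `points`. Within `pad` beyond the outermost
# nodes the field is clamped to the boundary node (the outer voxel extends
# half a voxel past its centre); beyond that it is zero. Returns a dense
# m x n matrix.
interp_weights <- function(points, nodes, pad = 0) {
  n <- length(nodes); m <- length(points)
  W <- matrix(0, m, n)
  if (n == 1L) {
    W[abs(points - nodes) <= pad + 1e-9, 1L] <- 1
    return(W)
  }
  inside <- points >= nodes[1L] - pad - 1e-9 & points <= nodes[n] + pad + 1e-9
  pts <- pmin(pmax(points, nodes[1L]), nodes[n])
  j <- findInterval(pts, nodes, rightmost.closed = TRUE)
  j <- pmin(pmax(j, 1L), n - 1L)
  t <- (pts - nodes[j]) / (nodes[j + 1L] - nodes[j])
  t <- pmin(pmax(t, 0), 1)
  rows <- which(inside)
  W[cbind(rows, j[rows])] <- 1 - t[rows]
  W[cbind(rows, j[rows] + 1L)] <- W[cbind(rows, j[rows] + 1L)] + t[rows]
  W
}

# Discrete Gaussian convolution matrix (zero padding) for n samples at pitch
# `res` mm and standard deviation `sigma` mm. Kernel normalised to unit mass,
# so interior mass is conserved; boundary rows lose the truncated tail.
gaussian_band <- function(n, sigma, res) {
  if (sigma == 0) return(diag(n))
  K <- max(1L, ceiling(4 * sigma / res))
  g <- exp(-((-K:K) * res)^2 / (2 * sigma^2))
  g <- g / sum(g)
  B <- matrix(0, n, n)
  for (k in -K:K) {
    i <- seq_len(n)
    ok <- i + k >= 1L & i + k <= n
    B[cbind(i[ok], (i + k)[ok])] <- g[k + K + 1L]
  }
  B
}

# ---- fine map construction ------------------------------------------------

fine_centers <- function(map) {
  g <- map$grid; d <- dim(map$grade)
  res <- g$fine_res
  ext <- function(o, n, pitch) {
    lo <- o * pitch
    nf <- round(n * pitch / res)
    lo + (seq_len(nf) - 0.5) * res
  }
  list(x = ext(map$origin[1L], d[1L], g$spacing),
       y = ext(map$origin[2L], d[2L], g$spacing),
       z = ext(map$origin[3L], d[3L], g$coarse_z_res))
}

coarse_indicators <- function(map) {
  gr <- map$grade
  gr0 <- ifelse(is.na(gr), 0L, gr)
  prim <- gr0 %/% 10L; sec <- gr0 %% 10L
  list(presence = (gr0 > 0L) * 1,
       g3 = (prim == 3L | sec == 3L) * 1,
       g4 = (prim == 4L | sec == 4L) * 1,
       g5 = (prim == 5L | sec == 5L) * 1)
}

#' Trilinear interpolation of the coarse map to the 0.5 mm fine grid
#'
#' Builds one scalar field per Gleason pattern (3, 4, 5) plus a
#' cancer-presence field. Each coarse voxel contributes an indicator that is 1
#' when its Gleason pair contains the pattern (a 3+4 voxel is read as
#' sub-voxel intermixture of patterns 3 and 4), and the indicators are
#' trilinearly interpolated from the coarse voxel centres to the fine voxel
#' centres. Between the outermost voxel centres and the edge of the coarse
#' volume (half a voxel) the fields are clamped to the boundary value; beyond
#' the volume they are zero. The interpolant reproduces the coarse indicators
#' exactly at the coarse voxel centres.
#'
#' @param map A `coarse_map` (typically [crop_coarse_map()]ped).
#' @param lesions Optional `lesion_map` of `map`; when supplied, lesion ids
#'   are propagated to fine cancer voxels by nearest coarse cancer voxel
#'   (in millimetres) once the map is labelled (see [reconstruct_fine()]).
#' @return An object of class `fine_map`: list with `fields` (named list of
#'   3-D arrays `presence`, `g3`, `g4`, `g5`), fine voxel centre coordinates,
#'   `sigma` (`NA` until smoothed), and the source map geometry.
#' @export
interpolate_fine <- function(map, lesions = NULL) {
  cc <- coarse_centers(map)
  fc <- fine_centers(map)
  Wx <- interp_weights(fc$x, cc$x, pad = map$grid$spacing / 2)
  Wy <- interp_weights(fc$y, cc$y, pad = map$grid$spacing / 2)
  Wz <- interp_weights(fc$z, cc$z, pad = map$grid$coarse_z_res / 2)
  ind <- coarse_indicators(map)
  fields <- lapply(ind, function(A) {
    if (!any(A > 0)) array(0, c(length(fc$x), length(fc$y), length(fc$z)))
    else apply_separable(A, Wx, Wy, Wz)
  })
  structure(list(fields = fields, centers = fc, res = map$grid$fine_res,
                 grid = map$grid, origin = map$origin, sigma = NA_real_,
                 lesions = lesions, label = NULL, lesion_id = NULL),
            class = "fine_map")
}

#' Isotropic Gaussian smoothing of the fine fields
#'
#' Convolves every scalar field with a separable isotropic Gaussian kernel of
#' standard deviation `sigma` (mm), with zero padding outside the volume.
#' `sigma = 0` is the identity. The kernel has unit mass, so field mass is
#' conserved away from the volume boundary.
#'
#' @param fine A `fine_map` (usually from [interpolate_fine()]).
#' @param sigma Standard deviation in mm, >= 0.
#' @return The smoothed `fine_map` with `sigma` recorded.
#' @export
gaussian_smooth <- function(fine, sigma) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma > 0) {
    d <- dim(fine$fields$presence)
    Bx <- gaussian_band(d[1L], sigma, fine$res)
    Bz <- gaussian_band(d[3L], sigma, fine$res)
    By <- if (d[2L] == d[1L]) Bx else gaussian_band(d[2L], sigma, fine$res)
    fine$fields <- lapply(fine$fields, function(A) {
      if (!any(A != 0)) A else apply_separable(A, Bx, By, Bz)
    })
  }
  fine$sigma <- sigma
  fine
}

# voxel label volume: 0 = benign; else highest pattern whose indicator >= 0.5
# at the voxel, falling back to the argmax pattern (ties to the higher grade).
fine_label <- function(fine) {
  f <- fine$fields
  cancer <- f$presence >= 0.5
  lab <- array(0L, dim(f$presence))
  lab[cancer & f$g3 >= 0.5] <- 3L
  lab[cancer & f$g4 >= 0.5] <- 4L
  lab[cancer & f$g5 >= 0.5] <- 5L
  rest <- cancer & lab == 0L
  if (any(rest)) {
    best <- array(3L, dim(lab))
    best[f$g4 >= f$g3 & f$g4 >= f$g5] <- 4L
    best[f$g5 >= f$g3 & f$g5 >= f$g4] <- 5L
    lab[rest] <- best[rest]
  }
  lab
}

#' Resample fine fields at the coarse template grid sites
#'
#' Point sampling (default) evaluates each field at the coarse voxel centres
#' by trilinear interpolation from the fine voxel centres; block averaging
#' instead averages the field over each 5 x 5 x 1 mm block. Point sampling is
#' the package default (deterministic and exact for the node-interpolation
#' property); the resampling operator behind the preservation criterion is
#' switchable here.
#'
#' @param fine A `fine_map`.
#' @param map The source `coarse_map` (same geometry).
#' @param method `"point"` or `"block"`.
#' @return Named list of arrays with the coarse dimensions.
#' @export
resample_at_sites <- function(fine, map, method = c("point", "block")) {
  method <- match.arg(method)
  if (!identical(dim(fine$fields$presence),
                 as.integer(round(dim(map$grade) *
                   c(map$grid$spacing, map$grid$spacing, map$grid$coarse_z_res) /
                   map$grid$fine_res))))
    stop("fine and coarse geometries do not match")
  cc <- coarse_centers(map)
  fc <- fine_centers(map)
  if (method == "point") {
    Sx <- interp_weights(cc$x, fc$x)
    Sy <- interp_weights(cc$y, fc$y)
    Sz <- interp_weights(cc$z, fc$z)
  } else {
    block_mat <- function(nc, nf) {
      k <- nf / nc
      M <- matrix(0, nc, nf)
      for (i in seq_len(nc)) M[i, ((i - 1L) * k + 1L):(i * k)] <- 1 / k
      M
    }
    d <- dim(map$grade); df <- dim(fine$fields$presence)
    Sx <- block_mat(d[1L], df[1L]); Sy <- block_mat(d[2L], df[2L])
    Sz <- block_mat(d[3L], df[3L])
  }
  lapply(fine$fields, apply_separable, Sx, Sy, Sz)
}

#' Check grid-site preservation of the reconstruction
#'
#' The clinical validity criterion of the reconstruction: re-sampling the
#' smoothed fine map at the template grid sites must reproduce the original
#' histology. Concretely, at every sampled coarse voxel centre (a) the
#' cancer-presence field is >= 0.5 exactly for the cancer voxels, and (b) at
#' cancer voxels the fine voxel label (highest pattern with indicator >= 0.5)
#' equals the coarse voxel's highest Gleason pattern. `strict = TRUE`
#' additionally requires the full pattern set \{p : indicator_p >= 0.5\} to
#' equal the coarse pair's pattern set.
#'
#' @param fine A `fine_map`.
#' @param map The source `coarse_map`.
#' @param strict Validate the full pattern set rather than the highest
#'   pattern.
#' @param method Resampling operator, see [resample_at_sites()].
#' @return A list with `ok` (logical) and `violations` (tibble of 0-based
#'   global voxel indices and the failed condition).
#' @export
preservation_check <- function(fine, map, strict = FALSE,
                               method = c("point", "block")) {
  rs <- resample_at_sites(fine, map, method)
  gr <- map$grade
  sampled <- !is.na(gr)
  cancer <- sampled & gr > 0L
  status_bad <- sampled & ((rs$presence >= 0.5) != cancer)
  prim <- ifelse(cancer, gr %/% 10L, NA_integer_)
  sec <- ifelse(cancer, gr %% 10L, NA_integer_)
  hi <- pmax(prim, sec)
  lab <- array(0L, dim(gr))
  lab[rs$g3 >= 0.5] <- 3L
  lab[rs$g4 >= 0.5] <- 4L
  lab[rs$g5 >= 0.5] <- 5L
  grade_bad <- cancer & (lab != hi)
  if (strict) {
    set_bad <- cancer & (
      ((rs$g3 >= 0.5) != (prim == 3L | sec == 3L)) |
      ((rs$g4 >= 0.5) != (prim == 4L | sec == 4L)) |
      ((rs$g5 >= 0.5) != (prim == 5L | sec == 5L)))
    set_bad[is.na(set_bad)] <- FALSE
    grade_bad <- grade_bad | set_bad
  }
  status_bad[is.na(status_bad)] <- FALSE
  grade_bad[is.na(grade_bad)] <- FALSE
  viol <- rbind(
    if (any(status_bad)) cbind(which(status_bad, arr.ind = TRUE), reason = 1L),
    if (any(grade_bad)) cbind(which(grade_bad, arr.ind = TRUE), reason = 2L))
  violations <- if (is.null(viol)) {
    tibble::tibble(ix = integer(0), iy = integer(0), iz = integer(0),
                   reason = character(0))
  } else {
    tibble::tibble(ix = viol[, 1L] - 1L + map$origin[1L],
                   iy = viol[, 2L] - 1L + map$origin[2L],
                   iz = viol[, 3L] - 1L + map$origin[3L],
                   reason = c("status", "grade")[viol[, 4L]])
  }
  list(ok = nrow(violations) == 0L, violations = violations)
}

#' Tune the smoothing parameter against the preservation constraint
#'
#' Selects the largest `sigma` in `[0, sigma_max]` (bisection to tolerance
#' `tol`) such that [preservation_check()] still holds — maximal smoothness
#' subject to fidelity at the grid sites. The unsmoothed interpolation always
#' satisfies the constraint, so the search is well defined; `sigma_max`
#' defaults to one grid pitch (5 mm).
#'
#' @param fine A pre-smoothing `fine_map` from [interpolate_fine()].
#' @param map The source `coarse_map`.
#' @param tol Bisection tolerance in mm.
#' @param sigma_max Upper search bound in mm.
#' @param strict,method Passed to [preservation_check()].
#' @return The tuned sigma (mm).
#' @export
tune_sigma <- function(fine, map, tol = 0.02, sigma_max = 5,
                       strict = FALSE, method = "point") {
  ok <- function(s) preservation_check(gaussian_smooth(fine, s), map,
                                       strict = strict, method = method)$ok
  if (!ok(0)) stop("unsmoothed interpolation violates preservation; geometry mismatch?")
  if (ok(sigma_max)) return(sigma_max)
  lo <- 0; hi <- sigma_max
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (ok(mid)) lo <- mid else hi <- mid
  }
  lo
}

# nearest-coarse-cancer-voxel lesion id propagation, chunked BLAS brute force
# in mm (argmin of |f - c|^2 = argmax of 2 f.c - |c|^2)
assign_fine_lesions <- function(fine, map, lesions) {
  lab <- fine$label
  d <- dim(lab)
  out <- array(0L, d)
  fidx <- which(lab > 0L)
  if (!length(fidx) || lesions$n_lesions == 0L) return(out)
  if (lesions$n_lesions == 1L) {
    out[fidx] <- 1L
    return(out)
  }
  cidx <- which(lesions$labels > 0L, arr.ind = TRUE)
  cid <- lesions$labels[lesions$labels > 0L]
  cc <- coarse_centers(map)
  C <- cbind(cc$x[cidx[, 1L]], cc$y[cidx[, 2L]], cc$z[cidx[, 3L]])
  fijk <- arrayInd(fidx, d)
  fc <- fine_centers(map)
  Fm <- cbind(fc$x[fijk[, 1L]], fc$y[fijk[, 2L]], fc$z[fijk[, 3L]])
  c2 <- rowSums(C^2)
  chunk <- max(1L, floor(2e7 / nrow(C)))
  for (s in seq(1L, length(fidx), by = chunk)) {
    e <- min(s + chunk - 1L, length(fidx))
    score <- 2 * (Fm[s:e, , drop = FALSE] %*% t(C))
    score <- score - rep(c2, each = e - s + 1L)
    out[fidx[s:e]] <- cid[max.col(score, ties.method = "first")]
  }
  out
}

#' Full reconstruction of one coarse map
#'
#' Runs [interpolate_fine()], tunes the smoothing parameter with
#' [tune_sigma()] (unless `sigma` is given), smooths, computes the voxel
#' label volume, and propagates lesion ids to the fine cancer voxels.
#'
#' @inheritParams tune_sigma
#' @param lesions A `lesion_map` from [label_lesions()] on `map`.
#' @param sigma Fixed smoothing sigma (mm); `NULL` to tune.
#' @return A `fine_map` with `label` (0/3/4/5 array), `lesion_id` (integer
#'   array) and `sigma` populated.
#' @export
reconstruct_fine <- function(map, lesions = NULL, sigma = NULL, tol = 0.02,
                             sigma_max = 5, strict = FALSE, method = "point") {
  if (is.null(lesions)) lesions <- label_lesions(map)
  pre <- interpolate_fine(map, lesions)
  if (is.null(sigma))
    sigma <- tune_sigma(pre, map, tol = tol, sigma_max = sigma_max,
                        strict = strict, method = method)
  fine <- gaussian_smooth(pre, sigma)
  fine$label <- fine_label(fine)
  fine$lesions <- lesions
  fine$lesion_id <- assign_fine_lesions(fine, map, lesions)
  fine
}

#' @export
print.fine_map <- function(x, ...) {
  cat(sprintf("fine map %s at %g mm, sigma = %s mm\n",
              paste(dim(x$fields$presence), collapse = " x "), x$res,
              ifelse(is.na(x$sigma), "untuned", format(x$sigma))))
  invisible(x)
}
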