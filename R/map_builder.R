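#' Cancer core length under the separate or cumulative counting rule
#'
#' When a core contains discontinuous cancer foci there are two conventions
#' for its cancer core length (CCL): the \emph{separate} count excludes the
#' intervening benign tissue (CCL = sum of focus lengths, one segment per
#' focus), while the \emph{cumulative} count spans from the start of the first
#' focus to the end of the last, regardless of benign gaps. Both agree on
#' cores with a single continuous focus.
#'
#' Under the cumulative rule the merged segment needs a single Gleason score;
#' the package recombines the foci by length-weighted pattern abundance
#' (primary pattern of each focus weighted 0.6, secondary 0.4, times focus
#' length): the merged primary is the most abundant pattern and the merged
#' secondary the highest other pattern present (equal to the primary for pure
#' segments).
#'
#' @param foci Focus data frame of one core (`offset`, `length`, `primary`,
#'   `secondary`, columns as in [core_records()]), or one row of a
#'   `tpm_cores` tibble.
#' @param mode `"separate"` or `"cumulative"`.
#' @return A list with `segments` (tibble `z_start`, `z_end`, `pair` in
#'   core-local mm), `ccl` (mm under the active mode) and `mccl_basis`
#'   (length of the longest single segment, the quantity a maximum-CCL
#'   comparison is based on).
#' @export
#' @examples
#' f <- data.frame(offset = c(2, 9), length = c(3, 2),
#'                 primary = 3, secondary = 3)
#' compute_ccl(f, "separate")$ccl    # 5
#' compute_ccl(f, "cumulative")$ccl  # 9
compute_ccl <- function(foci, mode = c("separate", "cumulative")) {
  mode <- match.arg(mode)
  if (is.data.frame(foci) && "foci" %in% names(foci)) foci <- foci$foci[[1L]]
  foci <- normalize_foci(foci)
  if (nrow(foci) > 1 &&
      any(foci$offset[-1] < (foci$offset + foci$length)[-nrow(foci)] - 1e-9))
    stop("overlapping cancer foci")
  if (!nrow(foci)) {
    return(list(segments = new_segments(numeric(0), numeric(0), integer(0)),
                ccl = 0, mccl_basis = 0))
  }
  pairs <- gleason_pair(foci$primary, foci$secondary)
  if (mode == "separate") {
    segments <- new_segments(foci$offset, foci$offset + foci$length, pairs)
    list(segments = segments, ccl = sum(foci$length),
         mccl_basis = max(foci$length))
  } else {
    span <- c(foci$offset[1L], foci$offset[nrow(foci)] + foci$length[nrow(foci)])
    segments <- new_segments(span[1L], span[2L],
                             recombine_grades(pairs, foci$length))
    list(segments = segments, ccl = diff(span), mccl_basis = diff(span))
  }
}

new_segments <- function(z_start, z_end, pair) {
  tibble::new_tibble(list(z_start = z_start, z_end = z_end, pair = pair),
                     nrow = length(z_start))
}

# Length-weighted Gleason recombination: pattern weight = sum over pieces of
# length * (0.6 for the piece's primary, 0.4 for its secondary). Primary of
# the result = most abundant pattern (ties to the higher pattern), secondary =
# highest other pattern with positive weight.
recombine_grades <- function(pairs, lengths) {
  w <- numeric(3L)  # patterns 3, 4, 5
  p <- gleason_primary(pairs); s <- gleason_secondary(pairs)
  for (i in seq_along(pairs)) {
    if (p[i] == s[i]) {
      w[p[i] - 2L] <- w[p[i] - 2L] + lengths[i]
    } else {
      w[p[i] - 2L] <- w[p[i] - 2L] + 0.6 * lengths[i]
      w[s[i] - 2L] <- w[s[i] - 2L] + 0.4 * lengths[i]
    }
  }
  prim <- max(which(w >= max(w) - 1e-12)) + 2L
  others <- which(w > 1e-12) + 2L
  others <- others[others != prim]
  sec <- if (length(others)) max(others) else prim
  gleason_pair(prim, sec)
}

#' Build the coarse 13 x 13 x 40 pathology map for one patient
#'
#' Paints each core's CCL segments into the 5 x 5 x 1 mm voxel grid at the
#' core's template coordinate. Apex cores map core-local z directly to global
#' z (apical end at z = 0); base cores are offset by one needle length
#' (20 mm). Voxels covered by a sampled core but by no cancer segment are
#' benign; template columns with no core at a given depth are no-tissue
#' (`NA`). Sub-millimetre segment boundaries are resolved by a >= 50%
#' voxel-overlap rule; where two segments claim one voxel the higher Gleason
#' score wins.
#'
#' @param records `tpm_cores` tibble for a single patient.
#' @param grid A [grid_spec()].
#' @param ccl_mode `"separate"` or `"cumulative"` (passed to [compute_ccl()]).
#' @return An object of class `coarse_map`: list with `grade` (nx x ny x nz
#'   integer array; `NA` = no tissue, `0` = benign, otherwise a Gleason pair
#'   code), `grid`, `ccl_mode`, and `origin` (0-based coarse indices of the
#'   array's first voxel, used by cropped maps).
#' @export
build_coarse_map <- function(records, grid = grid_spec(),
                             ccl_mode = c("separate", "cumulative")) {
  ccl_mode <- match.arg(ccl_mode)
  records <- validate_cores(records, grid)
  if (length(unique(records$patient_id)) > 1L)
    stop("coarse map expects records from one patient")
  dims <- grid$coarse_dim
  grade <- array(NA_integer_, dims)
  zres <- grid$coarse_z_res
  for (i in seq_len(nrow(records))) {
    ix <- records$grid_x[i] + 1L
    iy <- records$grid_y[i] + 1L
    z_off <- if (records$depth_slot[i] == "apex") 0 else grid$needle_length
    cover <- overlapped_voxels(z_off, z_off + records$core_length[i], zres, dims[3L])
    cur <- grade[ix, iy, cover]
    grade[ix, iy, cover] <- ifelse(is.na(cur), 0L, cur)
    res <- compute_ccl(records$foci[[i]], ccl_mode)
    segs <- res$segments
    for (j in seq_len(nrow(segs))) {
      a <- z_off + segs$z_start[j]; b <- z_off + segs$z_end[j]
      if (b > z_off + grid$needle_length + 1e-9)
        stop("segment extends past the ", grid$needle_length, " mm core window")
      vox <- overlapped_voxels(a, b, zres, dims[3L])
      cur <- grade[ix, iy, vox]
      take <- is.na(cur) | cur == 0L |
        gleason_rank(segs$pair[j]) >= ifelse(cur > 0L, gleason_rank(cur), -1L)
      grade[ix, iy, vox[take]] <- segs$pair[j]
    }
  }
  structure(list(grade = grade, grid = grid, ccl_mode = ccl_mode,
                 origin = c(0L, 0L, 0L)),
            class = "coarse_map")
}

# 1-based z voxel indices whose [i-1, i) mm extent is overlapped by [a, b)
# over at least half a voxel (or that contain [a, b) entirely when b - a < res/2
# never happens: such slivers are dropped, documented).
overlapped_voxels <- function(a, b, res, nz) {
  if (b <= a) return(integer(0))
  lo <- max(0L, floor(a / res))
  hi <- min(nz - 1L, ceiling(b / res) - 1L)
  if (hi < lo) return(integer(0))
  i <- lo:hi
  ov <- pmin(b, (i + 1) * res) - pmax(a, i * res)
  i[ov >= res / 2 - 1e-9] + 1L
}

#' @export
print.coarse_map <- function(x, ...) {
  n_cancer <- sum(x$grade > 0L, na.rm = TRUE)
  cat(sprintf("coarse TPM map %s (%s CCL): %d cancer voxel(s), %d sampled\n",
              paste(dim(x$grade), collapse = " x "), x$ccl_mode,
              n_cancer, sum(!is.na(x$grade))))
  invisible(x)
}

#' Crop a coarse map to its cancer bounding box
#'
#' Restricts the map to the cancer-bearing template sites plus a benign margin
#' (whole sites laterally, whole millimetres in z), recording the crop origin
#' so downstream coordinates stay in global millimetres. Reconstruction output
#' is unaffected away from the (all-but-zero) crop boundary; this exists so
#' that the 0.5 mm reconstruction does not allocate the full 65 x 65 x 40 mm
#' field for a 10 mm lesion.
#'
#' @param map A `coarse_map`.
#' @param margin_sites Benign margin in template sites (default 1).
#' @param margin_z Benign margin in coarse z voxels (default 3).
#' @return A `coarse_map` with reduced dimensions and a non-zero `origin`,
#'   or the input unchanged when it contains no cancer.
#' @export
crop_coarse_map <- function(map, margin_sites = 1L, margin_z = 3L) {
  idx <- which(map$grade > 0L, arr.ind = TRUE)
  if (!nrow(idx)) return(map)
  d <- dim(map$grade)
  rng <- function(v, m, n) c(max(1L, min(v) - m), min(n, max(v) + m))
  rx <- rng(idx[, 1L], margin_sites, d[1L])
  ry <- rng(idx[, 2L], margin_sites, d[2L])
  rz <- rng(idx[, 3L], margin_z, d[3L])
  map$grade <- map$grade[rx[1L]:rx[2L], ry[1L]:ry[2L], rz[1L]:rz[2L],
                         drop = FALSE]
  map$origin <- map$origin + c(rx[1L], ry[1L], rz[1L]) - 1L
  map
}

# physical mm coordinates of coarse voxel centres of a (possibly cropped) map
coarse_centers <- function(map) {
  d <- dim(map$grade); g <- map$grid
  list(x = (map$origin[1L] + seq_len(d[1L]) - 0.5) * g$spacing,
       y = (map$origin[2L] + seq_len(d[2L]) - 0.5) * g$spacing,
       z = (map$origin[3L] + seq_len(d[3L]) - 0.5) * g$coarse_z_res)
}
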