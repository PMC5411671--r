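# ---- virtual cranio-caudal needle simulation ------------------------------

#' Simulate one virtual biopsy needle through the reconstructed map
#'
#' Walks the cranio-caudal (z) column of fine voxels at a sampling-plane
#' coordinate and measures, for one lesion: the cancer core length
#' (`ccl` = number of lesion voxels x 0.5 mm), the highest Gleason pattern on
#' the track (`max_grade`), the z midpoint of the cancer run(s) (`ccl_z`) and
#' the z centroid of the voxels attaining the maximum grade (`grade_z`), all
#' in global millimetres.
#'
#' @param fine A `fine_map` from [reconstruct_fine()].
#' @param ix,iy 1-based fine column indices on the sampling plane.
#' @param lesion_id Lesion id in `fine$lesion_id`.
#' @return A one-row tibble (`x`, `y` in mm, `ccl`, `max_grade`, `ccl_z`,
#'   `grade_z`); `max_grade` and the z summaries are `NA` when the track
#'   misses the lesion.
#' @export
simulate_needle <- function(fine, ix, iy, lesion_id) {
  check_lesion_id(fine, lesion_id)
  col_id <- fine$lesion_id[ix, iy, ]
  col_lab <- fine$label[ix, iy, ]
  on <- col_id == lesion_id
  n <- sum(on)
  x <- fine$centers$x[ix]; y <- fine$centers$y[iy]
  if (n == 0L) {
    return(tibble::tibble(x = x, y = y, ccl = 0, max_grade = NA_integer_,
                          ccl_z = NA_real_, grade_z = NA_real_))
  }
  z <- fine$centers$z
  mg <- max(col_lab[on])
  tibble::tibble(
    x = x, y = y, ccl = n * fine$res,
    max_grade = as.integer(mg),
    ccl_z = (min(z[on]) + max(z[on])) / 2,
    grade_z = mean(z[on & col_lab == mg]))
}

check_lesion_id <- function(fine, lesion_id) {
  if (is.null(fine$lesion_id)) stop("fine map has no lesion ids")
  n <- if (!is.null(fine$lesions)) fine$lesions$n_lesions else max(fine$lesion_id)
  if (lesion_id < 1L || lesion_id > n) stop("unknown lesion id ", lesion_id)
  invisible(TRUE)
}

# per-column summaries for one lesion over the whole sampling plane:
# counts (matrix), max grade (matrix), computed vectorised over columns
column_profiles <- function(fine, lesion_id) {
  d <- dim(fine$lesion_id)
  mask <- fine$lesion_id == lesion_id
  m <- matrix(mask, d[1L] * d[2L], d[3L])
  counts <- matrix(rowSums(m), d[1L], d[2L])
  labm <- matrix(fine$label * mask, d[1L] * d[2L], d[3L])
  gmax <- matrix(do.call(pmax, asplit(labm, 2L)), d[1L], d[2L])
  list(counts = counts, gmax = gmax)
}

#' Locate the volume and Gleason grade hotspots of a lesion
#'
#' The volume hotspot set contains every sampling-plane coordinate whose
#' cranio-caudal needle returns the lesion's longest CCL; the Gleason grade
#' hotspot set contains every coordinate whose needle captures the lesion's
#' highest Gleason pattern, independent of CCL. The search runs on the 0.5 mm
#' fine sampling plane. Each coordinate carries its representative z: the
#' cancer-run midpoint (`ccl_z`) for volume hotspots, the max-grade voxel
#' centroid (`grade_z`) for grade hotspots.
#'
#' @param fine A `fine_map` from [reconstruct_fine()].
#' @param lesion_id Lesion id.
#' @return A list with tibbles `volume` (`ix`, `iy`, `x`, `y`, `z`, `ccl`) and
#'   `grade` (`ix`, `iy`, `x`, `y`, `z`, `max_grade`), plus `max_ccl` (mm) and
#'   `max_grade`.
#' @export
find_hotspots <- function(fine, lesion_id) {
  check_lesion_id(fine, lesion_id)
  prof <- column_profiles(fine, lesion_id)
  if (!any(prof$counts > 0L))
    stop("lesion ", lesion_id, " has no fine voxels")
  max_ccl <- max(prof$counts) * fine$res
  max_grade <- max(prof$gmax)
  vol_idx <- which(prof$counts == max(prof$counts), arr.ind = TRUE)
  grd_idx <- which(prof$counts > 0L & prof$gmax == max_grade, arr.ind = TRUE)
  zsum <- function(idx, what) {
    vapply(seq_len(nrow(idx)), function(r) {
      p <- simulate_needle(fine, idx[r, 1L], idx[r, 2L], lesion_id)
      p[[what]]
    }, 0)
  }
  volume <- tibble::tibble(
    ix = vol_idx[, 1L], iy = vol_idx[, 2L],
    x = fine$centers$x[vol_idx[, 1L]], y = fine$centers$y[vol_idx[, 2L]],
    z = zsum(vol_idx, "ccl_z"), ccl = max_ccl)
  grade <- tibble::tibble(
    ix = grd_idx[, 1L], iy = grd_idx[, 2L],
    x = fine$centers$x[grd_idx[, 1L]], y = fine$centers$y[grd_idx[, 2L]],
    z = zsum(grd_idx, "grade_z"), max_grade = max_grade)
  list(volume = volume, grade = grade, max_ccl = max_ccl,
       max_grade = as.integer(max_grade))
}

#' Concordance of the two hotspots and their 3-D distance
#'
#' The hotspots are concordant when the two sampling-plane coordinate sets
#' intersect: a needle deployed at a maximum-CCL coordinate then also captures
#' the maximum grade. For discordant hotspots a 3-D distance is computed
#' between the (x, y, z) points of the two sets, where each volume point uses
#' its cancer-run midpoint as z and each grade point its max-grade centroid.
#' Two conventions are available: `"centroid"` (default) takes the Euclidean
#' distance between the two sets' mean points, which recovers the offset of a
#' planted high-grade focus from the lesion centre; `"nearest"` takes the
#' minimal pairwise distance (a lower bound, shrunk by the extent of the two
#' sets).
#'
#' @param volume,grade Hotspot tibbles from [find_hotspots()] (non-empty).
#' @param method `"centroid"` or `"nearest"`.
#' @return A list with `concordant` (logical) and `distance` (mm; `NA` when
#'   concordant).
#' @export
#' @examples
#' v <- tibble::tibble(ix = 20, iy = 20, x = 10, y = 10, z = 12)
#' g <- tibble::tibble(ix = 20, iy = 32, x = 10, y = 16, z = 12)
#' assess_concordance(v, g)$distance  # 6
assess_concordance <- function(volume, grade, method = c("centroid", "nearest")) {
  method <- match.arg(method)
  if (!nrow(volume) || !nrow(grade)) stop("empty hotspot set")
  inter <- any(paste(volume$ix, volume$iy) %in% paste(grade$ix, grade$iy))
  if (inter) return(list(concordant = TRUE, distance = NA_real_))
  if (method == "centroid") {
    p <- c(mean(volume$x), mean(volume$y), mean(volume$z))
    q <- c(mean(grade$x), mean(grade$y), mean(grade$z))
    d <- sqrt(sum((p - q)^2))
  } else {
    D <- outer(volume$x, grade$x, "-")^2 + outer(volume$y, grade$y, "-")^2 +
         outer(volume$z, grade$z, "-")^2
    d <- sqrt(min(D))
  }
  list(concordant = FALSE, distance = d)
}

# ---- per-lesion reports ----------------------------------------------------

#' Per-lesion report for one reconstructed patient map
#'
#' Combines lesion volume (coarse blocks x 0.025 ml), Gleason composition
#' (set of pair codes painted on the lesion's coarse voxels), lesion score
#' (highest pair present), heterogeneity under both criteria, the two
#' hotspots, and hotspot concordance with 3-D distance when discordant.
#' Homogeneous lesions are inherently concordant (their only grade is
#' everywhere), and the hotspot search confirms this.
#'
#' @param map A `coarse_map` for one patient.
#' @param lesions Its `lesion_map`.
#' @param fine Its reconstructed `fine_map`.
#' @param grid A [grid_spec()].
#' @param distance_method Passed to [assess_concordance()].
#' @return A tibble with one row per lesion: `lesion_id`, `n_blocks`,
#'   `volume_ml`, `composition` (list of pair codes), `score` (pair code of
#'   the highest score present), `het_grades`, `het_score`, hotspot
#'   coordinates (`vol_x`, `vol_y`, `vol_z`, `max_ccl`, `grd_x`, `grd_y`,
#'   `grd_z`, `max_grade`), `concordant`, `distance_mm`.
#' @export
lesion_reports <- function(map, lesions, fine, grid = grid_spec(),
                           distance_method = "centroid") {
  n <- lesions$n_lesions
  rows <- lapply(seq_len(n), function(id) {
    vox <- lesions$voxels[[id]]
    comp <- sort(unique(map$grade[vox]))
    hs <- find_hotspots(fine, id)
    conc <- assess_concordance(hs$volume, hs$grade, method = distance_method)
    tibble::tibble(
      lesion_id = id,
      n_blocks = nrow(vox),
      volume_ml = lesion_volume(lesions, id, grid),
      composition = list(comp),
      score = gleason_max(comp),
      het_grades = classify_heterogeneity(comp, "grades"),
      het_score = classify_heterogeneity(comp, "score"),
      vol_x = mean(hs$volume$x), vol_y = mean(hs$volume$y),
      vol_z = mean(hs$volume$z), max_ccl = hs$max_ccl,
      grd_x = mean(hs$grade$x), grd_y = mean(hs$grade$y),
      grd_z = mean(hs$grade$z), max_grade = hs$max_grade,
      concordant = conc$concordant,
      distance_mm = conc$distance)
  })
  dplyr::bind_rows(rows)
}
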