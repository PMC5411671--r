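#' Analyse one patient's cores under one CCL counting rule
#'
#' Runs the whole reconstruction chain: coarse map painting, cropping to the
#' cancer bounding box, 26-connectivity lesion delineation, fine
#' reconstruction with tuned grid-site-preserving smoothing, virtual-needle
#' hotspot search, and the per-lesion report.
#'
#' @param records `tpm_cores` tibble for one patient.
#' @param grid A [grid_spec()].
#' @param ccl_mode `"separate"` or `"cumulative"`.
#' @param distance_method Hotspot distance convention, see
#'   [assess_concordance()].
#' @param tol,sigma_max Smoothing tuning parameters, see [tune_sigma()].
#' @return A list with `map` (cropped `coarse_map`), `lesions`, `fine`,
#'   `sigma`, and `reports` (tibble from [lesion_reports()] with `patient_id`
#'   and `ccl_mode` columns).
#' @export
analyze_patient <- function(records, grid = grid_spec(),
                            ccl_mode = c("separate", "cumulative"),
                            distance_method = "centroid",
                            tol = 0.02, sigma_max = 5) {
  ccl_mode <- match.arg(ccl_mode)
  pid <- unique(records$patient_id)
  if (length(pid) != 1L) stop("analyze_patient expects one patient")
  map <- crop_coarse_map(build_coarse_map(records, grid, ccl_mode))
  lesions <- label_lesions(map)
  if (lesions$n_lesions == 0L) {
    return(list(map = map, lesions = lesions, fine = NULL, sigma = NA_real_,
                reports = empty_reports(pid, ccl_mode)))
  }
  fine <- reconstruct_fine(map, lesions, tol = tol, sigma_max = sigma_max)
  reports <- lesion_reports(map, lesions, fine, grid,
                            distance_method = distance_method)
  reports <- dplyr::mutate(reports, patient_id = pid, ccl_mode = ccl_mode,
                           sigma = fine$sigma, .before = 1L)
  list(map = map, lesions = lesions, fine = fine, sigma = fine$sigma,
       reports = reports)
}

empty_reports <- function(pid = character(0), ccl_mode = character(0)) {
  tibble::tibble(patient_id = pid[0], ccl_mode = character(0),
                 sigma = numeric(0), lesion_id = integer(0),
                 n_blocks = integer(0), volume_ml = numeric(0),
                 composition = list(), score = integer(0),
                 het_grades = logical(0), het_score = logical(0),
                 vol_x = numeric(0), vol_y = numeric(0), vol_z = numeric(0),
                 max_ccl = numeric(0), grd_x = numeric(0), grd_y = numeric(0),
                 grd_z = numeric(0), max_grade = integer(0),
                 concordant = logical(0), distance_mm = numeric(0))
}

#' Analyse a cohort of TPM core tables
#'
#' Applies [analyze_patient()] to every patient under the requested CCL
#' counting rules and stacks the per-lesion reports. Lesion delineation (and
#' therefore the lesion count) depends only on the CCL rule; the two
#' heterogeneity criteria are applied afterwards by [summarize_cohort()].
#'
#' @param cores `tpm_cores` tibble (any number of patients), or a
#'   `tpm_cohort` from [make_cohort()].
#' @param grid A [grid_spec()].
#' @param ccl_modes Character vector of counting rules to run.
#' @param progress Print one line per patient.
#' @inheritParams analyze_patient
#' @return A tibble of lesion reports across patients and modes.
#' @export
analyze_cohort <- function(cores, grid = grid_spec(),
                           ccl_modes = c("separate", "cumulative"),
                           distance_method = "centroid",
                           tol = 0.02, sigma_max = 5, progress = FALSE) {
  if (inherits(cores, "tpm_cohort")) {
    grid <- cores$grid
    cores <- cores$cores
  }
  out <- list()
  for (pid in unique(cores$patient_id)) {
    sub <- cores[cores$patient_id == pid, ]
    class(sub) <- unique(c("tpm_cores", class(sub)))
    for (mode in ccl_modes) {
      res <- analyze_patient(sub, grid, mode, distance_method, tol, sigma_max)
      out[[length(out) + 1L]] <- res$reports
      if (progress)
        message(sprintf("%s [%s]: %d lesion(s), sigma %.2f mm", pid, mode,
                        res$lesions$n_lesions,
                        ifelse(is.na(res$sigma), 0, res$sigma)))
    }
  }
  reports <- dplyr::bind_rows(out)
  if (!nrow(reports)) empty_reports() else reports
}

#' Export a coarse or lesion map as NIfTI
#'
#' Writes the label array on the 1 x 1 x 1 index grid with the physical
#' voxel spacing (5, 5, 1 mm coarse; 0.5 mm isotropic fine) in the header,
#' plus a JSON sidecar with the label dictionary (and tuned sigma for fine
#' maps). Requires the RNifti package.
#'
#' @param x A `coarse_map`, `lesion_map` label array combination, or
#'   `fine_map`.
#' @param path Output `.nii` path; the sidecar replaces the extension with
#'   `.json`.
#' @export
write_map_nifti <- function(x, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("NIfTI export needs the RNifti package")
  if (inherits(x, "coarse_map")) {
    arr <- x$grade
    arr[is.na(arr)] <- -1L
    pix <- c(x$grid$spacing, x$grid$spacing, x$grid$coarse_z_res)
    side <- list(labels = list(no_tissue = -1, benign = 0,
                               gleason_pair = "10*primary + secondary"),
                 ccl_mode = x$ccl_mode, origin_voxel = x$origin)
  } else if (inherits(x, "fine_map")) {
    arr <- x$label
    pix <- rep(x$res, 3L)
    side <- list(labels = list(benign = 0, pattern = "3|4|5"),
                 sigma_mm = x$sigma, origin_voxel = x$origin)
  } else stop("unsupported object")
  img <- RNifti::asNifti(arr * 1)
  RNifti::pixdim(img) <- pix
  RNifti::writeNifti(img, path)
  jsonlite::write_json(side, sub("\\.nii(\\.gz)?$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
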