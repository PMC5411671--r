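#' Core-level TPM pathology records
#'
#' A cohort of TPM biopsy cores is held as a tibble of class `tpm_cores` with
#' one row per core:
#' \describe{
#'   \item{patient_id}{opaque string}
#'   \item{grid_x, grid_y}{0-based template coordinates (columns A-M map to
#'     x = 0..12, rows 1-13 to y = 0..12)}
#'   \item{depth_slot}{`"apex"` or `"base"`}
#'   \item{core_length}{mm, in (0, 20\]}
#'   \item{foci}{list-column; each element a data frame with one row per cancer
#'     focus: `offset` (mm from the apical, India-ink stained end of the core),
#'     `length` (mm), `primary`, `secondary`, `tertiary` Gleason patterns
#'     (`tertiary` may be `NA`). Foci are sorted by offset and non-overlapping,
#'     and must fit inside the core.}
#' }
#'
#' @param patient_id,grid_x,grid_y,depth_slot,core_length Per-core fields
#'   (recycled to a common length).
#' @param foci List of focus data frames (or `NULL` entries for benign cores).
#' @param grid A [grid_spec()].
#' @return A validated `tpm_cores` tibble.
#' @export
#' @examples
#' core_records("P01", 3, 6, "apex", 18,
#'              foci = list(data.frame(offset = 2, length = 3,
#'                                     primary = 3, secondary = 3)))
core_records <- function(patient_id, grid_x, grid_y, depth_slot, core_length,
                         foci = NULL, grid = grid_spec()) {
  n <- max(length(patient_id), length(grid_x), length(grid_y),
           length(depth_slot), length(core_length))
  if (is.null(foci)) foci <- rep(list(NULL), n)
  records <- tibble::tibble(
    patient_id = rep_len(as.character(patient_id), n),
    grid_x = rep_len(as.integer(grid_x), n),
    grid_y = rep_len(as.integer(grid_y), n),
    depth_slot = rep_len(as.character(depth_slot), n),
    core_length = rep_len(as.numeric(core_length), n),
    foci = lapply(foci, normalize_foci)
  )
  validate_cores(records, grid)
}

normalize_foci <- function(f) {
  cols <- c("offset", "length", "primary", "secondary", "tertiary")
  if (is.null(f) || !nrow(as.data.frame(f))) {
    out <- data.frame(offset = numeric(0), length = numeric(0),
                      primary = integer(0), secondary = integer(0),
                      tertiary = integer(0))
    return(out)
  }
  f <- as.data.frame(f)
  if (!"tertiary" %in% names(f)) f$tertiary <- NA_integer_
  missing <- setdiff(cols, names(f))
  if (length(missing))
    stop("focus table lacks columns: ", paste(missing, collapse = ", "))
  f <- f[order(f$offset), cols, drop = FALSE]
  f$offset <- as.numeric(f$offset); f$length <- as.numeric(f$length)
  f$primary <- as.integer(f$primary); f$secondary <- as.integer(f$secondary)
  f$tertiary <- as.integer(f$tertiary)
  rownames(f) <- NULL
  f
}

#' Validate TPM core records against the grid geometry
#'
#' Checks coordinates against the template, core lengths against the needle,
#' per-patient coordinate uniqueness, and per-core focus geometry (foci sorted,
#' non-overlapping, inside the core, patterns in \{3,4,5\}).
#'
#' @param records A `tpm_cores` tibble (or plain tibble with the same columns).
#' @param grid A [grid_spec()].
#' @return The records, invisibly classed as `tpm_cores`.
#' @export
validate_cores <- function(records, grid = grid_spec()) {
  req <- c("patient_id", "grid_x", "grid_y", "depth_slot", "core_length", "foci")
  missing <- setdiff(req, names(records))
  if (length(missing))
    stop("core table lacks columns: ", paste(missing, collapse = ", "))
  bad_x <- records$grid_x < 0L | records$grid_x >= grid$nx
  bad_y <- records$grid_y < 0L | records$grid_y >= grid$ny
  if (any(bad_x | bad_y))
    stop("coordinate outside the ", grid$nx, "x", grid$ny, " grid in row(s) ",
         paste(which(bad_x | bad_y), collapse = ", "))
  if (!all(records$depth_slot %in% c("apex", "base")))
    stop("depth_slot must be 'apex' or 'base'")
  if (any(records$core_length <= 0 | records$core_length > grid$needle_length))
    stop("core_length must lie in (0, ", grid$needle_length, "] mm")
  key <- paste(records$patient_id, records$grid_x, records$grid_y,
               records$depth_slot)
  if (anyDuplicated(key))
    stop("duplicate (patient, x, y, depth) coordinate in row(s) ",
         paste(which(duplicated(key)), collapse = ", "))
  for (i in seq_len(nrow(records))) {
    f <- records$foci[[i]]
    if (!nrow(f)) next
    if (any(f$length <= 0) || any(f$offset < 0))
      stop("row ", i, ": focus offsets must be >= 0 and lengths > 0")
    if (any(f$offset + f$length > records$core_length[i] + 1e-9))
      stop("row ", i, ": focus extends beyond the ",
           records$core_length[i], " mm core")
    if (nrow(f) > 1 && any(f$offset[-1] < (f$offset + f$length)[-nrow(f)] - 1e-9))
      stop("row ", i, ": overlapping cancer foci")
    if (any(!f$primary %in% 3:5) || any(!f$secondary %in% 3:5) ||
        any(!is.na(f$tertiary) & !f$tertiary %in% 3:5))
      stop("row ", i, ": Gleason patterns must be in {3, 4, 5}")
  }
  class(records) <- unique(c("tpm_cores", class(records)))
  invisible(records)
}

max_foci <- function(records) {
  if (!nrow(records)) return(0L)
  max(vapply(records$foci, nrow, 0L))
}

#' Read / write a TPM core table
#'
#' The CSV schema is the package's own serialisation of the per-core pathology
#' report: one row per core with columns `patient_id`, `grid_col` (letter A-M),
#' `grid_row` (number 1-13), `depth_slot` (apex|base), `core_length`, followed
#' by repeated focus groups `focus<k>_offset`, `focus<k>_length`,
#' `focus<k>_primary`, `focus<k>_secondary`, `focus<k>_tertiary`. Benign cores
#' leave all focus columns empty. `read_core_table(write_core_table(x))` is
#' lossless for valid records.
#'
#' @param path CSV file path.
#' @param grid A [grid_spec()].
#' @return A validated `tpm_cores` tibble.
#' @export
read_core_table <- function(path, grid = grid_spec()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  base_cols <- c("patient_id", "grid_col", "grid_row", "depth_slot", "core_length")
  missing <- setdiff(base_cols, names(raw))
  if (length(missing))
    stop("malformed core table ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  if (!nrow(raw)) {
    return(core_records(character(0), integer(0), integer(0),
                        character(0), numeric(0), grid = grid))
  }
  grid_row <- suppressWarnings(as.integer(raw$grid_row))
  if (anyNA(grid_row) || any(grid_row < 1L | grid_row > grid$ny))
    stop("grid_row outside 1..", grid$ny, " in row(s) ",
         paste(which(is.na(grid_row) | grid_row < 1L | grid_row > grid$ny),
               collapse = ", "))
  ks <- sort(unique(as.integer(sub("^focus(\\d+)_.*$", "\\1",
                                   grep("^focus\\d+_", names(raw), value = TRUE)))))
  foci <- lapply(seq_len(nrow(raw)), function(i) {
    rows <- lapply(ks, function(k) {
      off <- raw[[paste0("focus", k, "_offset")]][i]
      if (is.na(off) || (is.character(off) && !nzchar(trimws(off)))) return(NULL)
      num <- function(col) {
        v <- raw[[paste0("focus", k, "_", col)]][i]
        v <- suppressWarnings(as.numeric(v))
        if (is.na(v) && col != "tertiary")
          stop("malformed row ", i, ": focus", k, "_", col)
        v
      }
      data.frame(offset = num("offset"), length = num("length"),
                 primary = num("primary"), secondary = num("secondary"),
                 tertiary = num("tertiary"))
    })
    do.call(rbind, rows)
  })
  core_records(raw$patient_id,
               grid_letter_to_index(raw$grid_col, grid),
               grid_row - 1L,
               raw$depth_slot,
               as.numeric(raw$core_length),
               foci = foci, grid = grid)
}

#' @param records A validated `tpm_cores` tibble.
#' @rdname read_core_table
#' @export
write_core_table <- function(records, path, grid = grid_spec()) {
  records <- validate_cores(records, grid)
  k <- max_foci(records)
  out <- data.frame(
    patient_id = records$patient_id,
    grid_col = if (nrow(records)) grid_index_to_letter(records$grid_x, grid) else character(0),
    grid_row = records$grid_y + 1L,
    depth_slot = records$depth_slot,
    core_length = records$core_length,
    check.names = FALSE
  )
  for (j in seq_len(k)) {
    for (col in c("offset", "length", "primary", "secondary", "tertiary")) {
      out[[paste0("focus", j, "_", col)]] <- vapply(records$foci, function(f) {
        if (nrow(f) >= j) as.numeric(f[[col]][j]) else NA_real_
      }, 0)
    }
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Clinical risk class of one core
#'
#' Applies the UCL definitions of clinical significance used to colour-code
#' TPM visual reports: definition 1 (red) is maximum cancer core length
#' (MCCL) >= 6 mm and/or Gleason score >= 4+3; definition 2 (yellow) is
#' MCCL >= 4 mm and/or Gleason score >= 3+4; insignificant disease (green) is
#' MCCL < 4 mm and Gleason score <= 3+3; cores without cancer are `no_cancer`
#' (white). Definition 1 takes precedence over definition 2. CCLs are reported
#' in integer millimetres clinically, so "MCCL <= 3 mm" and "MCCL < 4 mm"
#' coincide there; the latter keeps the classification total and monotone on
#' fractional lengths.
#'
#' @param mccl Cancer core length(s) in mm, >= 0.
#' @param best_score Gleason pair code(s) (the core's highest score among its
#'   foci); `NA` allowed when `mccl` is 0.
#' @return Factor with ordered levels
#'   `no_cancer < insignificant < definition2 < definition1`.
#' @export
#' @examples
#' classify_core_risk(6, gleason_pair(3, 3))  # definition1
#' classify_core_risk(3, gleason_pair(3, 3))  # insignificant
classify_core_risk <- function(mccl, best_score) {
  n <- max(length(mccl), length(best_score))
  mccl <- rep_len(as.numeric(mccl), n)
  best_score <- rep_len(as.integer(best_score), n)
  if (any(mccl < 0)) stop("negative MCCL")
  if (any(mccl > 0 & is.na(best_score)))
    stop("cores with cancer need a Gleason score")
  rank <- ifelse(is.na(best_score), -Inf, gleason_rank(best_score))
  out <- ifelse(mccl == 0, "no_cancer",
         ifelse(mccl >= 6 | rank >= gleason_rank(43L), "definition1",
         ifelse(mccl >= 4 | rank >= gleason_rank(34L), "definition2",
                "insignificant")))
  factor(out, levels = c("no_cancer", "insignificant", "definition2",
                         "definition1"), ordered = TRUE)
}

risk_colors <- c(no_cancer = "white", insignificant = "#2ca02c",
                 definition2 = "#ffd92f", definition1 = "#d62728")

#' Render the colour-coded TPM visual report for one patient
#'
#' Reproduces the per-patient visual map: one 13 x 13 grid per depth slot,
#' each sampled cell coloured by its UCL risk class (red definition 1, yellow
#' definition 2, green insignificant, white no cancer) and annotated with the
#' core's cancer core length in mm. Unsampled template holes are blank.
#' Risk is derived from the core's separate-count CCL and its highest Gleason
#' score across foci.
#'
#' @param records A `tpm_cores` tibble for a single patient.
#' @param grid A [grid_spec()].
#' @return A list with `plot` (a ggplot object) and `cells` (a tibble with one
#'   row per sampled cell: coordinates, `ccl`, `risk`).
#' @export
render_visual_map <- function(records, grid = grid_spec()) {
  records <- validate_cores(records, grid)
  if (length(unique(records$patient_id)) > 1L)
    stop("visual map expects records from one patient")
  ccl <- vapply(records$foci, function(f) sum(f$length), 0)
  best <- vapply(records$foci, function(f) {
    if (!nrow(f)) NA_integer_ else gleason_max(gleason_pair(f$primary, f$secondary))
  }, 0L)
  cells <- tibble::tibble(
    patient_id = records$patient_id,
    depth_slot = records$depth_slot,
    grid_x = records$grid_x, grid_y = records$grid_y,
    grid_col = grid_index_to_letter(records$grid_x, grid),
    grid_row = records$grid_y + 1L,
    ccl = ccl,
    best_score = ifelse(is.na(best), NA_character_, gleason_label(best)),
    risk = classify_core_risk(ccl, best)
  )
  p <- ggplot2::ggplot(cells, ggplot2::aes(x = .data$grid_x, y = .data$grid_y)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$risk), colour = "grey40") +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(.data$ccl > 0,
                                                   format(.data$ccl), "")),
                       size = 2.6) +
    ggplot2::scale_fill_manual(values = risk_colors, drop = FALSE) +
    ggplot2::scale_x_continuous(breaks = 0:(grid$nx - 1L),
                                labels = LETTERS[seq_len(grid$nx)],
                                expand = c(0, 0), limits = c(-0.5, grid$nx - 0.5)) +
    ggplot2::scale_y_continuous(breaks = 0:(grid$ny - 1L),
                                labels = seq_len(grid$ny),
                                expand = c(0, 0), limits = c(-0.5, grid$ny - 0.5)) +
    ggplot2::facet_wrap(~depth_slot) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "risk",
                  title = unique(cells$patient_id)) +
    ggplot2::theme_minimal()
  list(plot = p, cells = cells)
}

#' Save a visual map as PNG plus a machine-readable JSON grid
#'
#' @param vm Result of [render_visual_map()].
#' @param png_path,json_path Output paths (either may be `NULL` to skip).
#' @export
save_visual_map <- function(vm, png_path = NULL, json_path = NULL) {
  if (!is.null(png_path))
    ggplot2::ggsave(png_path, vm$plot, width = 8, height = 4.5, dpi = 150)
  if (!is.null(json_path)) {
    cells <- vm$cells
    cells$risk <- as.character(cells$risk)
    jsonlite::write_json(cells, json_path, dataframe = "rows", auto_unbox = TRUE,
                         na = "null", digits = NA)
  }
  invisible(NULL)
}
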