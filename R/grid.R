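#' Template grid geometry
#'
#' Describes the brachytherapy template used for transperineal mapping (TPM)
#' biopsy: a 13 x 13 grid of holes at 5 mm pitch, each hole sampled with two
#' stacked 20 mm needles (apex and base), giving a 40 mm cranio-caudal extent.
#' The coarse pathology map has one voxel per (hole, mm of core): 13 x 13 x 40
#' voxels of 5 x 5 x 1 mm. The reconstructed fine map is 0.5 mm isotropic,
#' i.e. 130 x 130 x 80 voxels over the same 65 x 65 x 40 mm field.
#'
#' The z axis runs cranio-caudally with its origin at the apical end of the
#' apex needle (the India-ink stained core end), so the apex needle covers
#' z in \[0, 20) mm and the base needle z in \[20, 40) mm.
#'
#' @param nx,ny Number of grid columns/rows (default 13 x 13).
#' @param spacing Lateral grid pitch in mm (default 5).
#' @param needle_length Length of one needle in mm (default 20).
#' @param depth_slots Number of stacked needles per hole (default 2: apex, base).
#' @param coarse_z_res Coarse z section thickness in mm (default 1).
#' @param fine_res Fine isotropic voxel edge in mm (default 0.5).
#'
#' @return An object of class `grid_spec`: a list with the arguments plus the
#'   derived dimensions `coarse_dim` (13, 13, 40), `fine_dim` (130, 130, 80),
#'   the total z extent `z_extent` (40 mm) and lateral field size `field`
#'   (65 mm).
#' @export
#' @examples
#' g <- grid_spec()
#' g$coarse_dim
#' g$fine_dim
grid_spec <- function(nx = 13L, ny = 13L, spacing = 5, needle_length = 20,
                      depth_slots = 2L, coarse_z_res = 1, fine_res = 0.5) {
  stopifnot(nx >= 1, ny >= 1, spacing > 0, needle_length > 0,
            depth_slots >= 1, coarse_z_res > 0, fine_res > 0)
  z_extent <- depth_slots * needle_length
  nz <- z_extent / coarse_z_res
  if (abs(nz - round(nz)) > 1e-9)
    stop("needle geometry does not tile the coarse z resolution")
  fine_nx <- nx * spacing / fine_res
  fine_nz <- z_extent / fine_res
  if (abs(fine_nx - round(fine_nx)) > 1e-9 || abs(fine_nz - round(fine_nz)) > 1e-9)
    stop("fine resolution does not tile the field")
  structure(list(
    nx = as.integer(nx), ny = as.integer(ny), spacing = spacing,
    needle_length = needle_length, depth_slots = as.integer(depth_slots),
    coarse_z_res = coarse_z_res, fine_res = fine_res,
    coarse_dim = c(as.integer(nx), as.integer(ny), as.integer(round(nz))),
    fine_dim = c(as.integer(round(fine_nx)),
                 as.integer(round(ny * spacing / fine_res)),
                 as.integer(round(fine_nz))),
    z_extent = z_extent,
    field = c(nx * spacing, ny * spacing)
  ), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("TPM grid: %d x %d holes at %g mm pitch, %d x %g mm needles\n",
              x$nx, x$ny, x$spacing, x$depth_slots, x$needle_length))
  cat(sprintf("coarse map %s (%g x %g x %g mm voxels), fine map %s (%g mm)\n",
              paste(x$coarse_dim, collapse = " x "),
              x$spacing, x$spacing, x$coarse_z_res,
              paste(x$fine_dim, collapse = " x "), x$fine_res))
  invisible(x)
}

# physical x (mm) of the centre of coarse grid column ix (0-based); same for y
site_center <- function(ix, grid) (ix + 0.5) * grid$spacing

# physical z (mm) of the centre of coarse z voxel iz (0-based)
coarse_z_center <- function(iz, grid) (iz + 0.5) * grid$coarse_z_res

#' Convert between grid letters and 0-based column indices
#'
#' Template columns are labelled A-M in pathology reports; rows 1-13.
#' Letters map left-to-right to x = 0..12 and numbers to y = 0..12.
#'
#' @param x Character vector of single letters (for `grid_letter_to_index`) or
#'   integer indices (for `grid_index_to_letter`).
#' @param grid A `grid_spec`.
#' @return Integer 0-based indices, or single letters.
#' @export
grid_letter_to_index <- function(x, grid = grid_spec()) {
  idx <- match(toupper(trimws(x)), LETTERS[seq_len(grid$nx)])
  if (anyNA(idx))
    stop("grid column letter outside A-", LETTERS[grid$nx], ": ",
         paste(unique(x[is.na(idx)]), collapse = ", "))
  idx - 1L
}

#' @rdname grid_letter_to_index
#' @export
grid_index_to_letter <- function(x, grid = grid_spec()) {
  x <- as.integer(x)
  if (any(x < 0L | x >= grid$nx))
    stop("grid column index outside 0..", grid$nx - 1L)
  LETTERS[x + 1L]
}
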