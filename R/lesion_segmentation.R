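#' Delineate independent lesions by 26-connectivity
#'
#' Connected-component labelling of the cancer voxels of a coarse map under
#' the rule of 26 connectivity: every voxel is adjacent to the (up to) 26
#' voxels sharing a face, edge or corner with it in index space. Adjacency is
#' evaluated on the anisotropic 5 x 5 x 1 mm blocks as index neighbourhood,
#' not in physical millimetres. Gleason labels are ignored for connectivity: a
#' lesion may mix grades (heterogeneity is assessed downstream).
#'
#' Lesion ids are 1..n, assigned in ascending order of each component's
#' minimal (x, y, z) voxel (lexicographic), so the labelling is deterministic
#' and independent of record order.
#'
#' @param map A `coarse_map` (or a plain logical/numeric 3-D array, where
#'   `TRUE`/positive marks cancer).
#' @return An object of class `lesion_map`: list with `labels` (integer array,
#'   0 = background), `n_lesions`, and `voxels` (list of 1-based index
#'   matrices, one per lesion).
#' @export
#' @examples
#' a <- array(FALSE, c(3, 3, 3)); a[1, 1, 1] <- a[2, 2, 2] <- TRUE
#' label_lesions(a)$n_lesions  # 1: corner contact joins
label_lesions <- function(map) {
  cancer <- if (inherits(map, "coarse_map")) {
    !is.na(map$grade) & map$grade > 0L
  } else {
    m <- as.array(map)
    !is.na(m) & m > 0
  }
  d <- dim(cancer)
  stopifnot(length(d) == 3L)
  labels <- array(0L, d)
  idx <- which(cancer)
  out <- structure(list(labels = labels, n_lesions = 0L, voxels = list()),
                   class = "lesion_map")
  if (!length(idx)) return(out)
  ijk <- arrayInd(idx, d)
  ord <- order(ijk[, 1L], ijk[, 2L], ijk[, 3L])
  idx <- idx[ord]; ijk <- ijk[ord, , drop = FALSE]
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0L, , drop = FALSE]
  next_id <- 0L
  voxels <- list()
  for (s in seq_along(idx)) {
    if (labels[idx[s]] != 0L) next
    next_id <- next_id + 1L
    comp <- idx[s]
    labels[idx[s]] <- next_id
    frontier <- ijk[s, , drop = FALSE]
    while (nrow(frontier)) {
      nb <- frontier[rep(seq_len(nrow(frontier)), each = nrow(off)), ,
                     drop = FALSE] +
        off[rep(seq_len(nrow(off)), times = nrow(frontier)), , drop = FALSE]
      ok <- nb[, 1L] >= 1L & nb[, 1L] <= d[1L] &
            nb[, 2L] >= 1L & nb[, 2L] <= d[2L] &
            nb[, 3L] >= 1L & nb[, 3L] <= d[3L]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1L] + (nb[, 2L] - 1L) * d[1L] + (nb[, 3L] - 1L) * d[1L] * d[2L]
      keep <- !duplicated(lin)
      lin <- lin[keep]; nb <- nb[keep, , drop = FALSE]
      new <- cancer[lin] & labels[lin] == 0L
      lin <- lin[new]
      if (!length(lin)) break
      labels[lin] <- next_id
      comp <- c(comp, lin)
      frontier <- nb[new, , drop = FALSE]
    }
    voxels[[next_id]] <- arrayInd(sort(comp), d)
  }
  structure(list(labels = labels, n_lesions = next_id, voxels = voxels),
            class = "lesion_map")
}

#' @export
print.lesion_map <- function(x, ...) {
  cat(sprintf("lesion map: %d lesion(s), sizes %s\n", x$n_lesions,
              paste(vapply(x$voxels, nrow, 0L), collapse = ", ")))
  invisible(x)
}

#' Lesion volume from coarse blocks
#'
#' One coarse block is 5 x 5 x 1 mm = 0.025 ml; lesion volume is the block
#' count times the block volume.
#'
#' @param lesions A `lesion_map`.
#' @param lesion_id Lesion id (1-based).
#' @param grid A [grid_spec()].
#' @return Volume in ml.
#' @export
#' @examples
#' a <- array(0, c(3, 3, 3)); a[1, 1, 1:3] <- 1
#' lesion_volume(label_lesions(a), 1)  # 0.075
lesion_volume <- function(lesions, lesion_id, grid = grid_spec()) {
  if (lesion_id < 1L || lesion_id > lesions$n_lesions)
    stop("unknown lesion id ", lesion_id)
  block_ml <- grid$spacing^2 * grid$coarse_z_res / 1000
  nrow(lesions$voxels[[lesion_id]]) * block_ml
}
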