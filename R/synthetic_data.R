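# ---- synthetic ground-truth prostates -------------------------------------

# run `code` under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Specify one synthetic lesion
#'
#' Lesions are axis-aligned ellipsoids of a uniform base Gleason score, read
#' as sub-voxel intermixture of the score's two patterns. A heterogeneous
#' lesion carries a planted spherical high-grade focus with its own Gleason
#' score; the focus must lie inside the ellipsoid. All coordinates are in
#' global millimetres (x, y in the 65 mm template plane, z cranio-caudal in
#' \[0, 40\]).
#'
#' @param center Numeric length 3, ellipsoid centre (mm).
#' @param radii Numeric length 3, semi-axes (mm), all > 0.
#' @param base_score Gleason pair code (e.g. `33`, `34`) of the bulk lesion.
#' @param focus Optional list with `center` (length 3, mm), `radius` (mm) and
#'   `score` (pair code) of the planted high-grade focus.
#' @param grid A [grid_spec()]; the ellipsoid must fit inside the field.
#' @return A `lesion_spec` list.
#' @export
lesion_spec <- function(center, radii, base_score = 33L, focus = NULL,
                        grid = grid_spec()) {
  stopifnot(length(center) == 3L, length(radii) == 3L, all(radii > 0))
  gleason_pair(gleason_primary(base_score), gleason_secondary(base_score))
  lim <- c(grid$field, grid$z_extent)
  if (any(center - radii < -1e-9) || any(center + radii > lim + 1e-9))
    stop("lesion extends outside the ", paste(lim, collapse = " x "), " mm field")
  if (!is.null(focus)) {
    stopifnot(length(focus$center) == 3L, focus$radius > 0)
    gleason_pair(gleason_primary(focus$score), gleason_secondary(focus$score))
    probes <- rbind(matrix(focus$center, 6L, 3L, byrow = TRUE) +
                      focus$radius * rbind(diag(3), -diag(3)))
    u <- sweep(sweep(probes, 2L, center), 2L, radii, "/")
    if (any(rowSums(u^2) > 1 + 1e-6))
      stop("planted focus does not fit inside the lesion ellipsoid")
  }
  structure(list(center = as.numeric(center), radii = as.numeric(radii),
                 base_score = as.integer(base_score), focus = focus),
            class = "lesion_spec")
}

inside_ellipsoid <- function(x, y, z, center, radii) {
  ((x - center[1L]) / radii[1L])^2 + ((y - center[2L]) / radii[2L])^2 +
    ((z - center[3L]) / radii[3L])^2 <= 1
}

#' Generate the fine ground-truth grade volume for one prostate
#'
#' Rasterises the lesion ellipsoids (and planted foci) onto the fine 0.5 mm
#' grid. Voxels carry Gleason pair codes (0 = benign); a pair voxel stands
#' for sub-voxel intermixture of its two patterns.
#'
#' @param lesions List of [lesion_spec()]s (may overlap the template grid
#'   anywhere inside the field; later lesions overwrite earlier ones where
#'   they overlap).
#' @param grid A [grid_spec()].
#' @return A list of class `truth_volume`: `volume` (fine-dim integer array of
#'   pair codes), `lesions` (the specs) and `meta` (tibble: per-lesion centre,
#'   radii, scores, focus geometry, planted lateral offset in mm, analytic
#'   ellipsoid volume in ml, and the z extent at the centre column
#'   `truth_max_ccl`).
#' @export
generate_truth_volume <- function(lesions, grid = grid_spec()) {
  if (inherits(lesions, "lesion_spec")) lesions <- list(lesions)
  d <- grid$fine_dim
  res <- grid$fine_res
  vol <- array(0L, d)
  xs <- (seq_len(d[1L]) - 0.5) * res
  ys <- (seq_len(d[2L]) - 0.5) * res
  zs <- (seq_len(d[3L]) - 0.5) * res
  for (ls in lesions) {
    rng <- function(ctr, rad, coords) which(coords >= ctr - rad - res &
                                            coords <= ctr + rad + res)
    ix <- rng(ls$center[1L], ls$radii[1L], xs)
    iy <- rng(ls$center[2L], ls$radii[2L], ys)
    iz <- rng(ls$center[3L], ls$radii[3L], zs)
    g <- expand.grid(x = xs[ix], y = ys[iy], z = zs[iz])
    inside <- inside_ellipsoid(g$x, g$y, g$z, ls$center, ls$radii)
    sub <- array(vol[ix, iy, iz], c(length(ix), length(iy), length(iz)))
    sub[inside] <- ls$base_score
    if (!is.null(ls$focus)) {
      inf <- inside_ellipsoid(g$x, g$y, g$z, ls$focus$center,
                              rep(ls$focus$radius, 3L))
      sub[inf] <- as.integer(ls$focus$score)
    }
    vol[ix, iy, iz] <- sub
  }
  meta <- dplyr::bind_rows(lapply(seq_along(lesions), function(i) {
    ls <- lesions[[i]]
    has_focus <- !is.null(ls$focus)
    offset <- if (has_focus)
      sqrt(sum((ls$focus$center[1:2] - ls$center[1:2])^2)) else 0
    tibble::tibble(
      lesion = i,
      center_x = ls$center[1L], center_y = ls$center[2L],
      center_z = ls$center[3L],
      a = ls$radii[1L], b = ls$radii[2L], c = ls$radii[3L],
      base_score = ls$base_score,
      has_focus = has_focus,
      focus_x = if (has_focus) ls$focus$center[1L] else NA_real_,
      focus_y = if (has_focus) ls$focus$center[2L] else NA_real_,
      focus_z = if (has_focus) ls$focus$center[3L] else NA_real_,
      focus_r = if (has_focus) ls$focus$radius else NA_real_,
      focus_score = if (has_focus) as.integer(ls$focus$score) else NA_integer_,
      offset_mm = offset,
      truth_concordant = !has_focus || offset <= ls$focus$radius,
      ellipsoid_ml = 4 / 3 * pi * prod(ls$radii) / 1000,
      truth_max_ccl = 2 * ls$radii[3L])
  }))
  structure(list(volume = vol, lesions = lesions, meta = meta, grid = grid),
            class = "truth_volume")
}

# Gleason pair codes along the needle track at template site (ix, iy)
# (0-based), evaluated analytically from the lesion specs at the fine z
# sample centres — the sampling replicates the template geometry exactly.
track_pairs <- function(lesions, ix, iy, grid) {
  x <- site_center(ix, grid); y <- site_center(iy, grid)
  zs <- (seq_len(grid$fine_dim[3L]) - 0.5) * grid$fine_res
  pairs <- integer(length(zs))
  for (ls in lesions) {
    inside <- inside_ellipsoid(x, y, zs, ls$center, ls$radii)
    pairs[inside] <- ls$base_score
    if (!is.null(ls$focus)) {
      inf <- inside_ellipsoid(x, y, zs, ls$focus$center,
                              rep(ls$focus$radius, 3L))
      pairs[inf] <- as.integer(ls$focus$score)
    }
  }
  pairs
}

#' Sample a ground-truth prostate on the 5 mm template grid
#'
#' Simulates the TPM procedure: at every template hole a 20 mm apex and a
#' 20 mm base core are taken along the cranio-caudal axis through the hole
#' centre, and each contiguous cancer run along the track becomes one
#' reported focus. The focus Gleason score is the length-weighted
#' recombination of the grades on the run (primary = most abundant pattern,
#' secondary = highest other pattern), the per-core convention of biopsy
#' reporting. With probability `discontinuity_prob` a core's longest focus
#' (>= 4 mm) is reported as two foci separated by a 1-3 mm benign gap,
#' emulating discontinuous cancer in the specimen.
#'
#' @param truth A `truth_volume` from [generate_truth_volume()].
#' @param grid A [grid_spec()].
#' @param discontinuity_prob Probability of splitting a core's cancer run.
#' @param seed Optional RNG seed (only the splitting is stochastic).
#' @param patient_id Patient id for the records.
#' @return A validated `tpm_cores` tibble with one apex and one base record
#'   per template hole.
#' @export
sample_cores <- function(truth, grid = grid_spec(), discontinuity_prob = 0,
                         seed = NULL, patient_id = "P1") {
  with_seed(seed, {
    res <- grid$fine_res
    nl <- grid$needle_length
    rows <- list()
    for (iy in 0:(grid$ny - 1L)) for (ix in 0:(grid$nx - 1L)) {
      pairs <- track_pairs(truth$lesions, ix, iy, grid)
      for (slot in c("apex", "base")) {
        z0 <- if (slot == "apex") 0 else nl
        k <- which(pairs > 0L &
                     (seq_along(pairs) - 0.5) * res > z0 &
                     (seq_along(pairs) - 0.5) * res < z0 + nl)
        foci <- NULL
        if (length(k)) {
          breaks <- c(0L, which(diff(k) > 1L), length(k))
          foci <- do.call(rbind, lapply(seq_len(length(breaks) - 1L), function(r) {
            kk <- k[(breaks[r] + 1L):breaks[r + 1L]]
            pair <- recombine_grades(pairs[kk], rep(res, length(kk)))
            data.frame(offset = (kk[1L] - 1L) * res - z0,
                       length = length(kk) * res,
                       primary = gleason_primary(pair),
                       secondary = gleason_secondary(pair),
                       tertiary = NA_integer_)
          }))
          if (discontinuity_prob > 0 && stats::runif(1) < discontinuity_prob) {
            foci <- split_longest_focus(foci)
          }
        }
        rows[[length(rows) + 1L]] <- list(ix = ix, iy = iy, slot = slot,
                                          foci = foci)
      }
    }
    core_records(
      patient_id,
      vapply(rows, `[[`, 0L, "ix"),
      vapply(rows, `[[`, 0L, "iy"),
      vapply(rows, function(r) r$slot, ""),
      grid$needle_length,
      foci = lapply(rows, `[[`, "foci"),
      grid = grid)
  })
}

# replace the longest focus (if >= 4 mm) by two foci around a central benign
# gap of 1-3 mm (multiples of 0.5 mm); both halves keep the original score
split_longest_focus <- function(foci) {
  j <- which.max(foci$length)
  L <- foci$length[j]
  if (L < 4) return(foci)
  gap <- sample(seq(1, 3, by = 0.5), 1L)
  l1 <- round((L - gap) / 2 / 0.5) * 0.5
  l2 <- L - gap - l1
  if (l1 < 0.5 || l2 < 0.5) return(foci)
  top <- foci[j, , drop = FALSE]
  a <- top; a$length <- l1
  b <- top; b$offset <- top$offset + l1 + gap; b$length <- l2
  out <- rbind(foci[-j, , drop = FALSE], a, b)
  out[order(out$offset), , drop = FALSE]
}

# ---- cohort generation -----------------------------------------------------

#' Parameters of a synthetic TPM cohort
#'
#' Defaults emulate the scale and mix of a ~94-patient biopsy-naive pilot
#' cohort: a Poisson number of lesions per prostate (mean 2.1, so some
#' patients are cancer-free), lesion volumes lognormal around a 0.06 ml
#' median with a long upper tail, bulk Gleason scores dominated by 3+3 and
#' 3+4, 24% of lesions heterogeneous (planted high-grade focus), and, for
#' heterogeneous lesions, a focus placed at the lesion centre with
#' probability 0.75 or else offset 5-15 mm towards the periphery. Foci are
#' snapped to the nearest template grid site so that the planted pattern is
#' always expressed in at least one sampled core. 10% of cancer-bearing
#' cores report their longest focus as two discontinuous foci.
#'
#' @param n_patients Number of prostates.
#' @param lesion_rate Poisson mean of lesions per prostate.
#' @param fraction_heterogeneous Probability a lesion carries a planted
#'   high-grade focus.
#' @param p_focus_central Probability a planted focus sits at the lesion
#'   centre (concordant by construction).
#' @param offset_range Range (mm) of non-central focus offsets.
#' @param discontinuity_prob Per-core probability of a split cancer run.
#' @param vol_meanlog,vol_sdlog Lognormal parameters of the ellipsoid volume
#'   (ml).
#' @param vol_range Truncation range (ml) for the ellipsoid volume.
#' @param score_probs Named probabilities of the bulk Gleason score
#'   (pair-code names).
#' @param seed RNG seed; a fixed seed reproduces the cohort byte for byte.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 94L, lesion_rate = 2.1,
                        fraction_heterogeneous = 0.24,
                        p_focus_central = 0.75, offset_range = c(5, 15),
                        discontinuity_prob = 0.1,
                        vol_meanlog = log(0.025), vol_sdlog = 1.2,
                        vol_range = c(0.01, 6),
                        score_probs = c(`33` = 0.61, `34` = 0.30,
                                        `43` = 0.05, `44` = 0.04),
                        seed = 1L) {
  stopifnot(n_patients >= 0, lesion_rate >= 0,
            fraction_heterogeneous >= 0, fraction_heterogeneous <= 1,
            p_focus_central >= 0, p_focus_central <= 1,
            abs(sum(score_probs) - 1) < 1e-6)
  structure(as.list(environment()), class = "cohort_spec")
}

# 6-probe check that a sphere (centre fc, radius fr) lies inside an ellipsoid
sphere_in_ellipsoid <- function(fc, fr, ctr, radii) {
  probes <- matrix(fc, 6L, 3L, byrow = TRUE) + fr * rbind(diag(3), -diag(3))
  u <- sweep(sweep(probes, 2L, ctr), 2L, radii, "/")
  all(rowSums(u^2) <= 1 + 1e-9)
}

# draw one lesion inside the field, avoiding `taken` bounding boxes;
# returns NULL if no placement found. Heterogeneous lesions are drawn large
# enough to span at least two template columns (grade heterogeneity confined
# to a single core is not observable across cores and is not emulated), and
# lesions hosting an off-centre focus are elongated along the offset axis.
draw_lesion <- function(spec, taken, grid) {
  het <- stats::runif(1) < spec$fraction_heterogeneous
  kappa <- stats::runif(1, 0.7, 1.8)
  V <- exp(stats::rnorm(1, spec$vol_meanlog, spec$vol_sdlog))
  V <- min(max(V, spec$vol_range[1L]), spec$vol_range[2L])
  r <- (3 * V * 1000 / (4 * pi * kappa))^(1 / 3)
  radii <- c(r, r, kappa * r)
  d <- 0; axis <- 1L; dir <- 1
  if (het) {
    radii[1:2] <- pmax(radii[1:2], 6.2)
    radii[3L] <- max(radii[3L], 2.5)
    if (stats::runif(1) >= spec$p_focus_central) {
      d <- round(stats::runif(1, spec$offset_range[1L], spec$offset_range[2L]) /
                   grid$spacing) * grid$spacing
      axis <- sample(1:2, 1L)
      dir <- sample(c(-1, 1), 1L)
      radii[axis] <- max(radii[axis], d + 4.5)
      radii[3L] <- max(radii[3L], 4.5)
    }
  }
  lim <- c(grid$field, grid$z_extent)
  if (any(2 * radii + 2 > lim)) radii <- pmin(radii, (lim - 2) / 2)
  for (try in 1:60) {
    ctr <- stats::runif(3, radii + 1, lim - radii - 1)
    # snap the lateral centre to the nearest template site so the lesion's
    # centre column (and a central planted focus) is actually sampled
    ctr[1:2] <- (round(ctr[1:2] / grid$spacing - 0.5) + 0.5) * grid$spacing
    if (any(ctr - radii < 0) || any(ctr + radii > lim))
      next
    box <- rbind(ctr - radii - c(6, 6, 2.5), ctr + radii + c(6, 6, 2.5))
    clash <- any(vapply(taken, function(tb)
      all(box[1L, ] <= tb[2L, ]) && all(tb[1L, ] <= box[2L, ]), TRUE))
    if (!clash) {
      base <- as.integer(names(spec$score_probs))[
        sample.int(length(spec$score_probs), 1L, prob = spec$score_probs)]
      focus <- if (het) draw_focus(spec, ctr, radii, base, d, axis, dir, grid)
      return(list(spec = lesion_spec(ctr, radii, base, focus, grid), box = box))
    }
  }
  NULL
}

draw_focus <- function(spec, ctr, radii, base, d, axis, dir, grid) {
  fr <- min(2, 0.7 * min(radii))
  if (fr < 0.5) return(NULL)
  hi <- max(gleason_primary(base), gleason_secondary(base))
  # a grade-4-dominant nodule inside a Gleason-7 lesion yields 4+3 cores next
  # to 3+4 ones (heterogeneous by grades, homogeneous by score); otherwise the
  # focus carries the next pattern up
  fscore <- if (hi >= 5L) 55L else if (hi == 4L) {
    if (stats::runif(1) < 0.6) 44L else 55L
  } else 44L
  # walk the planted offset back towards the centre (site by site) until the
  # focus sphere fits inside the ellipsoid; d = 0 (central) always fits
  while (d > 0) {
    fc <- ctr; fc[axis] <- fc[axis] + dir * d
    if (sphere_in_ellipsoid(fc, fr, ctr, radii)) break
    d <- d - grid$spacing
  }
  fc <- ctr; fc[axis] <- fc[axis] + dir * d
  if (!sphere_in_ellipsoid(fc, fr, ctr, radii)) return(NULL)
  list(center = fc, radius = fr, score = fscore)
}

#' Generate a synthetic TPM cohort with ground truth
#'
#' Draws every patient's lesions under [cohort_spec()], rasterises the truth,
#' and samples the template cores. Lesions within one prostate are placed
#' with disjoint safety boxes so they cannot merge under 26-connectivity.
#'
#' @param spec A [cohort_spec()].
#' @param grid A [grid_spec()].
#' @return A list of class `tpm_cohort`: `cores` (one `tpm_cores` tibble for
#'   all patients), `truth` (per-lesion tibble with patient ids and planted
#'   geometry), and `spec`.
#' @export
make_cohort <- function(spec = cohort_spec(), grid = grid_spec()) {
  with_seed(spec$seed, {
    all_cores <- list(); all_truth <- list()
    for (p in seq_len(spec$n_patients)) {
      pid <- sprintf("P%03d", p)
      n_les <- stats::rpois(1, spec$lesion_rate)
      lesions <- list(); taken <- list()
      while (length(lesions) < n_les) {
        drawn <- draw_lesion(spec, taken, grid)
        if (is.null(drawn)) break
        lesions[[length(lesions) + 1L]] <- drawn$spec
        taken[[length(taken) + 1L]] <- drawn$box
      }
      truth <- generate_truth_volume(lesions, grid)
      cores <- sample_cores(truth, grid,
                            discontinuity_prob = spec$discontinuity_prob,
                            patient_id = pid)
      all_cores[[p]] <- cores
      if (nrow(truth$meta))
        all_truth[[p]] <- dplyr::mutate(truth$meta, patient_id = pid,
                                        .before = 1L)
    }
    cores <- dplyr::bind_rows(all_cores)
    class(cores) <- unique(c("tpm_cores", class(cores)))
    structure(list(cores = cores,
                   truth = dplyr::bind_rows(all_truth),
                   spec = spec, grid = grid),
              class = "tpm_cohort")
  })
}

#' Generate the hotspot-recovery study cohort
#'
#' One large lesion per patient, Gleason 3+3 bulk with a 2 mm Gleason 4+4
#' focus planted at a controlled lateral offset from the lesion centre
#' (0 mm = centred, concordant by construction; 5, 10 or 15 mm = discordant).
#' Lesion centres and foci sit on template grid sites so the planted offset
#' is exact; semi-axes vary mildly across patients and grow with the offset
#' so the focus stays well inside the lesion.
#'
#' @param offsets Vector of planted offsets in mm (multiples of the 5 mm
#'   pitch, 0 allowed).
#' @param n_per_offset Lesions (= patients) per offset.
#' @param seed RNG seed.
#' @param grid A [grid_spec()].
#' @return A `tpm_cohort` whose `truth` carries `offset_mm` and
#'   `truth_concordant` for scoring recovery.
#' @export
make_offset_cohort <- function(offsets = c(0, 5, 10, 15), n_per_offset = 50L,
                               seed = 1L, grid = grid_spec()) {
  with_seed(seed, {
    all_cores <- list(); all_truth <- list(); p <- 0L
    for (d in offsets) for (i in seq_len(n_per_offset)) {
      p <- p + 1L
      pid <- sprintf("R%03d", p)
      ctr_site <- c(6L, 6L)  # centre hole of the 13 x 13 template
      ctr <- c((ctr_site + 0.5) * grid$spacing, stats::runif(1, 17, 23))
      a <- max(8, d + 4.5) + stats::runif(1, 0, 1.5)
      b <- stats::runif(1, 6, 8)
      cz <- stats::runif(1, 7, 9)
      dir <- sample(c(1, -1), 1L)
      axis <- sample(1:2, 1L)
      fc <- ctr
      fc[axis] <- fc[axis] + dir * d
      radii <- c(b, b, cz)
      radii[axis] <- a
      focus <- list(center = fc, radius = 2, score = 44L)
      lesions <- list(lesion_spec(ctr, radii, 33L, focus, grid))
      truth <- generate_truth_volume(lesions, grid)
      cores <- sample_cores(truth, grid, patient_id = pid)
      all_cores[[p]] <- cores
      all_truth[[p]] <- dplyr::mutate(truth$meta, patient_id = pid,
                                      .before = 1L)
    }
    cores <- dplyr::bind_rows(all_cores)
    class(cores) <- unique(c("tpm_cores", class(cores)))
    structure(list(cores = cores, truth = dplyr::bind_rows(all_truth),
                   spec = list(offsets = offsets, n_per_offset = n_per_offset,
                               seed = seed),
                   grid = grid),
              class = "tpm_cohort")
  })
}

#' Write a synthetic cohort to disk
#'
#' One core-table CSV per patient (the [write_core_table()] schema) plus
#' `truth.json` with the planted lesion geometry.
#'
#' @param cohort A `tpm_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (pid in unique(cohort$cores$patient_id)) {
    sub <- dplyr::filter(cohort$cores, .data$patient_id == pid)
    class(sub) <- unique(c("tpm_cores", class(sub)))
    write_core_table(sub, file.path(dir, paste0(pid, ".csv")),
                     grid = cohort$grid)
  }
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(dir)
}
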