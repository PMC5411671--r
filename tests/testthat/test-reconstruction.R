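# small hand-made coarse map: pair codes painted into an nx x ny x nz array
toy_map <- function(paint, dims = c(5, 5, 8), sampled = TRUE) {
  grade <- array(if (sampled) 0L else NA_integer_, dims)
  for (p in paint) grade[p$ix, p$iy, p$iz] <- p$pair
  structure(list(grade = grade, grid = grid_spec(), ccl_mode = "separate",
                 origin = c(0L, 0L, 0L)),
            class = "coarse_map")
}

test_that("trilinear interpolation reproduces its nodes and the hat profile", {
  m <- toy_map(list(list(ix = 3, iy = 3, iz = 4, pair = 33L)))
  fine <- interpolate_fine(m)
  cc <- tpm3d:::coarse_centers(m)
  fc <- tpm3d:::fine_centers(m)
  # against the 8-corner oracle at random interior points
  ind <- tpm3d:::coarse_indicators(m)
  set.seed(5)
  for (r in 1:25) {
    i <- sample(seq_along(fc$x), 1); j <- sample(seq_along(fc$y), 1)
    k <- sample(seq_along(fc$z), 1)
    p <- c(fc$x[i], fc$y[j], fc$z[k])
    expect_equal(fine$fields$presence[i, j, k],
                 trilinear_oracle(ind$presence, cc, p), tolerance = 1e-12)
  }
  # the interpolant is exact at the coarse nodes (weights matrix identity)
  W <- tpm3d:::interp_weights(cc$z, cc$z)
  expect_equal(W, diag(length(cc$z)))
  # hat decay towards the neighbouring voxel centres
  peak_neighbour <- fine$fields$presence[25, 25, 8]  # 0.25 mm off in z only
  expect_equal(peak_neighbour, 0.95 * 0.95 * 0.75, tolerance = 1e-12)

  benign <- toy_map(list())
  f0 <- interpolate_fine(benign)
  expect_true(all(f0$fields$presence == 0) && all(f0$fields$g3 == 0))
})

test_that("Gaussian smoothing: identity at zero, kernel oracle, mass conservation", {
  m <- toy_map(list(list(ix = 3, iy = 3, iz = 20, pair = 34L)),
               dims = c(5, 5, 40))
  fine <- interpolate_fine(m)
  expect_identical(gaussian_smooth(fine, 0)$fields, fine$fields)
  expect_error(gaussian_smooth(fine, -1), "sigma")

  # impulse response matches the direct (non-separable) kernel oracle
  imp <- fine
  imp$fields <- list(presence = array(0, dim(fine$fields$presence)))
  imp$fields$presence[20, 20, 40] <- 1
  sm <- gaussian_smooth(imp, 1)
  for (probe in list(c(20, 20, 40), c(21, 20, 39), c(18, 22, 41))) {
    expect_equal(sm$fields$presence[probe[1], probe[2], probe[3]],
                 gauss_oracle(imp$fields$presence, probe[1], probe[2],
                              probe[3], 1, 0.5),
                 tolerance = 1e-12)
  }
  # total mass is conserved away from the volume boundary
  expect_equal(sum(sm$fields$presence), 1, tolerance = 1e-9)

  # a constant field is a fixed point away from the boundary
  const <- fine
  const$fields <- list(presence = array(1, dim(fine$fields$presence)))
  smc <- gaussian_smooth(const, 1)
  interior <- smc$fields$presence[15:35, 15:35, 20:60]

  expect_equal(max(abs(interior - 1)), 0, tolerance = 1e-9)
})

test_that("preservation holds unsmoothed and flags over-smoothed sites", {
  set.seed(12)
  for (r in 1:10) {
    paint <- lapply(1:4, function(i)
      list(ix = sample(5, 1), iy = sample(5, 1), iz = sample(8, 1),
           pair = sample(c(33L, 34L, 43L, 44L), 1)))
    m <- toy_map(paint)
    expect_true(preservation_check(interpolate_fine(m), m)$ok)
  }

  # isolated voxel smoothed to oblivion: status violation at that site
  m1 <- toy_map(list(list(ix = 3, iy = 3, iz = 4, pair = 33L)))
  pc <- preservation_check(gaussian_smooth(interpolate_fine(m1), 3), m1)
  expect_false(pc$ok)
  expect_true(any(pc$violations$reason == "status" &
                    pc$violations$ix == 2 & pc$violations$iy == 2 &
                    pc$violations$iz == 3))

  # a single 4+4 section inside a 3+3 run: moderate smoothing washes the
  # thin pattern-4 band out while presence survives -> grade violation at
  # exactly that section
  paint <- lapply(1:8, function(z)
    list(ix = 3, iy = 3, iz = z, pair = if (z == 4) 44L else 33L))
  m2 <- toy_map(paint)
  pc2 <- preservation_check(gaussian_smooth(interpolate_fine(m2), 2), m2)
  expect_false(pc2$ok)
  expect_true(any(pc2$violations$reason == "grade" &
                    pc2$violations$ix == 2 & pc2$violations$iy == 2 &
                    pc2$violations$iz == 3))
})

test_that("tuned sigma matches a grid-search oracle and sits on the boundary", {
  m <- toy_map(list(list(ix = 3, iy = 3, iz = 4, pair = 33L),
                    list(ix = 3, iy = 3, iz = 5, pair = 33L)))
  pre <- interpolate_fine(m)
  tol <- 0.02
  s_bis <- tune_sigma(pre, m, tol = tol)
  ok <- function(s) preservation_check(gaussian_smooth(pre, s), m)$ok
  grid_s <- seq(0, 5, by = 0.01)
  s_scan <- max(grid_s[vapply(grid_s, ok, TRUE)])
  expect_lt(abs(s_bis - s_scan), tol + 0.01 + 1e-9)
  expect_true(ok(s_bis))
  expect_false(ok(s_bis + 2 * tol + 0.02))
})

test_that("well-separated bulky lesions allow maximal smoothing", {
  paint <- list()
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:3)
    paint <- c(paint,
               list(list(ix = 1 + dx, iy = 1 + dy, iz = 1 + dz, pair = 33L),
                    list(ix = 9 + dx, iy = 9 + dy, iz = 30 + dz, pair = 33L)))
  m <- toy_map(paint, dims = c(11, 11, 36))
  # the 1 mm z sections cap useful smoothing well below the grid pitch, so
  # probe with a bound the bulky blocks can certainly sustain
  s <- tune_sigma(interpolate_fine(m), m, sigma_max = 0.5)
  expect_equal(s, 0.5)
})

test_that("resampling operators agree with the coarse map at tuned sigma", {
  coh <- make_cohort(cohort_spec(n_patients = 2, seed = 33))
  sub <- coh$cores[coh$cores$patient_id == "P001", ]
  class(sub) <- unique(c("tpm_cores", class(sub)))
  map <- crop_coarse_map(build_coarse_map(sub, ccl_mode = "separate"))
  les <- label_lesions(map)
  fine <- reconstruct_fine(map, les)
  expect_true(preservation_check(fine, map)$ok)
  # the point and block operators both exist; block averaging is smoother
  rs_point <- resample_at_sites(fine, map, "point")
  rs_block <- resample_at_sites(fine, map, "block")
  expect_identical(dim(rs_point$presence), dim(map$grade))
  expect_identical(dim(rs_block$presence), dim(map$grade))
  expect_error(resample_at_sites(fine, toy_map(list())), "geometries")
})

test_that("fine lesion ids cover exactly the fine cancer voxels", {
  rec <- core_records("P1", c(3, 9), c(3, 9), "apex", 20, foci = list(
    data.frame(offset = 5, length = 4, primary = 3, secondary = 3),
    data.frame(offset = 5, length = 4, primary = 4, secondary = 4)))
  map <- crop_coarse_map(build_coarse_map(rec, ccl_mode = "separate"))
  les <- label_lesions(map)
  expect_identical(les$n_lesions, 2L)
  fine <- reconstruct_fine(map, les)
  expect_identical(fine$lesion_id > 0L, fine$label > 0L)
  expect_setequal(unique(fine$lesion_id[fine$lesion_id > 0]), 1:2)
  # the two lesions' fine voxels sit laterally near their own cores
  fc <- tpm3d:::fine_centers(map)
  idx1 <- which(fine$lesion_id == 1L, arr.ind = TRUE)
  idx2 <- which(fine$lesion_id == 2L, arr.ind = TRUE)
  expect_true(all(fc$x[idx1[, 1]] < 32.5))
  expect_true(all(fc$x[idx2[, 1]] > 32.5))
})
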