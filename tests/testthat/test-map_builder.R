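test_that("separate and cumulative CCL follow their counting definitions", {
  f <- data.frame(offset = c(2, 9), length = c(3, 2), primary = 3,
                  secondary = 3)
  sep <- compute_ccl(f, "separate")
  expect_equal(sep$ccl, 5)
  expect_equal(sep$mccl_basis, 3)
  expect_equal(as.data.frame(sep$segments),
               data.frame(z_start = c(2, 9), z_end = c(5, 11),
                          pair = c(33L, 33L)))
  cum <- compute_ccl(f, "cumulative")
  expect_equal(cum$ccl, 9)
  expect_equal(cum$mccl_basis, 9)
  expect_equal(as.data.frame(cum$segments),
               data.frame(z_start = 2, z_end = 11, pair = 33L))

  single <- data.frame(offset = 4, length = 6, primary = 3, secondary = 4)
  expect_equal(compute_ccl(single, "separate")$segments,
               compute_ccl(single, "cumulative")$segments)
  expect_equal(compute_ccl(single, "separate")$ccl, 6)

  none <- compute_ccl(data.frame(), "separate")
  expect_equal(none$ccl, 0)

  overlap <- data.frame(offset = c(2, 4), length = c(3, 2), primary = 3,
                        secondary = 3)
  expect_error(compute_ccl(overlap, "separate"), "overlapping")
})

test_that("cumulative CCL dominates separate CCL on random foci", {
  set.seed(11)
  for (i in 1:100) {
    n <- sample(1:4, 1)
    starts <- sort(sample(seq(0, 16, by = 0.5), n))
    lens <- pmin(runif(n, 0.5, 4), c(diff(starts), 20 - starts[n]))
    f <- data.frame(offset = starts, length = pmax(lens, 0.5),
                    primary = sample(3:5, n, TRUE), secondary = 3)
    f <- f[f$offset + f$length <= 20, , drop = FALSE]
    f <- f[c(TRUE, f$offset[-1] >= (f$offset + f$length)[-nrow(f)])[
      seq_len(nrow(f))], , drop = FALSE]
    if (!nrow(f)) next
    expect_gte(compute_ccl(f, "cumulative")$ccl,
               compute_ccl(f, "separate")$ccl)
  }
})

test_that("cumulative grade recombination weights patterns by length", {
  # 6 mm of 3+3 and 2 mm of 4+4 with a gap: w3 = 6, w4 = 2 -> 3+4
  f <- data.frame(offset = c(0, 8), length = c(6, 2),
                  primary = c(3, 4), secondary = c(3, 4))
  expect_identical(compute_ccl(f, "cumulative")$segments$pair, 34L)
  # 2 mm of 3+3 and 6 mm of 4+4 -> 4+3
  f2 <- data.frame(offset = c(0, 4), length = c(2, 6),
                   primary = c(3, 4), secondary = c(3, 4))
  expect_identical(compute_ccl(f2, "cumulative")$segments$pair, 43L)
})

test_that("segments paint the correct z voxels for apex and base cores", {
  rec <- core_records("P1", c(2, 2), c(4, 4), c("apex", "base"), 20,
                      foci = list(
                        data.frame(offset = 2, length = 3, primary = 3,
                                   secondary = 3),
                        data.frame(offset = 2, length = 3, primary = 4,
                                   secondary = 3)))
  m <- build_coarse_map(rec, ccl_mode = "separate")
  apex_z <- which(m$grade[3, 5, ] == 33L)
  base_z <- which(m$grade[3, 5, ] == 43L)
  expect_identical(apex_z, 3:5)     # 0-based voxels 2, 3, 4
  expect_identical(base_z, 23:25)   # 0-based voxels 22, 23, 24
  # voxels covered by the cores but free of cancer are benign; the rest of
  # the template carries no tissue
  expect_identical(sum(m$grade == 0L, na.rm = TRUE), 40L - 6L)
  expect_identical(sum(is.na(m$grade)), 13L * 13L * 40L - 40L)
})

test_that("painting is order-independent and length-preserving", {
  set.seed(4)
  coh <- make_cohort(cohort_spec(n_patients = 2, seed = 17))
  sub <- coh$cores[coh$cores$patient_id == "P001", ]
  class(sub) <- unique(c("tpm_cores", class(sub)))
  m1 <- build_coarse_map(sub, ccl_mode = "separate")
  perm <- sub[sample(nrow(sub)), ]
  class(perm) <- unique(c("tpm_cores", class(perm)))
  m2 <- build_coarse_map(perm, ccl_mode = "separate")
  expect_identical(m1$grade, m2$grade)

  # per-column painted cancer length equals the summed CCL of its two cores
  # (all synthetic focus boundaries are multiples of 0.5 mm >= half a voxel)
  for (ix in unique(sub$grid_x)) for (iy in unique(sub$grid_y)) {
    cores_xy <- sub[sub$grid_x == ix & sub$grid_y == iy, ]
    if (!nrow(cores_xy)) next
    ccl_sum <- sum(vapply(cores_xy$foci, function(f)
      compute_ccl(f, "separate")$ccl, 0))
    painted <- sum(m1$grade[ix + 1, iy + 1, ] > 0, na.rm = TRUE)
    expect_lte(abs(painted - ccl_sum), 1)
  }
})

test_that("gap filling in cumulative mode can only add cancer voxels", {
  coh <- make_cohort(cohort_spec(n_patients = 5, discontinuity_prob = 0.6,
                                 seed = 23))
  for (pid in unique(coh$cores$patient_id)) {
    sub <- coh$cores[coh$cores$patient_id == pid, ]
    class(sub) <- unique(c("tpm_cores", class(sub)))
    msep <- build_coarse_map(sub, ccl_mode = "separate")
    mcum <- build_coarse_map(sub, ccl_mode = "cumulative")
    expect_gte(sum(mcum$grade > 0, na.rm = TRUE),
               sum(msep$grade > 0, na.rm = TRUE))
    expect_true(all(which(msep$grade > 0) %in% which(mcum$grade > 0)))
  }
})

test_that("cropping preserves content and records the origin", {
  rec <- core_records("P1", 9, 11, "apex", 20,
                      foci = list(data.frame(offset = 10, length = 4,
                                             primary = 3, secondary = 3)))
  m <- build_coarse_map(rec, ccl_mode = "separate")
  mc <- crop_coarse_map(m)
  expect_lt(prod(dim(mc$grade)), prod(dim(m$grade)))
  idx <- which(mc$grade > 0L, arr.ind = TRUE)
  global <- sweep(idx, 2, mc$origin, "+")
  expect_identical(sort(m$grade[global]), sort(mc$grade[idx]))
  # centre of the cancer site is present among the cropped centres, in
  # global millimetres
  cc <- tpm3d:::coarse_centers(mc)
  expect_true((9.5 * 5) %in% cc$x && (11.5 * 5) %in% cc$y)
})
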