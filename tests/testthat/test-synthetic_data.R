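test_that("truth volumes rasterise planted ellipsoids and enforce geometry", {
  ls <- lesion_spec(c(32.5, 32.5, 20), c(8, 6, 5), 33L)
  truth <- generate_truth_volume(list(ls))
  vals <- unique(as.vector(truth$volume))
  expect_setequal(vals, c(0L, 33L))
  # voxel count approximates the analytic ellipsoid volume (0.5 mm voxels)
  v_vox <- sum(truth$volume > 0) * 0.5^3 / 1000
  expect_lt(abs(v_vox - truth$meta$ellipsoid_ml) / truth$meta$ellipsoid_ml, 0.05)
  expect_equal(truth$meta$truth_max_ccl, 10)

  expect_error(lesion_spec(c(2, 32.5, 20), c(8, 6, 5)), "outside")
  expect_error(lesion_spec(c(32.5, 32.5, 20), c(8, 6, 5), 33L,
                           focus = list(center = c(39, 32.5, 20), radius = 2,
                                        score = 44L)),
               "does not fit")
})

test_that("a centred high-grade focus overwrites the bulk label", {
  ls <- lesion_spec(c(32.5, 32.5, 20), c(8, 6, 5), 33L,
                    focus = list(center = c(32.5, 32.5, 20), radius = 2,
                                 score = 44L))
  truth <- generate_truth_volume(list(ls))
  expect_setequal(unique(as.vector(truth$volume)), c(0L, 33L, 44L))
  centre <- truth$volume[65, 65, 40]  # voxel containing the focus centre
  expect_identical(centre, 44L)
  expect_true(truth$meta$truth_concordant)
})

test_that("template sampling reports contiguous runs with exact geometry", {
  # ellipsoid centred on site (6, 6) at z = 10 with 3.5 mm z semi-axis:
  # the centre needle crosses exactly 7 mm of Gleason 3+3 in the apex core
  ls <- lesion_spec(c(32.5, 32.5, 10), c(4, 4, 3.5), 33L)
  cores <- sample_cores(generate_truth_volume(list(ls)))
  centre_apex <- cores[cores$grid_x == 6 & cores$grid_y == 6 &
                         cores$depth_slot == "apex", ]
  f <- centre_apex$foci[[1]]
  expect_identical(nrow(f), 1L)
  expect_equal(f$length, 7)
  expect_equal(f$offset, 6.5)
  expect_identical(gleason_pair(f$primary, f$secondary), 33L)
  # needles away from the lesion report benign cores
  far <- cores[cores$grid_x == 0, ]
  expect_true(all(vapply(far$foci, nrow, 0L) == 0L))
})

test_that("rebuilt coarse maps agree with the truth at every grid site", {
  coh <- make_cohort(cohort_spec(n_patients = 4, fraction_heterogeneous = 0,
                                 discontinuity_prob = 0, seed = 3))
  specs <- split(coh$truth, coh$truth$patient_id)
  for (pid in names(specs)) {
    sub <- coh$cores[coh$cores$patient_id == pid, ]
    class(sub) <- unique(c("tpm_cores", class(sub)))
    map <- build_coarse_map(sub, ccl_mode = "separate")
    tr <- specs[[pid]]
    lesions <- lapply(seq_len(nrow(tr)), function(i)
      lesion_spec(c(tr$center_x[i], tr$center_y[i], tr$center_z[i]),
                  c(tr$a[i], tr$b[i], tr$c[i]), tr$base_score[i]))
    for (ix in 0:12) for (iy in 0:12) {
      prof <- site_profile_oracle(lesions, ix, iy)
      got <- map$grade[ix + 1, iy + 1, ]
      expect_equal(unname(got), prof,
                   label = sprintf("%s site (%d,%d)", pid, ix, iy))
    }
  }
})

test_that("a fixed seed reproduces the cohort byte for byte", {
  a <- make_cohort(cohort_spec(n_patients = 4, seed = 9))
  b <- make_cohort(cohort_spec(n_patients = 4, seed = 9))
  expect_identical(as.data.frame(a$cores), as.data.frame(b$cores))
  expect_identical(as.data.frame(a$truth), as.data.frame(b$truth))
  c2 <- make_cohort(cohort_spec(n_patients = 4, seed = 10))
  expect_false(identical(as.data.frame(a$cores), as.data.frame(c2$cores)))
})

test_that("fraction_heterogeneous = 0 yields only homogeneous lesions downstream", {
  coh <- make_cohort(cohort_spec(n_patients = 6, fraction_heterogeneous = 0,
                                 discontinuity_prob = 0, seed = 21))
  expect_true(all(!coh$truth$has_focus))
  for (pid in unique(coh$cores$patient_id)) {
    sub <- coh$cores[coh$cores$patient_id == pid, ]
    class(sub) <- unique(c("tpm_cores", class(sub)))
    map <- build_coarse_map(sub, ccl_mode = "separate")
    les <- label_lesions(map)
    for (id in seq_len(les$n_lesions)) {
      comp <- unique(map$grade[les$voxels[[id]]])
      expect_false(classify_heterogeneity(comp, "grades"))
    }
  }
})

test_that("planted heterogeneity is recovered at the planted rate", {
  coh <- make_cohort(cohort_spec(n_patients = 40, fraction_heterogeneous = 0.24,
                                 discontinuity_prob = 0, seed = 13))
  n_planted <- nrow(coh$truth)
  n_het_truth <- sum(coh$truth$has_focus)
  n_het_obs <- 0L; n_obs <- 0L
  for (pid in unique(coh$cores$patient_id)) {
    sub <- coh$cores[coh$cores$patient_id == pid, ]
    class(sub) <- unique(c("tpm_cores", class(sub)))
    map <- build_coarse_map(sub, ccl_mode = "separate")
    les <- label_lesions(map)
    n_obs <- n_obs + les$n_lesions
    for (id in seq_len(les$n_lesions)) {
      comp <- unique(map$grade[les$voxels[[id]]])
      n_het_obs <- n_het_obs + classify_heterogeneity(comp, "grades")
    }
  }
  # every planted lesion is detected (centres sit on sampled sites) and every
  # planted focus is expressed across cores
  expect_identical(n_obs, n_planted)
  expect_identical(n_het_obs, n_het_truth)
  # the planted rate itself is binomial around 0.24
  expect_lt(abs(n_het_truth / n_planted - 0.24),
            3 * sqrt(0.24 * 0.76 / n_planted))
})

test_that("discontinuous reporting splits a run into two same-grade foci", {
  ls <- lesion_spec(c(32.5, 32.5, 10), c(4, 4, 4), 34L)
  truth <- generate_truth_volume(list(ls))
  whole <- sample_cores(truth, discontinuity_prob = 0)
  split <- sample_cores(truth, discontinuity_prob = 1, seed = 2)
  ca <- whole$foci[[which(whole$grid_x == 6 & whole$grid_y == 6 &
                            whole$depth_slot == "apex")]]
  cs <- split$foci[[which(split$grid_x == 6 & split$grid_y == 6 &
                            split$depth_slot == "apex")]]
  expect_identical(nrow(ca), 1L)
  expect_identical(nrow(cs), 2L)
  gap <- cs$offset[2] - (cs$offset[1] + cs$length[1])
  expect_gte(gap, 1); expect_lte(gap, 3)
  expect_equal(sum(cs$length) + gap, ca$length)
  expect_identical(unique(cs$primary), ca$primary)
})
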