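csv_header <- paste0("patient_id,grid_col,grid_row,depth_slot,core_length,",
                     "focus1_offset,focus1_length,focus1_primary,",
                     "focus1_secondary,focus1_tertiary")

write_csv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(c(csv_header, lines), path)
  path
}

test_that("core rows map letters, rows and packed foci onto validated records", {
  path <- write_csv_lines(c("P01,D,7,apex,18,2,3,3,3,",
                            "P01,A,1,base,20,,,,,"))
  rec <- read_core_table(path)
  expect_identical(rec$grid_x, c(3L, 0L))
  expect_identical(rec$grid_y, c(6L, 0L))
  expect_identical(rec$depth_slot, c("apex", "base"))
  expect_equal(rec$core_length, c(18, 20))
  f <- rec$foci[[1]]
  expect_equal(f$offset, 2)
  expect_equal(f$length, 3)
  expect_identical(gleason_pair(f$primary, f$secondary), 33L)
  expect_identical(nrow(rec$foci[[2]]), 0L)
})

test_that("malformed rows are rejected with a diagnostic", {
  expect_error(read_core_table(write_csv_lines("P01,N,7,apex,18,,,,,")),
               "outside A-M")
  expect_error(read_core_table(write_csv_lines("P01,D,14,apex,18,,,,,")),
               "grid_row")
  expect_error(read_core_table(write_csv_lines("P01,D,7,apex,18,16,5,3,3,")),
               "beyond")
  expect_error(read_core_table(write_csv_lines("P01,D,7,apex,18,2,,3,3,")),
               "focus1_length")
  expect_error(read_core_table(write_csv_lines(
    c("P01,D,7,apex,18,,,,,", "P01,D,7,apex,18,,,,,"))), "duplicate")
  expect_error(read_core_table(write_csv_lines("P01,D,7,middle,18,,,,,")),
               "apex")
})

test_that("write/read round-trip is lossless, including a generated cohort", {
  path <- withr::local_tempfile(fileext = ".csv")
  empty <- core_records(character(0), integer(0), integer(0), character(0),
                        numeric(0))
  write_core_table(empty, path)
  expect_identical(nrow(read_core_table(path)), 0L)

  coh <- make_cohort(cohort_spec(n_patients = 3, seed = 5))
  write_core_table(coh$cores, path)
  back <- read_core_table(path)
  expect_equal(as.data.frame(back), as.data.frame(coh$cores),
               ignore_attr = TRUE)
})

test_that("risk classification follows the UCL significance definitions", {
  expect_identical(as.character(classify_core_risk(6, 33L)), "definition1")
  expect_identical(as.character(classify_core_risk(2, 43L)), "definition1")
  expect_identical(as.character(classify_core_risk(4, 33L)), "definition2")
  expect_identical(as.character(classify_core_risk(2, 34L)), "definition2")
  expect_identical(as.character(classify_core_risk(3, 33L)), "insignificant")
  expect_identical(as.character(classify_core_risk(0, NA)), "no_cancer")
  expect_error(classify_core_risk(-1, 33L), "negative")
  expect_error(classify_core_risk(2, NA), "score")
})

test_that("risk class is monotone in MCCL and in Gleason score", {
  scores <- c(33L, 34L, 43L, 44L, 45L, 54L, 55L)
  mccls <- c(0.5, 1, 3, 3.5, 4, 5.5, 6, 10)
  for (s in scores) {
    r <- classify_core_risk(mccls, s)
    expect_true(all(diff(as.integer(r)) >= 0), label = gleason_label(s))
  }
  for (m in mccls) {
    r <- classify_core_risk(rep(m, length(scores)), scores)
    expect_true(all(diff(as.integer(r)) >= 0), label = paste("mccl", m))
  }
})

test_that("visual map colours exactly the sampled cells that contain cancer", {
  rec <- core_records("P01", c(3, 5, 5), c(6, 2, 2), c("apex", "apex", "base"),
                      20, foci = list(
                        data.frame(offset = 1, length = 7, primary = 4,
                                   secondary = 3),
                        NULL, NULL))
  vm <- render_visual_map(rec)
  expect_s3_class(vm$plot, "ggplot")
  expect_identical(nrow(vm$cells), 3L)
  expect_identical(as.character(vm$cells$risk),
                   c("definition1", "no_cancer", "no_cancer"))
  expect_equal(vm$cells$ccl, c(7, 0, 0))

  # planted lesion: coloured cells are exactly the sites the lesion crosses
  ls <- lesion_spec(c(32.5, 32.5, 10), c(7, 6, 4), 33L)
  cores <- sample_cores(generate_truth_volume(list(ls)), patient_id = "S1")
  vm <- render_visual_map(cores)
  pos <- vm$cells[vm$cells$ccl > 0, ]
  hit <- unique(pos[, c("grid_x", "grid_y")])
  truth_hit <- do.call(rbind, lapply(0:12, function(ix) do.call(rbind,
    lapply(0:12, function(iy) {
      prof <- site_profile_oracle(list(ls), ix, iy)
      if (any(prof > 0)) data.frame(grid_x = ix, grid_y = iy)
    }))))
  expect_equal(hit[order(hit$grid_x, hit$grid_y), ],
               truth_hit[order(truth_hit$grid_x, truth_hit$grid_y), ],
               ignore_attr = TRUE)

  one <- core_records("P01", 3, 6, "apex", 20)
  two <- dplyr::bind_rows(one, one)
  expect_error(render_visual_map(two), "duplicate")
})
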