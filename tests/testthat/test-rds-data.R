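test_that("a minimal forest builds with correct waves and size", {
  s <- rds_sample(toy_sample_df())
  expect_s3_class(s, "rds_sample")
  expect_equal(nrow(s), 3)
  expect_equal(s$wave, c(0L, 1L, 1L))
})

test_that("validation raises distinct, named errors", {
  df <- toy_sample_df()

  cyc <- df
  cyc$recruiter_id <- c("B", "A", "A") # A <-> B
  expect_error(rds_sample(cyc), class = "rdsize_error_recruitment_order")

  dd <- df
  dd$degree_seen[2] <- 9L # exceeds degree_known = 5
  err <- expect_error(rds_sample(dd), class = "rdsize_error_degree")
  expect_match(conditionMessage(err), "B") # names the offending row

  dup <- df
  dup$id <- c("A", "A", "C")
  expect_error(rds_sample(dup), class = "rdsize_error_duplicate_id")

  late <- df
  late$recruiter_id <- c(NA, "C", NA) # recruiter enrolled after recruit
  expect_error(rds_sample(late), class = "rdsize_error_recruitment_order")

  expect_error(rds_sample(df[, -1]), class = "rdsize_error_missing_column")
  expect_error(rds_sample(df[0, ]), class = "rdsize_error_empty_sample")

  overc <- df
  overc$coupons_issued <- c(1L, 3L, 3L) # A recruited B and C on one coupon
  expect_error(rds_sample(overc), class = "rdsize_error_coupons")

  perm <- df
  perm$enrollment_index <- c(1L, 2L, 4L)
  expect_error(rds_sample(perm), class = "rdsize_error_enrollment_index")
})

test_that("effective_degree takes the restrictive report and flags missing", {
  x <- data.frame(degree_known = c(20L, 5L, NA), degree_seen = c(8L, NA, NA))
  expect_equal(effective_degree(x), c(8L, 5L, NA))
  s <- rds_sample(toy_sample_df())
  expect_true(all(effective_degree(s) <= s$degree_known, na.rm = TRUE))
})

test_that("CSV round-trips losslessly, including simulated samples", {
  path <- withr::local_tempfile(fileext = ".csv")
  s <- rds_sample(toy_sample_df(), label = "toy")
  write_rds_csv(s, path)
  s2 <- read_rds_csv(path, label = "toy")
  expect_equal(tibble::as_tibble(s2), tibble::as_tibble(s))

  smp <- sim_study(seed = 7)$sample
  write_rds_csv(smp, path)
  back <- read_rds_csv(path)
  expect_equal(back$id, smp$id)
  expect_equal(back$enrollment_index, smp$enrollment_index)
  expect_equal(effective_degree(back), effective_degree(smp))
  expect_equal(back$wave, smp$wave)
})

test_that("reader derives enrollment order from dates, ties by file order", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "id,recruiter_id,enrollment_date,degree_known,degree_seen,coupons_issued",
    "A,,2016-01-02,5,2,3",
    "B,A,2016-01-05,4,1,3",
    "C,A,2016-01-05,6,3,3"), path)
  s <- read_rds_csv(path)
  expect_equal(s$id, c("A", "B", "C")) # B before C: tie broken by file order
  expect_equal(s$enrollment_index, 1:3)
})

test_that("reader supports a column-name dialect", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "uid,ref,netsize,seen,ncoupons",
    "A,,5,2,3",
    "B,A,4,1,3"), path)
  s <- read_rds_csv(path, dialect = c(
    id = "uid", recruiter_id = "ref", degree_known = "netsize",
    degree_seen = "seen", coupons_issued = "ncoupons"))
  expect_equal(nrow(s), 2)
  expect_equal(effective_degree(s), c(2L, 1L))
})
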