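# Claims bundle IO, enrollment interval algebra, age arithmetic.

test_that("tiny fixture bundle reads with expected shape and round-trips", {
  dir <- system.file("extdata", "tiny_bundle", package = "fracturepathways")
  b <- read_bundle(dir)
  expect_s3_class(b, "claims_bundle")
  expect_equal(nrow(b$members), 3L)
  expect_equal(nrow(b$medical_claims), 5L)
  expect_equal(nrow(attr(b, "validation")), 0L)

  out <- file.path(tempdir(), "roundtrip_bundle")
  write_bundle(b, out)
  b2 <- read_bundle(out)
  for (tbl in c("members", "enrollment", "medical_claims", "pharmacy_claims")) {
    expect_equal(as.data.frame(b2[[tbl]]), as.data.frame(b[[tbl]]), info = tbl)
  }
})

test_that("invalid rows are rejected with line-level diagnostics", {
  dir <- system.file("extdata", "tiny_bundle", package = "fracturepathways")
  tmp <- file.path(tempdir(), "bad_bundle")
  dir.create(tmp, showWarnings = FALSE)
  file.copy(list.files(dir, full.names = TRUE), tmp, overwrite = TRUE)
  # append a zero-days-supply fill (line 5) and an unparseable date (line 6)
  cat("M1,2016-07-01,RX_OBP_1,0\nM2,not-a-date,RX_OBP_1,30\n",
      file = file.path(tmp, "pharmacy_claims.csv"), append = TRUE)
  b <- read_bundle(tmp)
  v <- attr(b, "validation")
  expect_equal(nrow(b$pharmacy_claims), 3L)
  expect_setequal(v$line, c(5L, 6L))
  expect_true(any(grepl("days_supply", v$reason)))
  expect_true(any(grepl("fill_date", v$reason)))
})

test_that("a missing required column is a schema error naming the column", {
  tmp <- file.path(tempdir(), "noscol_bundle")
  dir.create(tmp, showWarnings = FALSE)
  dir <- system.file("extdata", "tiny_bundle", package = "fracturepathways")
  file.copy(list.files(dir, full.names = TRUE), tmp, overwrite = TRUE)
  m <- data.table::fread(file.path(tmp, "members.csv"))
  m[, sex := NULL]
  data.table::fwrite(m, file.path(tmp, "members.csv"))
  expect_error(read_bundle(tmp), "sex")
})

test_that("continuous enrollment follows the closed-interval day count", {
  sp <- data.frame(start_date = as.Date("2014-01-01"),
                   end_date = as.Date("2016-12-31"),
                   medical = TRUE, pharmacy = TRUE)
  expect_true(is_continuously_enrolled(sp, "2015-03-01", "2015-12-31"))

  d0 <- as.Date("2015-01-01")
  two <- data.frame(start_date = d0 + c(0, 102), end_date = d0 + c(100, 400),
                    medical = TRUE, pharmacy = TRUE)
  # day d0+101 uncovered: zero gap tolerance fails, 1-day tolerance passes
  expect_false(is_continuously_enrolled(two, d0, d0 + 400))
  expect_true(is_continuously_enrolled(two, d0, d0 + 400, allowed_gap_days = 1L))

  med_only <- data.frame(start_date = d0, end_date = d0 + 400,
                         medical = TRUE, pharmacy = FALSE)
  expect_true(is_continuously_enrolled(med_only, d0, d0 + 300,
                                       require_pharmacy = FALSE))
  expect_false(is_continuously_enrolled(med_only, d0, d0 + 300))

  expect_error(is_continuously_enrolled(sp, d0, d0 - 1), "empty")
})

test_that("separate medical-only and pharmacy-only spans jointly satisfy both benefits", {
  d0 <- as.Date("2015-01-01")
  sp <- data.frame(start_date = c(d0, d0), end_date = c(d0 + 200, d0 + 200),
                   medical = c(TRUE, FALSE), pharmacy = c(FALSE, TRUE))
  expect_true(is_continuously_enrolled(sp, d0, d0 + 200))
})

test_that("enrollment decisions equal the day-by-day oracle on random spans", {
  set.seed(401)
  for (i in 1:400) {
    sp <- random_spans()
    w0 <- sample(0:2000, 1)
    wlen <- sample(10:900, 1)
    ws <- as.Date("2014-01-01") + w0
    we <- ws + wlen
    gap <- sample(c(0L, 0L, 3L), 1)
    got <- is_continuously_enrolled(sp, ws, we, allowed_gap_days = gap)
    want <- oracle_enrolled(sp, ws, we, gap = gap)
    expect_identical(got, want,
                     info = sprintf("case %d: window %s..%s gap %d", i, ws, we, gap))
  }
})

test_that("age uses year arithmetic", {
  m <- list(birth_year = 1965L)
  expect_identical(age_at(m, as.Date("2015-06-01")), 50L)
  expect_identical(age_at(m, as.Date("2014-12-31")), 49L)
  expect_identical(age_at(list(birth_year = 1935L), as.Date("2015-01-01")), 80L)
})

test_that("analysis config validates window nesting and positivity", {
  expect_error(analysis_config(index_start = as.Date("2013-06-01")), "nested")
  expect_error(analysis_config(pre_index_days = 0), "positive")
  cfg <- analysis_config()
  expect_identical(unname(cfg$landmark_days), c(183L, 365L, 730L))
})
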