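test_that("generation is deterministic given the config seed", {
  cc <- cohort_config(n_surgeries = 3, duration_minutes_range = c(10, 12), seed = 7)
  a <- generate_cohort(cc)
  b <- generate_cohort(cc)
  expect_identical(unclass(a), unclass(b))
})

test_that("records satisfy the structural invariants", {
  co <- tiny_cohort(4, c(10, 15), seed = 3)
  for (r in co) {
    n <- length(r$label)
    expect_identical(r$window_index, 0:(n - 1L))
    for (m in list(r$autonomic, r$autonomic_derivative,
                   r$drug_cumulative, r$drug_time_since)) {
      expect_equal(nrow(m), n)
      expect_false(anyNA(m))
    }
    expect_true(all(r$label %in% c(0L, 1L)))
    # cumulative dose nondecreasing within each class
    expect_true(all(apply(r$drug_cumulative, 2, function(z) all(diff(z) >= 0))))
    # time-since-dose: resets to 0 at a dose, else grows by 5/60 min
    for (j in seq_len(ncol(r$drug_time_since))) {
      dt <- diff(r$drug_time_since[, j])
      dosed <- diff(r$drug_cumulative[, j]) > 0
      expect_equal(dt[!dosed], rep(5 / 60, sum(!dosed)), tolerance = 1e-12)
      expect_true(all(r$drug_time_since[-1, j][dosed] == 0))
    }
    # derivatives are lagged first differences / window length, zero backfill
    expect_equal(r$autonomic_derivative[1, ], setNames(rep(0, 15), colnames(r$autonomic_derivative)))
    expect_equal(unname(r$autonomic_derivative[-1, ]),
                 unname(diff(r$autonomic) / 5), tolerance = 1e-12)
  }
  expect_error(cohort_config(n_surgeries = 0), "configuration error")
  expect_error(cohort_config(duration_minutes_range = c(-5, 10)), "configuration error")
})

test_that("pooled prevalence is controlled at the target over a large cohort", {
  co <- generate_cohort(cohort_config(n_surgeries = 101, duration_minutes_range = c(40, 45),
                                      seed = 42))
  y <- unlist(lapply(co, `[[`, "label"))
  expect_gte(length(y), 50000)
  p <- mean(y)
  se <- sqrt(0.06 * 0.94 / length(y))
  expect_lt(abs(p - 0.06), 3 * se)
  expect_gt(p, 0.05)
  expect_lt(p, 0.07)
})

test_that("signal-free configs yield chance-level discrimination", {
  co <- null_cohort(4, c(15, 20), seed = 9)
  y <- unlist(lapply(co, `[[`, "label"))
  a1 <- unlist(lapply(co, function(r) r$autonomic[, 1]))
  expect_lt(abs(auroc(y, a1) - 0.5), 0.03)
})

test_that("increasing response amplitude strictly increases oracle-channel AUROC", {
  aucs <- vapply(c(0.5, 1.5, 3), function(amp) {
    co <- generate_cohort(cohort_config(n_surgeries = 4, duration_minutes_range = c(25, 30),
                                        response_amplitude = amp, seed = 11))
    y <- unlist(lapply(co, `[[`, "label"))
    a1 <- unlist(lapply(co, function(r) r$autonomic[, 1]))
    auroc(y, a1)
  }, numeric(1))
  expect_true(all(diff(aucs) > 0))
})

test_that("cohort CSV round trip is an identity", {
  co <- tiny_cohort(2, c(8, 10), seed = 5)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(length(back), 2L)
  for (i in 1:2) {
    expect_identical(back[[i]]$surgery_id, co[[i]]$surgery_id)
    expect_identical(back[[i]]$window_index, co[[i]]$window_index)
    expect_identical(back[[i]]$label, co[[i]]$label)
    expect_equal(back[[i]]$autonomic, co[[i]]$autonomic, tolerance = 1e-12)
    expect_equal(back[[i]]$drug_time_since, co[[i]]$drug_time_since, tolerance = 1e-12)
  }
})

test_that("malformed cohort files are rejected with the offending column named", {
  co <- tiny_cohort(1, c(8, 10), seed = 5)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  path <- list.files(dir, full.names = TRUE)[1]

  df <- utils::read.csv(path, check.names = FALSE)
  df$label[3] <- 2
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_cohort(dir), "label")

  df$label[3] <- 1
  df$window_index[5] <- 99999
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_cohort(dir), "window_index")

  df$window_index[5] <- 4
  df$surgery_id <- NULL
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_cohort(dir), "surgery_id")
})
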