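test_that("library scaling multiplies tracks by scale_target/raw_total", {
  lib <- make_library(c(0, 10, 0), c(0, 10, 0), raw_total = 5e7)
  sc <- scale_library(lib)
  expect_equal(sc$tracks$read_starts[["+"]]$values[2], 20)
  lib2 <- make_library(c(0, 10, 0), c(0, 10, 0), raw_total = 1e8)
  expect_equal(scale_library(lib2)$tracks$read_starts[["+"]]$values,
               lib2$tracks$read_starts[["+"]]$values)
  expect_error(scale_library(make_library(c(1), c(1), raw_total = 0)), "raw_total")
})

test_that("scaled read starts sum to the target when raw_total counts mapped starts", {
  set.seed(1)
  starts <- round(runif(100, 0, 50))
  lib <- make_library(starts, starts * 2, raw_total = sum(starts))
  sc <- scale_library(lib)
  expect_equal(sum(sc$tracks$read_starts[["+"]]$values), 1e8)
})

test_that("primary position calling enforces both the count and the ratio rule", {
  th <- dtx_thresholds()
  rs <- make_track(c(600, 600, 499, 500, 600, 0, 100), semantics = "read_starts")
  cv <- make_track(c(1000, 1500, 499, 500, 1200, 0, 0))
  got <- call_true_primary_positions(rs, cv, th)
  # 600/1000 = 0.6 in; 600/1500 = 0.4 out; 499 starts out (count rule);
  # 500/500 = 1 in; 600/1200 = 0.5 out (strict); zero-coverage nonzero starts
  # counts as ratio 1 but 100 < 500
  expect_identical(got, c(1L, 4L))
  expect_error(call_true_primary_positions(rs, make_track(c(1, 2)), th), "length")
})

test_that("primary calling is threshold-monotone", {
  set.seed(2)
  rs <- make_track(round(runif(500, 0, 2000)), semantics = "read_starts")
  cv <- make_track(round(runif(500, 0, 2000)))
  lo <- call_true_primary_positions(rs, cv, dtx_thresholds(min_read_starts = 300))
  hi <- call_true_primary_positions(rs, cv, dtx_thresholds(min_read_starts = 800))
  expect_true(all(hi %in% lo))
})

test_that("correction factors normalize primary fractions to their mean", {
  L <- 200
  mk <- function(primary_val, nonprimary_val, cond) {
    starts <- numeric(L); cov <- numeric(L)
    starts[10] <- primary_val; cov[10] <- primary_val          # primary: ratio 1
    starts[100] <- nonprimary_val; cov[100] <- nonprimary_val * 10  # fails ratio
    make_library(starts, cov, raw_total = 1e8, condition = cond)
  }
  # primary fractions 0.4 and 0.8 -> target 0.6 -> factors 1.5 and 0.75
  libs <- list(mk(4000, 6000, "exp"), mk(8000, 2000, "stat"))
  nl <- normalize_libraries(libs)
  expect_equal(nl[[1]]$correction_factor, 1.5)
  expect_equal(nl[[2]]$correction_factor, 0.75)
  # corrected primary counts
  expect_equal(nl[[1]]$tracks$read_starts[["+"]]$values[10], 6000)
  # identical fractions -> all factors 1
  nl2 <- normalize_libraries(list(mk(4000, 6000, "exp"), mk(2000, 3000, "stat")))
  expect_equal(vapply(nl2, `[[`, numeric(1), "correction_factor"), c(1, 1),
               ignore_attr = TRUE)
  # reciprocal factors average to 1 by construction
  expect_equal(mean(1 / vapply(nl, `[[`, numeric(1), "correction_factor")), 1)
})

test_that("a correction factor is invariant under rescaling a library's tracks", {
  L <- 200
  mk <- function(primary_val, nonprimary_val, cond, raw_total) {
    starts <- numeric(L); cov <- numeric(L)
    starts[10] <- primary_val; cov[10] <- primary_val
    starts[100] <- nonprimary_val; cov[100] <- nonprimary_val * 10
    make_library(starts, cov, raw_total = raw_total, condition = cond)
  }
  nl1 <- normalize_libraries(list(mk(4000, 6000, "exp", 1e8), mk(8000, 2000, "stat", 1e8)))
  nl2 <- normalize_libraries(list(mk(8000, 12000, "exp", 2e8), mk(8000, 2000, "stat", 1e8)))
  expect_equal(nl1[[1]]$correction_factor, nl2[[1]]$correction_factor)
})

test_that("a library with zero primary counts aborts with its id", {
  L <- 50
  starts <- numeric(L); cov <- numeric(L)
  starts[10] <- 100; cov[10] <- 1000   # ratio 0.1: never primary
  lib <- make_library(starts, cov, raw_total = 1e8, condition = "exp", id = "badlib")
  expect_error(normalize_libraries(list(lib)), "badlib")
})

test_that("the TSS table unions primary positions with full count vectors", {
  L <- 100
  conds <- dtx_conditions()
  libs <- lapply(seq_along(conds), function(i) {
    starts <- numeric(L); cov <- numeric(L)
    starts[10] <- 1000 + i; cov[10] <- 1000 + i
    if (i <= 3) { starts[50] <- 2000; cov[50] <- 2000 }  # primary in 3 conditions
    if (i > 3) { starts[50] <- 40; cov[50] <- 400 }      # present but not primary
    make_library(starts, cov, raw_total = 1e8, condition = conds[i])
  })
  nl <- normalize_libraries(libs)
  tss <- build_tss_set(nl, raw_libs = libs, strain = "s")
  expect_equal(nrow(tss), 2L)
  row50 <- tss[tss$position == 50, ]
  expect_equal(unname(as.numeric(row50[1, conds[1:3]])), rep(2000, 3),
               tolerance = 0.05)   # correction factors rescale the raw 2000
  # counts at non-primary conditions are reported, not zeroed
  expect_gt(row50[[conds[5]]], 0)
  expect_equal(row50$max_condition, conds[1])
  expect_equal(nrow(build_tss_set(list())), 0L)
})

test_that("TSS recovery on the synthetic strain is essentially perfect", {
  run <- small_run("a")
  truth <- run$truth$tss[run$truth$tss$strain == "a", ]
  called <- paste(run$tss$position, run$tss$strand)
  planted <- paste(truth$position, truth$strand)
  expect_gte(mean(planted %in% called), 0.9)
  expect_gte(mean(called %in% planted), 0.9)
})
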