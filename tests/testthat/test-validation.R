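fake_frame <- function(n) {
  data.frame(AREA_ID = sprintf("A%04d", rep(seq_len(ceiling(n / 6)),
                                            each = 6))[seq_len(n)],
             YEAR = rep(2014:2019, length.out = n),
             Y = rpois(n, 50), E = 10, TIME = rep(-5:0, length.out = n),
             RATE = NA_real_)
}

test_that("masking holds out floor(fraction * N) records and partitions", {
  set.seed(1)
  frame <- fake_frame(1146)
  split <- mask_records(frame, fraction = 0.1, seed = 4)
  expect_identical(nrow(split$holdout), 114L)  # floor(114.6)
  expect_identical(sum(is.na(split$training$Y)), 114L)
  # masked rows keep exposure and time, only the count is hidden
  expect_false(anyNA(split$training$E))
  expect_false(anyNA(split$training$TIME))
  # union reconstructs the frame
  rebuilt <- split$training
  rebuilt$Y[split$masked_idx] <- split$holdout$Y
  expect_identical(rebuilt$Y, frame$Y)

  again <- mask_records(frame, fraction = 0.1, seed = 4)
  expect_identical(again$masked_idx, split$masked_idx)
  other <- mask_records(frame, fraction = 0.1, seed = 5)
  expect_false(identical(other$masked_idx, split$masked_idx))

  expect_error(mask_records(frame, fraction = 0), "between 0 and 1")
  expect_error(mask_records(frame, fraction = 1), "between 0 and 1")
})

test_that("rmse matches its closed forms", {
  expect_identical(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(4, 5, 6), c(1, 2, 3)), 3)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  expect_error(rmse(1:3, 1:2), "equal")
})

test_that("coverage counts closed-interval membership and is monotone", {
  y <- c(1, 5, 10)
  expect_identical(coverage_fraction(rep(-Inf, 3), rep(Inf, 3), y), 1)
  expect_identical(coverage_fraction(y + 1, y + 1, y), 0)
  expect_identical(coverage_fraction(c(1, 6, 9), c(1, 7, 11), y), 2 / 3)
  set.seed(2)
  for (i in 1:10) {
    lo <- rnorm(20); hi <- lo + rexp(20); obs <- rnorm(20, 0, 2)
    base <- coverage_fraction(lo, hi, obs)
    expect_gte(coverage_fraction(lo - rexp(20), hi + rexp(20), obs), base)
  }
  expect_error(coverage_fraction(2, 1, 1.5), "malformed")
})

# straightforward reference implementations of the diagnostics, written
# independently of the package's vectorised versions
ref_rhat <- function(x) {  # x: iterations x chains
  half <- floor(nrow(x) / 2)
  sx <- cbind(x[1:half, ], x[(nrow(x) - half + 1):nrow(x), ])
  r <- rank(sx, ties.method = "average")
  zz <- qnorm((r - 3 / 8) / (length(sx) + 1 / 4))
  sx <- matrix(zz, nrow = half)
  n <- nrow(sx); m <- ncol(sx)
  bm <- colMeans(sx)
  W <- mean(apply(sx, 2, var))
  B <- n * var(bm)
  sqrt(((n - 1) / n * W + B / n) / W)
}

test_that("diagnostics behave on i.i.d. and on pathological chains", {
  set.seed(33)
  iid <- array(rnorm(10000 * 2), dim = c(10000, 2, 1),
               dimnames = list(NULL, NULL, "theta"))
  d <- compute_diagnostics(iid)
  expect_gt(d$rhat, 0.99)
  expect_lt(d$rhat, 1.01)
  expect_equal(d$ess, 20000, tolerance = 0.1)
  expect_equal(d$se_mean, sd(iid) / sqrt(d$ess), tolerance = 1e-12)

  disjoint <- array(c(rnorm(500), rnorm(500) + 50), dim = c(500, 2, 1),
                    dimnames = list(NULL, NULL, "theta"))
  expect_gt(compute_diagnostics(disjoint)$rhat, 1.1)

  expect_error(compute_diagnostics(iid[, 1, , drop = FALSE]), "2 chains")
})

test_that("rank-normalised split R-hat agrees with a reference implementation", {
  set.seed(34)
  for (i in 1:5) {
    x <- matrix(rnorm(400 * 4, sd = exp(rnorm(1))), ncol = 4)
    if (i == 3) x[, 1] <- x[, 1] + 2          # a shifted chain
    if (i == 4) x <- matrix(rt(1600, df = 2), ncol = 4)  # heavy tails
    a <- array(x, dim = c(400, 4, 1), dimnames = list(NULL, NULL, "p"))
    expect_equal(compute_diagnostics(a)$rhat, ref_rhat(x), tolerance = 1e-6)
  }
})

test_that("ESS agrees with coda on autocorrelated chains, roughly", {
  set.seed(35)
  ar <- function(n, phi) as.vector(stats::arima.sim(list(ar = phi), n))
  x <- cbind(ar(2000, 0.6), ar(2000, 0.6))
  a <- array(x, dim = c(2000, 2, 1), dimnames = list(NULL, NULL, "p"))
  ours <- compute_diagnostics(a)$ess
  coda_ess <- sum(apply(x, 2, function(v) coda::effectiveSize(v)))
  expect_equal(ours, coda_ess, tolerance = 0.25)
})

test_that("posterior predictive intervals cover the observed data at large", {
  g <- gen_adjacency(16, "grid")
  st <- build_icar_structure(g)
  frame <- make_test_frame(g, years = 2016:2019, seed = 20)
  fit <- suppressWarnings(fit_bym2(frame, st, chains = 2, iter_warmup = 200,
                                   iter_sampling = 200, seed = 21))
  ppi <- posterior_predictive_intervals(fit, seed = 22)
  expect_identical(nrow(ppi), nrow(frame))
  expect_true(all(ppi$lower <= ppi$upper))
  # in-sample coverage of a well-specified model should be near nominal
  expect_gt(coverage_fraction(ppi$lower, ppi$upper, frame$Y), 0.85)
  # theta-only intervals are narrower than predictive ones
  ppt <- posterior_predictive_intervals(fit, type = "theta", seed = 22)
  expect_true(mean(ppt$upper - ppt$lower <= ppi$upper - ppi$lower) > 0.9)
})

test_that("hold-out validation is a pure function of frame, seed and config", {
  g <- gen_adjacency(16, "grid")
  st <- build_icar_structure(g)
  frame <- make_test_frame(g, years = 2016:2019, seed = 23)
  r1 <- suppressWarnings(validate_holdout(frame, st, fraction = 0.15,
                                          seed = 24, chains = 2,
                                          iter_warmup = 150,
                                          iter_sampling = 150))
  r2 <- suppressWarnings(validate_holdout(frame, st, fraction = 0.15,
                                          seed = 24, chains = 2,
                                          iter_warmup = 150,
                                          iter_sampling = 150))
  expect_identical(r1$rmse_rate, r2$rmse_rate)
  expect_identical(r1$coverage, r2$coverage)
  expect_identical(r1$n_masked, as.integer(floor(0.15 * nrow(frame))))
  expect_gte(r1$coverage, 0)
  expect_lte(r1$coverage, 1)
  expect_gte(r1$rmse_rate, 0)

  f <- withr::local_tempfile(fileext = ".csv")
  s <- withr::local_tempfile(fileext = ".txt")
  write_validation_report(r1, f, s)
  expect_true(file.exists(f) && file.exists(s))
  expect_true(any(grepl("coverage", readLines(s))))
})
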