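test_that("the BYM2 mixture collapses correctly at the corners of rho", {
  eta <- c(0.4, -0.9)
  nu <- c(1.1, 0.2)
  expect_equal(mixed_effect(eta, nu, rho = 0, s = 0.3), nu)
  expect_equal(mixed_effect(eta, nu, rho = 1, s = 0.3), eta / sqrt(0.3))
  expect_equal(mixed_effect(1, 1, rho = 0.5, s = 1), sqrt(2))
  # islands never receive a structured contribution
  expect_equal(mixed_effect(eta, nu, 0.5, s = c(0.3, NA),
                            is_island = c(FALSE, TRUE)),
               c(sqrt(0.5 / 0.3) * 0.4 + sqrt(0.5) * 1.1, sqrt(0.5) * 0.2))
  expect_error(mixed_effect(eta, nu, rho = 1.4, s = 1), "rho")
})

test_that("the linear predictor follows the space-time decomposition", {
  p0 <- bym2_params(beta0 = 0, beta3 = 0, sigma = 1, rho = 0.5,
                    eta = 0, nu = 0)
  expect_equal(log_relative_rate(p0, numeric(0), time = 0, kappa = 0), 0)

  p1 <- bym2_params(beta0 = log(2), beta3 = 0, sigma = 1, rho = 0.5,
                    eta = 0, nu = 0)
  mu <- log_relative_rate(p1, numeric(0), time = c(-5, -2, 0), kappa = 0)
  expect_equal(exp(mu), rep(2, 3))

  # year 2014 sits at time -5 relative to the 2019 reference
  p2 <- bym2_params(beta0 = 0, beta3 = 0.1, sigma = 1, rho = 0.5,
                    eta = 0, nu = 0)
  expect_equal(log_relative_rate(p2, numeric(0), time = -5, kappa = 0), -0.5)
})

test_that("joint log density matches the brute-force oracle", {
  pr <- prior_spec()
  for (seed in c(8, 9, 10)) {
    fx <- make_lp_fixture(seed)
    expect_equal(joint_log_density(fx$params, fx$frame, fx$st, pr),
                 naive_joint_lp(fx$params, fx$frame, fx$st, pr),
                 tolerance = 1e-8)
  }
  # masked rows drop out of the likelihood
  fx <- make_lp_fixture(11)
  fr2 <- fx$frame
  fr2$Y[2] <- NA
  expect_equal(joint_log_density(fx$params, fr2, fx$st, pr),
               naive_joint_lp(fx$params, fr2, fx$st, pr), tolerance = 1e-8)
})

test_that("constant eta on an edge contributes nothing pairwise", {
  g <- adjacency_graph(c("A", "B"), rbind(c("A", "B")))
  st <- build_icar_structure(g)
  frame <- make_test_frame(g, years = 2019, seed = 2)
  pr <- prior_spec()
  base <- list(beta0 = 0.1, beta = numeric(0), beta3 = 0, sigma = 0.5,
               rho = 0.5, nu = c(0, 0))
  # strip likelihood and sum-to-zero penalty; what remains of the change in
  # the density between eta = (a, a) and eta = (0, 0) is the pairwise
  # difference term, which must vanish for a constant field
  delta_pairwise <- function(a) {
    p1 <- bym2_params(base$beta0, base$beta, base$beta3, base$sigma, base$rho,
                      eta = c(a, a), nu = base$nu)
    p0 <- bym2_params(base$beta0, base$beta, base$beta3, base$sigma, base$rho,
                      eta = c(0, 0), nu = base$nu)
    like1 <- sum(dpois(frame$Y, frame$E *
                         exp(base$beta0 + base$sigma *
                               mixed_effect(c(a, a), base$nu, base$rho,
                                            st$s_area)), log = TRUE))
    like0 <- sum(dpois(frame$Y, frame$E *
                         exp(base$beta0 + base$sigma *
                               mixed_effect(c(0, 0), base$nu, base$rho,
                                            st$s_area)), log = TRUE))
    pen1 <- dnorm(2 * a, 0, 0.002, log = TRUE)
    pen0 <- dnorm(0, 0, 0.002, log = TRUE)
    (joint_log_density(p1, frame, st, pr) - like1 - pen1) -
      (joint_log_density(p0, frame, st, pr) - like0 - pen0)
  }
  expect_equal(delta_pairwise(0.7), 0, tolerance = 1e-10)
  expect_equal(delta_pairwise(-1.3), 0, tolerance = 1e-10)
})

test_that("the density peaks where counts sit at their Poisson mean", {
  fx <- make_lp_fixture(12)
  pr <- prior_spec()
  frame <- fx$frame
  kappa <- mixed_effect(fx$params$eta, fx$params$nu, fx$params$rho,
                        fx$st$s_area, fx$st$is_island)
  mu <- log_relative_rate(fx$params, as.matrix(frame$x_IMD), frame$TIME,
                          kappa[match(frame$AREA_ID, fx$st$graph$nodes)])
  lam <- frame$E * exp(mu)
  center <- frame
  center$Y <- as.integer(round(lam))
  lp_center <- joint_log_density(fx$params, center, fx$st, pr)
  for (shift in c(-2, 5)) {
    moved <- center
    moved$Y <- pmax(0L, moved$Y + as.integer(shift * ceiling(sqrt(lam)) * 3L))
    expect_lt(joint_log_density(fx$params, moved, fx$st, pr), lp_center)
  }
})

test_that("the compiled sampler density agrees with the R density", {
  fx <- make_lp_fixture(14, n_areas = 5, years = 2016:2019)
  pr <- prior_spec()
  dat <- ddmap:::sampler_data(fx$frame, fx$st, pr)
  p <- fx$params
  z <- c(p$beta0, p$beta, p$beta3, log(p$sigma), qlogis(p$rho), p$eta, p$nu)
  jac <- log(p$sigma) + log(p$rho * (1 - p$rho))
  expect_equal(ddmap:::hmc_lp(dat, z) - jac,
               joint_log_density(p, fx$frame, fx$st, pr), tolerance = 1e-8)
})

test_that("the compiled gradient matches finite differences", {
  fx <- make_lp_fixture(15, n_areas = 4, years = 2018:2019)
  dat <- ddmap:::sampler_data(fx$frame, fx$st, prior_spec())
  d <- 5 + 2 * 4
  set.seed(1)
  z <- rnorm(d, 0, 0.3)
  ga <- ddmap:::hmc_grad(dat, z)
  gn <- vapply(seq_len(d), function(i) {
    h <- 1e-5
    zp <- z; zp[i] <- z[i] + h
    zm <- z; zm[i] <- z[i] - h
    (ddmap:::hmc_lp(dat, zp) - ddmap:::hmc_lp(dat, zm)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(ga - gn) / (abs(gn) + 1)), 1e-5)
})

test_that("fits are reproducible and summaries recomputable from draws", {
  g <- gen_adjacency(9, "grid")
  st <- build_icar_structure(g)
  frame <- make_test_frame(g, years = 2017:2019, seed = 5)
  fit1 <- suppressWarnings(fit_bym2(frame, st, chains = 2, iter_warmup = 100,
                                    iter_sampling = 100, seed = 42))
  fit2 <- suppressWarnings(fit_bym2(frame, st, chains = 2, iter_warmup = 100,
                                    iter_sampling = 100, seed = 42))
  expect_identical(fit1$draws, fit2$draws)
  fit3 <- suppressWarnings(fit_bym2(frame, st, chains = 2, iter_warmup = 100,
                                    iter_sampling = 100, seed = 43))
  expect_false(identical(fit1$draws, fit3$draws))

  # summary quantiles are the 2.5/50/97.5 empirical percentiles of the draws
  sig <- as.vector(fit1$draws[, , "sigma"])
  row <- fit1$summary[fit1$summary$parameter == "sigma", ]
  expect_equal(row$median, unname(quantile(sig, 0.5)))
  expect_equal(row$q2.5, unname(quantile(sig, 0.025)))
  expect_equal(row$q97.5, unname(quantile(sig, 0.975)))

  expect_error(fit_bym2(frame, st, chains = 1), "2 chains")
})

test_that("with vanishing random effects beta0 recovers the GLM intercept", {
  g <- gen_adjacency(16, "grid")
  st <- build_icar_structure(g)
  truth <- gen_truth(g, list(beta0 = log(8), beta3 = 0, sigma = 1e-6,
                             rho = 0.5), seed = 6)
  frame <- gen_area_year_counts(truth, g, 2015:2019, 30000, seed = 7)
  frame$RATE <- frame$Y / frame$E
  class(frame) <- c("model_frame", "data.frame")
  fit <- suppressWarnings(fit_bym2(frame, st, chains = 2, iter_warmup = 300,
                                   iter_sampling = 300, seed = 8))
  glm_b0 <- log(mean(frame$Y / frame$E))
  row <- fit$summary[fit$summary$parameter == "beta0", ]
  expect_lt(abs(row$median - glm_b0), 3 * row$sd + 0.02)
})

test_that("rate summaries are keyed by area-year with percentile intervals", {
  g <- gen_adjacency(6, "grid")
  st <- build_icar_structure(g)
  frame <- make_test_frame(g, years = 2018:2019, seed = 9)
  fit <- suppressWarnings(fit_bym2(frame, st, chains = 2, iter_warmup = 100,
                                   iter_sampling = 100, seed = 10))
  s <- summarize_fit(fit)
  expect_identical(nrow(s$theta), nrow(frame))
  expect_true(all(s$theta$theta_q2.5 <= s$theta$theta_median))
  expect_true(all(s$theta$theta_median <= s$theta$theta_q97.5))

  # chain order cannot matter: percentiles are computed on pooled draws
  fitp <- fit
  fitp$draws <- fit$draws[, 2:1, , drop = FALSE]
  sp <- summarize_fit(fitp)
  expect_equal(sp$theta$theta_median, s$theta$theta_median)
})
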