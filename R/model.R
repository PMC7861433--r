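#' Prior specification for the BYM2 space-time model
#'
#' Families follow common disease-mapping practice: weakly-informative
#' normals on the fixed effects, a half-normal on the combined
#' random-effect standard deviation and a Beta (default flat) on the
#' spatial mixing fraction.
#'
#' @param beta_sd Normal sd for `beta0`, `beta` and `beta3` (default 5).
#' @param sigma_scale Half-normal scale for `sigma` (default 1).
#' @param rho_shape Length-2 Beta shape for `rho`; `c(1, 1)` is uniform.
#'   `c(0.5, 0.5)` gives a penalised-complexity-flavoured U-shape favouring
#'   the simpler pure-spatial / pure-heterogeneity corners.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(beta_sd = 5, sigma_scale = 1, rho_shape = c(1, 1)) {
  stopifnot(beta_sd > 0, sigma_scale > 0, length(rho_shape) == 2,
            all(rho_shape > 0))
  structure(list(beta_sd = beta_sd, sigma_scale = sigma_scale,
                 rho_shape = as.numeric(rho_shape)),
            class = "prior_spec")
}

#' @method print prior_spec
#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf(
    "<prior_spec> beta* ~ N(0, %g); sigma ~ half-N(0, %g); rho ~ Beta(%g, %g)\n",
    x$beta_sd, x$sigma_scale, x$rho_shape[1], x$rho_shape[2]))
  invisible(x)
}

#' Model parameter bundle
#'
#' Validated container for one point in the BYM2 space-time parameter
#' space. Island areas (per `structure`) must have `eta = 0`; they are
#' zeroed here.
#'
#' @param beta0,beta,beta3 Fixed effects (log-rate scale).
#' @param sigma Combined random-effect sd (> 0).
#' @param rho Spatial mixing fraction in \[0, 1\].
#' @param eta,nu Structured / unstructured effects (one per area).
#' @param structure Optional `icar_structure` used to zero island `eta`.
#' @return An object of class `bym2_params`.
#' @export
bym2_params <- function(beta0, beta = numeric(0), beta3, sigma, rho,
                        eta, nu, structure = NULL) {
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]", call. = FALSE)
  if (length(eta) != length(nu)) stop("eta and nu lengths differ", call. = FALSE)
  if (!is.null(structure)) eta[structure$is_island] <- 0
  structure(list(beta0 = beta0, beta = as.numeric(beta), beta3 = beta3,
                 sigma = sigma, rho = rho, eta = eta, nu = nu),
            class = "bym2_params")
}

#' BYM2 mixed random effect
#'
#' Combines the structured and unstructured area effects into the BYM2
#' mixture \eqn{\kappa_i = \eta_i \sqrt{\rho/s} + \nu_i \sqrt{1-\rho}},
#' where \eqn{s} is the component's ICAR scaling factor, so that
#' \eqn{\kappa} has unit typical marginal variance and \eqn{\rho} is the
#' fraction of that variance carried by spatial structure. Island areas
#' (no neighbours, `is_island`) take \eqn{\kappa_i = \nu_i\sqrt{1-\rho}}:
#' the structured part is identically zero.
#'
#' @param eta,nu Numeric vectors of structured / unstructured effects.
#' @param rho Mixing fraction in \[0, 1\].
#' @param s Scaling factor(s): scalar or per-area vector (`NA` allowed on
#'   islands).
#' @param is_island Logical per area; default all `FALSE`.
#' @return Numeric vector of kappa values.
#' @export
mixed_effect <- function(eta, nu, rho, s, is_island = NULL) {
  if (length(rho) != 1L || is.na(rho) || rho < 0 || rho > 1) {
    stop("rho must be a single value in [0, 1]", call. = FALSE)
  }
  if (is.null(is_island)) is_island <- rep(FALSE, length(eta))
  s <- rep_len(s, length(eta))
  if (any(!is_island & (is.na(s) | s <= 0))) {
    stop("scaling factor must be positive for non-island areas", call. = FALSE)
  }
  a <- ifelse(is_island, 0, sqrt(rho / ifelse(is_island, 1, s)))
  a * eta + sqrt(1 - rho) * nu
}

#' Log relative rate of an area-year record
#'
#' The linear predictor of the model:
#' \eqn{\mu_{ij} = \beta_0 + \beta x_{ij} + \kappa_i\sigma + \beta_3\,time_{ij}},
#' with the relative rate \eqn{\theta_{ij} = e^{\mu_{ij}}} interpreted as
#' DDD per 1,000 population. `time` is the calendar year minus the
#' reference year 2019.
#'
#' @param params A [bym2_params()].
#' @param x Covariate vector/matrix (rows = records); may be zero-length.
#' @param time Year offset(s) from 2019.
#' @param kappa Pre-computed mixed effect per record (see [mixed_effect()]).
#' @return Numeric vector of `mu` values.
#' @export
log_relative_rate <- function(params, x, time, kappa) {
  p <- length(params$beta)
  xb <- 0
  if (p > 0L) {
    X <- matrix(x, ncol = p)
    if (nrow(X) != length(time) && nrow(X) != 1L) {
      stop("covariate rows do not match records", call. = FALSE)
    }
    xb <- as.vector(X %*% params$beta)
  } else if (length(x) > 0L) {
    stop("covariates supplied but beta is empty", call. = FALSE)
  }
  params$beta0 + xb + kappa * params$sigma + params$beta3 * time
}

#' Joint log posterior density (unnormalised in eta)
#'
#' The full model density on the natural parameter scale:
#' Poisson log-likelihood \eqn{\sum_{ij}\log f(y_{ij}\mid E_{ij}\theta_{ij})},
#' the ICAR improper prior on eta in pairwise-difference form
#' \eqn{-\tfrac12\sum_{i\sim j}(\eta_i-\eta_j)^2} with a per-component soft
#' sum-to-zero constraint (the component sum gets a tight
#' `Normal(0, 0.001 m)` density, `m` the component size), standard-normal
#' terms for nu, and the [prior_spec()] densities of the remaining
#' parameters. Frame rows with `Y = NA` (masked records) contribute no
#' likelihood term. Transformation Jacobians are *not* included; the
#' sampler adds them internally on its unconstrained scale.
#'
#' @param params A [bym2_params()] (island `eta` is ignored/zeroed).
#' @param frame A model frame ([aggregate_to_area_year()]).
#' @param structure An [build_icar_structure()] for the frame's areas.
#' @param priors A [prior_spec()].
#' @return A single finite number for interior parameter values.
#' @export
joint_log_density <- function(params, frame, structure, priors = prior_spec()) {
  areas <- structure$graph$nodes
  if (length(params$eta) != length(areas)) {
    stop("eta length does not match the graph", call. = FALSE)
  }
  eta <- params$eta
  eta[structure$is_island] <- 0
  if (any(!is.finite(c(params$beta0, params$beta, params$beta3, params$sigma,
                       params$rho, eta, params$nu)))) {
    stop("non-finite parameter values", call. = FALSE)
  }
  kappa_area <- mixed_effect(eta, params$nu, params$rho, structure$s_area,
                             structure$is_island)
  obs <- frame[!is.na(frame$Y), , drop = FALSE]
  xcols <- frame_covariate_cols(obs)
  X <- if (length(xcols)) as.matrix(obs[, xcols, drop = FALSE]) else numeric(0)
  mu <- log_relative_rate(params, X, obs$TIME,
                          kappa_area[match(obs$AREA_ID, areas)])
  lp <- sum(stats::dpois(obs$Y, obs$E * exp(mu), log = TRUE))

  edges <- structure$graph$edges
  if (nrow(edges) > 0L) {
    d <- eta[match(edges[, 1], areas)] - eta[match(edges[, 2], areas)]
    lp <- lp - 0.5 * sum(d^2)
  }
  comp <- structure$components
  for (c in seq_along(structure$scaling)) {
    if (!is.na(structure$scaling[c])) {
      m <- sum(comp == c)
      lp <- lp + stats::dnorm(sum(eta[comp == c]), 0, 0.001 * m, log = TRUE)
    }
  }
  lp <- lp + sum(stats::dnorm(params$nu, 0, 1, log = TRUE))
  lp <- lp + sum(stats::dnorm(c(params$beta0, params$beta, params$beta3),
                              0, priors$beta_sd, log = TRUE))
  lp <- lp + log(2) + stats::dnorm(params$sigma, 0, priors$sigma_scale,
                                   log = TRUE)
  lp <- lp + stats::dbeta(params$rho, priors$rho_shape[1], priors$rho_shape[2],
                          log = TRUE)
  lp
}

# Pack the sampler's data list from frame + structure + priors.
sampler_data <- function(frame, structure, priors) {
  areas <- structure$graph$nodes
  obs <- frame[!is.na(frame$Y), , drop = FALSE]
  if (nrow(obs) == 0L) stop("no observed records to fit", call. = FALSE)
  if (!all(frame$AREA_ID %in% areas)) {
    stop("frame contains areas absent from the graph", call. = FALSE)
  }
  xcols <- frame_covariate_cols(frame)
  X <- as.matrix(obs[, xcols, drop = FALSE])
  storage.mode(X) <- "double"
  comp <- structure$components
  soft_sd <- 0.001 * as.numeric(table(comp))
  list(
    y = as.numeric(obs$Y), E = as.numeric(obs$E), tvec = as.numeric(obs$TIME),
    X = X,
    area = match(obs$AREA_ID, areas) - 1L,
    e1 = match(structure$graph$edges[, 1], areas) - 1L,
    e2 = match(structure$graph$edges[, 2], areas) - 1L,
    comp = as.integer(comp) - 1L,
    s_area = ifelse(is.na(structure$s_area), 1, structure$s_area),
    island = as.logical(structure$is_island),
    comp_soft_sd = soft_sd,
    beta_sd = priors$beta_sd, sigma_scale = priors$sigma_scale,
    rho_a = priors$rho_shape[1], rho_b = priors$rho_shape[2],
    n_area = length(areas), p = ncol(X)
  )
}

param_names <- function(xcols, areas) {
  c("beta0",
    if (length(xcols)) paste0("beta[", sub("^x_", "", xcols), "]"),
    "beta3", "sigma", "rho",
    paste0("eta[", areas, "]"), paste0("nu[", areas, "]"))
}

#' Fit the BYM2 space-time Poisson model
#'
#' Samples the posterior of [joint_log_density()] by Hamiltonian Monte
#' Carlo with analytic gradients (compiled core): unconstrained
#' parameterisation (`log sigma`, `logit rho`), dual-averaging step-size
#' adaptation towards a target acceptance rate, diagonal mass-matrix
#' adaptation during warmup, and jittered leapfrog path lengths. Island
#' areas' structured effects are frozen at zero. Runs are fully
#' reproducible from `seed`; chains are run sequentially off one seeded
#' stream.
#'
#' Convergence is assessed with split rank-normalised R-hat and
#' autocorrelation-based effective sample size on every parameter; a fit
#' whose worst R-hat exceeds 1.01 or whose smallest ESS falls under 400
#' carries a warning in `$warnings` (it is returned, never discarded).
#'
#' @param frame Model frame; rows with `Y = NA` are treated as missing and
#'   excluded from the likelihood (their areas still borrow strength).
#' @param structure [build_icar_structure()] over the frame's areas.
#' @param priors A [prior_spec()].
#' @param chains Number of chains (>= 2).
#' @param iter_warmup,iter_sampling Iterations per chain.
#' @param seed Integer seed.
#' @param control List: `target_accept` (0.9), `path_length` (32, the
#'   nominal trajectory length in metric-scaled units; long trajectories
#'   are what traverse the weakly identified eta/nu trade-off),
#'   `max_leapfrog` (512), `dense_metric` (`FALSE`; switch to a dense
#'   Gauss-Newton metric after the first warmup phase).
#' @return An object of class `bym2_fit`: `draws` (array iterations x
#'   chains x parameters, natural scale), `summary` (per-parameter table
#'   with median, 2.5/97.5 percentiles, mean, sd, se_mean, ess, rhat),
#'   `sampler` (step sizes, acceptance, divergences), `warnings`,
#'   plus the inputs needed downstream.
#' @export
fit_bym2 <- function(frame, structure, priors = prior_spec(), chains = 4,
                     iter_warmup = 1000, iter_sampling = 1000, seed = 1L,
                     control = list()) {
  if (chains < 2) stop("at least 2 chains are required", call. = FALSE)
  if (iter_warmup < 1 || iter_sampling < 1) {
    stop("iterations must be positive", call. = FALSE)
  }
  ctl <- utils::modifyList(list(target_accept = 0.9, path_length = 32,
                                max_leapfrog = 512L, dense_metric = FALSE),
                           control)
  data <- sampler_data(frame, structure, priors)
  xcols <- frame_covariate_cols(frame)
  areas <- structure$graph$nodes
  n <- data$n_area; p <- data$p
  d <- 4L + p + 2L * n
  obs <- frame[!is.na(frame$Y), ]
  b0_init <- log(max(mean(obs$Y / obs$E), 1e-3))

  res <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(chains), function(ch) {
      init <- c(b0_init, rep(0, p), 0, log(0.5), 0, rep(0, 2L * n)) +
        stats::rnorm(d, 0, 0.1)
      init[5L + p + which(data$island) - 1L] <- 0  # island eta frozen at 0
      hmc_run(data, init, as.integer(iter_warmup), as.integer(iter_sampling),
              ctl$target_accept, ctl$path_length, as.integer(ctl$max_leapfrog),
              isTRUE(ctl$dense_metric))
    })
  })

  pn <- param_names(xcols, areas)
  draws <- array(NA_real_, dim = c(iter_sampling, chains, d),
                 dimnames = list(NULL, paste0("chain", seq_len(chains)), pn))
  for (ch in seq_len(chains)) {
    m <- res[[ch]]$draws
    m[, 3L + p] <- exp(m[, 3L + p])                   # sigma
    m[, 4L + p] <- stats::plogis(m[, 4L + p])         # rho
    draws[, ch, ] <- m
  }
  diag_tab <- compute_diagnostics(draws)
  qs <- apply(draws, 3, function(v) stats::quantile(v, c(0.5, 0.025, 0.975),
                                                    names = FALSE))
  summary_tab <- data.frame(
    parameter = pn,
    median = qs[1, ], q2.5 = qs[2, ], q97.5 = qs[3, ],
    mean = apply(draws, 3, mean), sd = apply(draws, 3, stats::sd),
    se_mean = diag_tab$se_mean, ess = diag_tab$ess, rhat = diag_tab$rhat,
    row.names = NULL, stringsAsFactors = FALSE
  )
  divergences <- sum(vapply(res, function(r) r$divergences, 0))
  core <- !grepl("^(eta|nu)\\[", pn)  # diagnostics thresholds on model-level parameters
  warnings <- character(0)
  worst_rhat <- suppressWarnings(max(diag_tab$rhat[core], na.rm = TRUE))
  min_ess <- suppressWarnings(min(diag_tab$ess[core], na.rm = TRUE))
  if (is.finite(worst_rhat) && worst_rhat > 1.01) {
    warnings <- c(warnings, sprintf("max R-hat %.3f exceeds 1.01", worst_rhat))
  }
  if (is.finite(min_ess) && min_ess < 400) {
    warnings <- c(warnings, sprintf("min ESS %.0f below 400", min_ess))
  }
  if (divergences > 0) {
    warnings <- c(warnings, sprintf("%d divergent transition(s)", divergences))
  }
  for (w in warnings) warning(w, call. = FALSE)

  structure(
    list(draws = draws, summary = summary_tab, param_names = pn,
         frame = frame, structure = structure, priors = priors,
         sampler = list(
           chains = chains, iter_warmup = iter_warmup,
           iter_sampling = iter_sampling, seed = as.integer(seed),
           step_size = vapply(res, function(r) r$step_size, 0),
           accept_rate = vapply(res, function(r) r$accept_rate, 0),
           divergences = divergences, control = ctl),
         warnings = warnings),
    class = "bym2_fit"
  )
}

#' @method print bym2_fit
#' @export
print.bym2_fit <- function(x, ...) {
  cat(sprintf("<bym2_fit> %d chains x %d draws | seed %d\n",
              x$sampler$chains, x$sampler$iter_sampling, x$sampler$seed))
  core <- x$summary[!grepl("^(eta|nu)\\[", x$summary$parameter), ]
  print(core, digits = 3, row.names = FALSE)
  if (length(x$warnings)) cat("warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

# Flatten the draws array to (total draws) x (params), chains stacked.
flat_draws <- function(fit) {
  d <- dim(fit$draws)
  m <- matrix(aperm(fit$draws, c(1, 2, 3)), nrow = d[1] * d[2], ncol = d[3])
  colnames(m) <- dimnames(fit$draws)[[3]]
  m
}

# Per-draw matrix of theta (relative rates) for the rows of `frame`:
# (total draws) x nrow(frame).
theta_draw_matrix <- function(fit, frame = fit$frame) {
  dm <- flat_draws(fit)
  areas <- fit$structure$graph$nodes
  xcols <- frame_covariate_cols(frame)
  p <- length(xcols)
  beta0 <- dm[, "beta0"]
  beta3 <- dm[, "beta3"]
  sigma <- dm[, "sigma"]
  rho <- dm[, "rho"]
  eta <- dm[, paste0("eta[", areas, "]"), drop = FALSE]
  nu <- dm[, paste0("nu[", areas, "]"), drop = FALSE]
  s <- ifelse(is.na(fit$structure$s_area), 1, fit$structure$s_area)
  isl <- fit$structure$is_island
  a <- sqrt(outer(rho, 1 / s))          # draws x areas
  a[, isl] <- 0
  kappa <- a * eta + sqrt(1 - rho) * nu
  ai <- match(frame$AREA_ID, areas)
  xb <- if (p > 0) dm[, paste0("beta[", sub("^x_", "", xcols), "]"),
                      drop = FALSE] %*% t(as.matrix(frame[, xcols, drop = FALSE]))
        else 0
  mu <- beta0 + xb + sigma * kappa[, ai, drop = FALSE] +
    outer(beta3, frame$TIME)
  exp(mu)
}

#' Posterior summaries of parameters and area-year rates
#'
#' Medians and central 95% credible intervals (2.5th and 97.5th
#' percentiles) computed from the posterior draws: one table for the model
#' parameters and one table of relative rates `theta` (DDD per 1,000
#' population) keyed by area and year.
#'
#' @param fit A [fit_bym2()] result.
#' @param frame Records to summarise rates for; defaults to the fitted frame.
#' @return List with `parameters` (the fit's summary table) and `theta`
#'   (data frame `AREA_ID, YEAR, theta_median, theta_q2.5, theta_q97.5`).
#' @export
summarize_fit <- function(fit, frame = fit$frame) {
  stopifnot(inherits(fit, "bym2_fit"))
  if (length(fit$draws) == 0L) stop("empty draws", call. = FALSE)
  th <- theta_draw_matrix(fit, frame)
  qs <- apply(th, 2, stats::quantile, probs = c(0.5, 0.025, 0.975),
              names = FALSE)
  theta <- data.frame(
    AREA_ID = frame$AREA_ID, YEAR = frame$YEAR,
    theta_median = qs[1, ], theta_q2.5 = qs[2, ], theta_q97.5 = qs[3, ],
    stringsAsFactors = FALSE
  )
  list(parameters = fit$summary, theta = theta)
}
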