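# term-by-term oracle for the joint density, written as plain loops,
# independent of the vectorised implementation and of the compiled sampler
naive_joint_lp <- function(params, frame, structure, priors) {
  areas <- structure$graph$nodes
  eta <- params$eta
  eta[structure$is_island] <- 0
  xcols <- grep("^x_", names(frame), value = TRUE)
  lp <- 0
  for (r in seq_len(nrow(frame))) {
    row <- frame[r, ]
    if (is.na(row$Y)) next
    i <- match(row$AREA_ID, areas)
    kap <- if (structure$is_island[i]) {
      sqrt(1 - params$rho) * params$nu[i]
    } else {
      sqrt(params$rho / structure$s_area[i]) * eta[i] +
        sqrt(1 - params$rho) * params$nu[i]
    }
    mu <- params$beta0 + params$beta3 * row$TIME + kap * params$sigma
    if (length(xcols)) {
      for (k in seq_along(xcols)) {
        mu <- mu + params$beta[k] * row[[xcols[k]]]
      }
    }
    lam <- row$E * exp(mu)
    lp <- lp + row$Y * log(lam) - lam - lgamma(row$Y + 1)
  }
  for (e in seq_len(nrow(structure$graph$edges))) {
    d <- eta[match(structure$graph$edges[e, 1], areas)] -
      eta[match(structure$graph$edges[e, 2], areas)]
    lp <- lp - d^2 / 2
  }
  for (c in seq_along(structure$scaling)) {
    if (is.na(structure$scaling[c])) next
    members <- which(structure$components == c)
    lp <- lp + dnorm(sum(eta[members]), 0, 0.001 * length(members), log = TRUE)
  }
  for (i in seq_along(params$nu)) lp <- lp + dnorm(params$nu[i], log = TRUE)
  lp <- lp + dnorm(params$beta0, 0, priors$beta_sd, log = TRUE)
  for (b in params$beta) lp <- lp + dnorm(b, 0, priors$beta_sd, log = TRUE)
  lp <- lp + dnorm(params$beta3, 0, priors$beta_sd, log = TRUE)
  lp <- lp + log(2) + dnorm(params$sigma, 0, priors$sigma_scale, log = TRUE)
  lp <- lp + dbeta(params$rho, priors$rho_shape[1], priors$rho_shape[2],
                   log = TRUE)
  lp
}

make_lp_fixture <- function(seed = 8, n_areas = 3, years = 2018:2019) {
  set.seed(seed)
  g <- path_graph(n_areas)
  st <- build_icar_structure(g)
  frame <- make_test_frame(g, years = years, population = 8000, seed = seed)
  frame$x_IMD <- rnorm(nrow(frame))
  params <- bym2_params(
    beta0 = rnorm(1), beta = rnorm(1), beta3 = rnorm(1, 0, 0.1),
    sigma = runif(1, 0.2, 1), rho = runif(1),
    eta = rnorm(n_areas, 0, 0.5), nu = rnorm(n_areas), structure = st
  )
  list(g = g, st = st, frame = frame, params = params)
}
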