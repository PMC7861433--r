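#' MCMC convergence diagnostics
#'
#' Computes, for every parameter: split-chain rank-normalised R-hat,
#' autocorrelation-based effective sample size (Geyer initial monotone
#' sequence on split chains), and the Monte Carlo standard error of the
#' posterior mean (`sd / sqrt(ESS)`).
#'
#' Chains are split in half before anything else, so within-chain trends
#' inflate R-hat as they should. For R-hat the pooled draws are replaced by
#' their normal scores (rank-normalisation) to be robust to heavy tails.
#' The ESS uses the chain-averaged autocovariance combined with the
#' between-chain variance, paired into Geyer sums truncated at the first
#' negative pair and enforced monotone.
#'
#' @param draws 3-d array `iterations x chains x parameters` (with
#'   parameter dimnames), or a `bym2_fit`.
#' @return Data frame `parameter, se_mean, ess, rhat`. Constant draws give
#'   `NA` diagnostics.
#' @export
compute_diagnostics <- function(draws) {
  if (inherits(draws, "bym2_fit")) draws <- draws$draws
  stopifnot(is.array(draws), length(dim(draws)) == 3)
  n_chain <- dim(draws)[2]
  if (n_chain < 2) stop("at least 2 chains are required", call. = FALSE)
  if (dim(draws)[1] < 4) stop("at least 4 draws per chain are required",
                              call. = FALSE)
  pn <- dimnames(draws)[[3]]
  if (is.null(pn)) pn <- paste0("param", seq_len(dim(draws)[3]))
  out <- data.frame(parameter = pn, se_mean = NA_real_, ess = NA_real_,
                    rhat = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_len(dim(draws)[3])) {
    x <- draws[, , k, drop = FALSE]
    dim(x) <- dim(draws)[1:2]
    sx <- split_chains(x)
    if (stats::sd(as.vector(x)) == 0) next
    out$rhat[k] <- rhat_basic(rank_normalize(sx))
    ess <- ess_basic(sx)
    out$ess[k] <- ess
    out$se_mean[k] <- stats::sd(as.vector(x)) / sqrt(ess)
  }
  out
}

# iterations x chains -> first/second halves side by side (2x chains)
split_chains <- function(x) {
  n <- nrow(x)
  h <- n %/% 2L
  cbind(x[seq_len(h), , drop = FALSE],
        x[seq.int(n - h + 1L, n), , drop = FALSE])
}

# Normal scores of the pooled draws, reshaped back to chains.
rank_normalize <- function(x) {
  r <- rank(as.vector(x), ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  matrix(z, nrow = nrow(x), ncol = ncol(x))
}

# Classic split R-hat: sqrt(var_plus / W) on the (already split) chains.
rhat_basic <- function(x) {
  n <- nrow(x)
  means <- colMeans(x)
  vars <- apply(x, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  var_plus <- (n - 1) / n * W + B / n
  if (W == 0) return(NA_real_)
  sqrt(var_plus / W)
}

# Bulk ESS on (already split) chains via chain-averaged autocovariance and
# Geyer's initial monotone positive sequence.
ess_basic <- function(x) {
  n <- nrow(x)
  m <- ncol(x)
  acov <- apply(x, 2, function(v) {
    stats::acf(v, lag.max = n - 1L, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1, 1]
  })
  chain_var <- acov[1, ] * n / (n - 1)
  W <- mean(chain_var)
  var_plus <- mean(acov[1, ]) * (n - 1) / n + stats::var(colMeans(x))
  if (var_plus == 0) return(NA_real_)
  rho <- 1 - (W - rowMeans(acov)) / var_plus
  rho[1] <- 1
  # pair sums P_t = rho_{2t} + rho_{2t+1}; stop at first negative, make
  # the sequence non-increasing
  max_t <- (n - 1) %/% 2L
  tau <- 0
  prev <- Inf
  for (t in 0:max_t) {
    p <- rho[2 * t + 1] + if (2 * t + 2 <= n) rho[2 * t + 2] else 0
    if (t > 0 && p < 0) break
    p <- min(p, prev)
    prev <- p
    tau <- tau + p
  }
  tau <- max(2 * tau - 1, 1 / log10(n * m + 1))  # tau = -1 + 2*sum P_t
  n * m / tau
}
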