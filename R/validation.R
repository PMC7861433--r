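#' Randomly mask a fraction of area-year records
#'
#' Hold-out split for the two-stage validation: a simple random sample of
#' `floor(fraction * N)` records (without replacement) has its count `Y`
#' hidden; exposure, covariates and time are kept so the model can predict
#' the missing counts. The union of the two outputs reconstructs the frame.
#'
#' @param frame A model frame.
#' @param fraction Fraction in (0, 1); defaults to 0.10.
#' @param seed Integer seed.
#' @return List: `training` (full frame with `Y = NA` on masked rows),
#'   `holdout` (the masked rows with their true `Y`), `masked_idx`
#'   (row indices into `frame`).
#' @export
mask_records <- function(frame, fraction = 0.1, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) {
    stop("fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  n_mask <- floor(fraction * nrow(frame))
  if (n_mask < 1) stop("fraction masks no records at this frame size",
                       call. = FALSE)
  idx <- withr::with_seed(as.integer(seed),
                          sort(sample.int(nrow(frame), n_mask)))
  training <- frame
  training$Y[idx] <- NA_integer_
  training$RATE[idx] <- NA_real_
  list(training = training, holdout = frame[idx, , drop = FALSE],
       masked_idx = idx)
}

#' Root mean squared error
#'
#' @param predicted,observed Equal-length numeric vectors (hold-out scoring uses
#'   the DDD-per-1,000 rate scale, predictions being posterior-median
#'   predicted rates).
#' @return `sqrt(mean((predicted - observed)^2))`.
#' @export
rmse <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(predicted) < 1L) {
    stop("predicted and observed must have equal positive length",
         call. = FALSE)
  }
  sqrt(mean((predicted - observed)^2))
}

#' Interval coverage of held-out observations
#'
#' Fraction of observations falling inside their (closed) intervals.
#' Widening any interval can never decrease the result.
#'
#' @param lower,upper Interval endpoints, one per observation.
#' @param observed Held-out values.
#' @return Fraction in \[0, 1\].
#' @export
coverage_fraction <- function(lower, upper, observed) {
  if (length(lower) != length(observed) || length(upper) != length(observed)) {
    stop("one interval is required per observation", call. = FALSE)
  }
  if (any(lower > upper, na.rm = TRUE)) {
    stop("malformed interval (lower > upper)", call. = FALSE)
  }
  mean(observed >= lower & observed <= upper)
}

#' Posterior predictive intervals for area-year counts
#'
#' For each requested record and each posterior draw, simulates a replicate
#' count `y ~ Poisson(E * theta_draw)` and takes the 2.5th and 97.5th
#' percentiles across draws — i.e. the interval includes Poisson sampling
#' noise on top of parameter uncertainty. `type = "theta"` instead returns
#' percentile intervals of the latent mean `E * theta` only.
#'
#' @param fit A [fit_bym2()].
#' @param frame Records to predict (defaults to the fitted frame).
#' @param type `"predictive"` (default) or `"theta"`.
#' @param seed Seed for the Poisson replicates.
#' @return Data frame `AREA_ID, YEAR, pred_median, lower, upper` on the
#'   count scale, plus `rate_median` (posterior-median predicted rate).
#' @export
posterior_predictive_intervals <- function(fit, frame = fit$frame,
                                           type = c("predictive", "theta"),
                                           seed = 1L) {
  type <- match.arg(type)
  th <- theta_draw_matrix(fit, frame)           # draws x records
  lam <- sweep(th, 2, frame$E, `*`)
  yrep <- if (type == "predictive") {
    withr::with_seed(as.integer(seed),
                     matrix(stats::rpois(length(lam), lam), nrow = nrow(lam)))
  } else lam
  qs <- apply(yrep, 2, stats::quantile, probs = c(0.5, 0.025, 0.975),
              names = FALSE)
  data.frame(
    AREA_ID = frame$AREA_ID, YEAR = frame$YEAR,
    pred_median = qs[1, ], lower = qs[2, ], upper = qs[3, ],
    rate_median = apply(th, 2, stats::median),
    stringsAsFactors = FALSE
  )
}

#' Hold-out validation of the space-time model
#'
#' The two-stage sensitivity check as one call: mask `fraction` of the
#' records, refit the model on the rest, then (1) score the RMSE of
#' posterior-median predicted rates against the held-out observed rates
#' (count-scale RMSE is also reported), and (2) compute the share of
#' held-out counts inside their 95% posterior predictive intervals.
#'
#' @param frame Model frame with complete `Y`.
#' @param structure [build_icar_structure()] for the frame's areas.
#' @param priors A [prior_spec()].
#' @param fraction Mask fraction (default 0.1).
#' @param seed Integer seed driving the mask, the sampler and the
#'   predictive replicates.
#' @param interval_type Passed to [posterior_predictive_intervals()].
#' @param ... Passed to [fit_bym2()] (chains, iterations, control).
#' @return An object of class `validation_report`: list with `rmse_rate`,
#'   `rmse_count`, `coverage`, `n_masked`, `masked_idx`, `holdout` (scored
#'   table), `fit`.
#' @export
validate_holdout <- function(frame, structure, priors = prior_spec(),
                             fraction = 0.1, seed = 1L,
                             interval_type = "predictive", ...) {
  split <- mask_records(frame, fraction, seed = seed)
  fit <- fit_bym2(split$training, structure, priors, seed = seed, ...)
  pred <- posterior_predictive_intervals(fit, split$holdout,
                                         type = interval_type, seed = seed)
  obs_rate <- split$holdout$Y / split$holdout$E
  report <- list(
    rmse_rate = rmse(pred$rate_median, obs_rate),
    rmse_count = rmse(pred$pred_median, split$holdout$Y),
    coverage = coverage_fraction(pred$lower, pred$upper, split$holdout$Y),
    n_masked = nrow(split$holdout),
    fraction = fraction,
    masked_idx = split$masked_idx,
    holdout = cbind(split$holdout[, c("AREA_ID", "YEAR", "Y")], pred[, -(1:2)]),
    fit = fit
  )
  class(report) <- "validation_report"
  report
}

#' @method print validation_report
#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "<validation_report> %d records held out (%.0f%%)\n  RMSE (rate scale)  %.4f\n  RMSE (count scale) %.4f\n  95%% predictive interval coverage %.3f\n",
    x$n_masked, 100 * x$fraction, x$rmse_rate, x$rmse_count, x$coverage))
  invisible(x)
}

#' Write a validation report as CSV + text summary
#' @param report A `validation_report`.
#' @param csv_path,summary_path Output files (either may be `NULL`).
#' @return Invisible character vector of files written.
#' @export
write_validation_report <- function(report, csv_path = NULL,
                                    summary_path = NULL) {
  written <- character(0)
  if (!is.null(csv_path)) {
    utils::write.csv(report$holdout, csv_path, row.names = FALSE)
    written <- c(written, csv_path)
  }
  if (!is.null(summary_path)) {
    con <- file(summary_path, "w")
    writeLines(c(
      sprintf("n_masked\t%d", report$n_masked),
      sprintf("fraction\t%g", report$fraction),
      sprintf("rmse_rate\t%.6f", report$rmse_rate),
      sprintf("rmse_count\t%.6f", report$rmse_count),
      sprintf("coverage\t%.6f", report$coverage)
    ), con)
    close(con)
    written <- c(written, summary_path)
  }
  invisible(written)
}
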