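#' Read the prescribing-pipeline CSV dialects
#'
#' Thin readers for the four file kinds the pipeline exchanges:
#' prescribing rows (`PRACTICE, BNF_CODE, BNF_NAME, STRENGTH_MG, QUANTITY,
#' PERIOD`), the practice-to-area mapping (`PRACTICE, AREA_ID`), the
#' demography series (`AREA_ID, PERIOD, POPULATION, PROP_MALE, MEAN_AGE`)
#' and the covariate table (`AREA_ID, IMD_SCORE, RUC_CLASS`). `PERIOD` is
#' `YYYYMM`. Column presence is validated; extra columns are kept.
#'
#' @param path CSV file path.
#' @return A data frame.
#' @name readers
NULL

read_checked_csv <- function(path, required) {
  cc <- if ("PERIOD" %in% required) c(PERIOD = "character") else NA
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = cc)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s) %s", basename(path),
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

#' @rdname readers
#' @export
read_prescribing_csv <- function(path) {
  read_checked_csv(path, c("PRACTICE", "BNF_CODE", "STRENGTH_MG",
                           "QUANTITY", "PERIOD"))
}

#' @rdname readers
#' @export
read_mapping_csv <- function(path) read_checked_csv(path, c("PRACTICE", "AREA_ID"))

#' @rdname readers
#' @export
read_demography_csv <- function(path) {
  read_checked_csv(path, c("AREA_ID", "PERIOD", "POPULATION"))
}

#' @rdname readers
#' @export
read_covariates_csv <- function(path) read_checked_csv(path, c("AREA_ID"))

period_to_index <- function(period) {
  yr <- as.integer(substr(period, 1, 4))
  mo <- as.integer(substr(period, 5, 6))
  yr * 12L + (mo - 1L)
}

index_to_period <- function(idx) sprintf("%d%02d", idx %/% 12L, idx %% 12L + 1L)

#' Linearly interpolate a sparse population series to monthly resolution
#'
#' Population denominators are published at mixed cadence (quarterly early
#' on, monthly later); the model frame needs a value for any month. Between
#' known periods the series is linearly interpolated; outside the known
#' range it is extended flat. Known periods are returned unchanged.
#'
#' @param series Data frame with `AREA_ID`, `PERIOD` (`YYYYMM`),
#'   `POPULATION`; at least two known periods per area.
#' @param months Optional character vector of `YYYYMM` periods to evaluate;
#'   defaults to every month spanning the series.
#' @return Data frame `AREA_ID, PERIOD, POPULATION`, one row per area-month,
#'   sorted.
#' @export
interpolate_population <- function(series, months = NULL) {
  stopifnot(all(c("AREA_ID", "PERIOD", "POPULATION") %in% names(series)))
  series$PERIOD <- as.character(series$PERIOD)
  if (is.null(months)) {
    rng <- range(period_to_index(series$PERIOD))
    months <- index_to_period(seq(rng[1], rng[2]))
  }
  months <- as.character(months)
  out <- lapply(split(series, series$AREA_ID), function(s) {
    if (nrow(s) < 2L) {
      stop(sprintf("area %s: need at least 2 known periods to interpolate",
                   s$AREA_ID[1]), call. = FALSE)
    }
    s <- s[order(period_to_index(s$PERIOD)), ]
    fit <- stats::approx(period_to_index(s$PERIOD), s$POPULATION,
                         xout = period_to_index(months), rule = 2)
    data.frame(AREA_ID = s$AREA_ID[1], PERIOD = months, POPULATION = fit$y,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$AREA_ID, out$PERIOD), ]
}

#' Aggregate practice-level prescribing to the area-year model frame
#'
#' The central data-processing step: practice rows are converted to DDD
#' equivalents (quantity x strength / DDD), linked to areas through the
#' practice mapping, summed per (area, year) and rounded half-up to the
#' integer count `Y`. The exposure `E` is the mid-year (July, interpolated)
#' population divided by 1,000, so `Y / E` is the DDD-per-1,000 rate.
#' `TIME` is the year minus the reference year 2019. Covariates are
#' attached per area: continuous columns and the one-hot expansion of
#' `RUC_CLASS` (first level alphabetically dropped as reference) are all
#' z-standardised across areas (zero-variance columns are dropped with a
#' warning). Every (area, year) pair yields a record, with `Y = 0` where no
#' prescriptions occurred.
#'
#' @param rows Prescribing data frame ([read_prescribing_csv()] layout).
#' @param mapping Practice-to-area data frame.
#' @param demography Population series (sparse allowed; interpolated here).
#' @param covariates Per-area covariate table, or `NULL` for none.
#' @param drug A [drug_identifier()]; rows are filtered to its BNF code.
#' @param years Integer vector of calendar years to frame.
#' @return A `model_frame` data frame: `AREA_ID, YEAR, Y, E, TIME,
#'   POPULATION, RATE` plus standardised covariate columns (prefixed `x_`).
#' @export
aggregate_to_area_year <- function(rows, mapping, demography, covariates,
                                   drug, years) {
  stopifnot(inherits(drug, "drug_identifier"))
  years <- sort(as.integer(years))
  areas <- sort(unique(mapping$AREA_ID))

  rows <- rows[toupper(rows$BNF_CODE) == drug$bnf_code, , drop = FALSE]
  unmapped <- setdiff(unique(rows$PRACTICE), mapping$PRACTICE)
  if (length(unmapped)) {
    stop("unmapped practice id(s): ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  }

  # mid-year population per area-year; interpolation extends flat, so
  # demand that the demography series actually spans the requested years
  demo_years <- range(as.integer(substr(as.character(demography$PERIOD),
                                        1, 4)))
  if (min(years) < demo_years[1] || max(years) > demo_years[2]) {
    stop(sprintf("demography (%d-%d) does not cover the requested years",
                 demo_years[1], demo_years[2]), call. = FALSE)
  }
  july <- sprintf("%d07", years)
  pop <- interpolate_population(demography, months = july)
  pop$YEAR <- as.integer(substr(pop$PERIOD, 1, 4))
  missing_demo <- setdiff(areas, unique(demography$AREA_ID))
  if (length(missing_demo)) {
    stop("missing demography for area(s): ",
         paste(missing_demo, collapse = ", "), call. = FALSE)
  }

  frame <- expand.grid(AREA_ID = areas, YEAR = years,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  frame <- frame[order(frame$YEAR, frame$AREA_ID), ]

  if (nrow(rows) > 0L) {
    rows$AREA_ID <- mapping$AREA_ID[match(rows$PRACTICE, mapping$PRACTICE)]
    rows$YEAR <- as.integer(substr(as.character(rows$PERIOD), 1, 4))
    rows$DDD <- rows$QUANTITY * rows$STRENGTH_MG / drug$ddd_mg
    agg <- stats::aggregate(DDD ~ AREA_ID + YEAR, data = rows, FUN = sum)
  } else {
    agg <- data.frame(AREA_ID = character(0), YEAR = integer(0),
                      DDD = numeric(0))
  }
  key <- paste(frame$AREA_ID, frame$YEAR)
  ddd <- stats::setNames(rep(0, nrow(frame)), key)
  hit <- paste(agg$AREA_ID, agg$YEAR)
  ddd[hit[hit %in% key]] <- agg$DDD[hit %in% key]
  frame$Y <- as.integer(round_half_up(unname(ddd)))

  pop_key <- paste(pop$AREA_ID, pop$YEAR)
  frame$POPULATION <- pop$POPULATION[match(key, pop_key)]
  if (anyNA(frame$POPULATION)) {
    stop("demography does not cover all requested years", call. = FALSE)
  }
  frame$E <- frame$POPULATION / 1000
  frame$TIME <- frame$YEAR - 2019L
  frame$RATE <- frame$Y / frame$E

  if (!is.null(covariates)) {
    X <- standardize_covariates(covariates, areas)
    frame <- cbind(frame, X[match(frame$AREA_ID, rownames(X)), , drop = FALSE])
  }
  rownames(frame) <- NULL
  class(frame) <- c("model_frame", "data.frame")
  frame
}

# Build the standardised per-area design matrix: continuous covariates as-is,
# RUC_CLASS one-hot with the alphabetically first level as reference; every
# column z-scored across areas (sample sd).
standardize_covariates <- function(covariates, areas) {
  cov <- covariates[match(areas, covariates$AREA_ID), , drop = FALSE]
  if (anyNA(cov$AREA_ID)) {
    stop("covariate table missing area(s): ",
         paste(setdiff(areas, covariates$AREA_ID), collapse = ", "),
         call. = FALSE)
  }
  num_cols <- setdiff(names(cov)[vapply(cov, is.numeric, TRUE)], "AREA_ID")
  X <- as.matrix(cov[, num_cols, drop = FALSE])
  if (!is.null(cov$RUC_CLASS)) {
    lev <- sort(unique(as.character(cov$RUC_CLASS)))
    for (l in lev[-1]) {
      X <- cbind(X, as.numeric(cov$RUC_CLASS == l))
      colnames(X)[ncol(X)] <- paste0("RUC_", l)
    }
  }
  if (ncol(X) == 0L) return(matrix(numeric(0), nrow = length(areas),
                                   dimnames = list(areas, NULL)))
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant covariate column(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  X <- scale(X, center = TRUE, scale = sds)
  colnames(X) <- paste0("x_", colnames(X))
  rownames(X) <- areas
  X[, , drop = FALSE]
}

#' Write / read a model frame as CSV
#' @param frame A `model_frame`.
#' @param path CSV path.
#' @return `write_model_frame()` returns `path` invisibly;
#'   `read_model_frame()` returns a `model_frame`.
#' @export
write_model_frame <- function(frame, path) {
  utils::write.csv(frame, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_model_frame
#' @export
read_model_frame <- function(path) {
  frame <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("AREA_ID", "YEAR", "Y", "E", "TIME")
  missing <- setdiff(needed, names(frame))
  if (length(missing)) {
    stop("model frame missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(frame$RATE)) frame$RATE <- frame$Y / frame$E
  class(frame) <- c("model_frame", "data.frame")
  frame
}

# Covariate column names of a model frame (x_ prefix convention).
frame_covariate_cols <- function(frame) grep("^x_|^x[0-9]+$", names(frame),
                                             value = TRUE)
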