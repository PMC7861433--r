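#' Generate an area adjacency graph
#'
#' Synthetic stand-ins for the contiguity structure of administrative areas.
#' Two topologies:
#' \describe{
#'   \item{`grid`}{rook-contiguity rectangular lattice, rows x cols chosen
#'     as close to square as possible (a perfect square count gives the
#'     square lattice).}
#'   \item{`random-planar`}{Gabriel graph of points drawn uniformly in the
#'     unit square — a planar, connected graph whose degree distribution
#'     resembles real contiguity maps.}
#' }
#'
#' @param n_areas Number of areas (>= 2).
#' @param topology `"grid"` or `"random-planar"`.
#' @param seed Integer RNG seed (only `random-planar` consumes randomness).
#' @return An [adjacency_graph()] with node ids `"A001"`, `"A002"`, ...
#' @export
gen_adjacency <- function(n_areas, topology = c("grid", "random-planar"),
                          seed = 1L) {
  if (!is.numeric(n_areas) || n_areas < 2) {
    stop("n_areas must be at least 2", call. = FALSE)
  }
  n_areas <- as.integer(n_areas)
  topology <- match.arg(topology)
  ids <- area_ids(n_areas)
  if (topology == "grid") {
    nr <- floor(sqrt(n_areas))
    nc <- ceiling(n_areas / nr)
    pos <- cbind(row = (seq_len(n_areas) - 1L) %/% nc,
                 col = (seq_len(n_areas) - 1L) %% nc)
    edges <- NULL
    for (k in seq_len(n_areas)) {
      right <- k + 1L
      if (pos[k, "col"] < nc - 1L && right <= n_areas) {
        edges <- rbind(edges, c(ids[k], ids[right]))
      }
      down <- k + nc
      if (down <= n_areas) edges <- rbind(edges, c(ids[k], ids[down]))
    }
    return(adjacency_graph(ids, edges))
  }
  # Gabriel graph: i~j iff no third point lies inside the circle with
  # diameter ij; planar and connected (contains the EMST).
  pts <- withr::with_seed(seed, matrix(stats::runif(2 * n_areas), ncol = 2))
  edges <- NULL
  for (i in seq_len(n_areas - 1L)) {
    for (j in (i + 1L):n_areas) {
      mid <- (pts[i, ] + pts[j, ]) / 2
      r2 <- sum((pts[i, ] - pts[j, ])^2) / 4
      d2 <- (pts[, 1] - mid[1])^2 + (pts[, 2] - mid[2])^2
      d2[c(i, j)] <- Inf
      if (all(d2 > r2)) edges <- rbind(edges, c(ids[i], ids[j]))
    }
  }
  adjacency_graph(ids, edges)
}

area_ids <- function(n) sprintf("A%03d", seq_len(n))

#' Ground-truth parameters for the generative model
#'
#' Draws the latent effects of the BYM2 space-time model on a given graph:
#' the structured effect eta from the ICAR distribution of each connected
#' component (zero-mean on the component, covariance the generalised inverse
#' of the component precision, sampled through its eigendecomposition) and
#' the unstructured effect nu i.i.d. standard normal. Fixed-effect and
#' variance parameters are taken from `config`.
#'
#' @param graph An [adjacency_graph()].
#' @param config List with `beta0` (intercept on the log-rate scale),
#'   `beta` (covariate coefficients, possibly length 0), `beta3` (yearly
#'   slope), `sigma` (> 0, combined random-effect sd), `rho` (in \[0, 1\],
#'   spatial mixing fraction).
#' @param seed Integer RNG seed.
#' @return An object of class `synthetic_truth`: `config`'s parameters plus
#'   `eta` and `nu` (named per area; island `eta` is 0) and the `seed`.
#' @export
gen_truth <- function(graph, config, seed = 1L) {
  stopifnot(inherits(graph, "adjacency_graph"))
  needed <- c("beta0", "beta3", "sigma", "rho")
  if (!all(needed %in% names(config))) {
    stop("config must supply ", paste(needed, collapse = ", "), call. = FALSE)
  }
  if (config$sigma <= 0) stop("sigma must be positive", call. = FALSE)
  if (config$rho < 0 || config$rho > 1) {
    stop("rho must lie in [0, 1]", call. = FALSE)
  }
  beta <- if (is.null(config$beta)) numeric(0) else as.numeric(config$beta)
  n <- length(graph$nodes)
  structure_ <- build_icar_structure(graph)
  comp <- structure_$components
  draws <- withr::with_seed(seed, {
    eta <- stats::setNames(numeric(n), graph$nodes)
    for (c in seq_len(max(comp))) {
      idx <- which(comp == c)
      m <- length(idx)
      if (m >= 2L) {
        Qc <- as.matrix(structure_$precision[idx, idx, drop = FALSE])
        eig <- eigen(Qc, symmetric = TRUE)
        z <- stats::rnorm(m - 1L)
        # covariance = pseudo-inverse of Qc; constant eigenvector excluded,
        # so the draw sums to zero on the component by construction
        eta[idx] <- eig$vectors[, seq_len(m - 1L), drop = FALSE] %*%
          (z / sqrt(eig$values[seq_len(m - 1L)]))
      } # islands: eta stays 0
    }
    list(eta = eta, nu = stats::setNames(stats::rnorm(n), graph$nodes))
  })
  structure(
    list(beta0 = config$beta0, beta = beta, beta3 = config$beta3,
         sigma = config$sigma, rho = config$rho,
         eta = draws$eta, nu = draws$nu, seed = as.integer(seed)),
    class = "synthetic_truth"
  )
}

#' @method print synthetic_truth
#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "<synthetic_truth> %d areas | beta0=%.3f beta3=%.3f sigma=%.3f rho=%.3f | seed=%d\n",
    length(x$eta), x$beta0, x$beta3, x$sigma, x$rho, x$seed))
  invisible(x)
}

#' Simulate area-year DDD counts from the generative model
#'
#' For each area i and calendar year j computes the exposure
#' E_ij = population_ij / 1000 (so the relative rate theta_ij is the DDD per
#' 1,000 population), the log relative rate
#' mu_ij = beta0 + beta x_ij + kappa_i sigma + beta3 time_ij with
#' kappa_i = eta_i sqrt(rho / s) + nu_i sqrt(1 - rho), and draws
#' y_ij ~ Poisson(E_ij exp(mu_ij)). `time_ij` is the year minus the
#' reference year 2019.
#'
#' @param truth A [gen_truth()] result.
#' @param graph The generating [adjacency_graph()].
#' @param years Integer vector of calendar years.
#' @param populations Matrix (areas x years) of positive populations, or a
#'   single number recycled; rows in graph node order.
#' @param covariates Optional matrix (areas x p) or (areas*years x p) whose
#'   columns match `truth$beta`; omit/NULL when `beta` is empty.
#' @param seed Integer RNG seed for the Poisson draws.
#' @return Data frame with one row per (area, year): `AREA_ID`, `YEAR`,
#'   `TIME`, `POPULATION`, `E`, `THETA` (true rate), `Y`, plus covariate
#'   columns `x1..xp` when present.
#' @export
gen_area_year_counts <- function(truth, graph, years, populations,
                                 covariates = NULL, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  n <- length(graph$nodes)
  J <- length(years)
  pop <- matrix(populations, nrow = n, ncol = J)
  if (any(pop <= 0)) stop("populations must be positive", call. = FALSE)
  p <- length(truth$beta)
  X <- NULL
  if (p > 0L) {
    if (is.null(covariates)) {
      stop("covariates required when beta is non-empty", call. = FALSE)
    }
    X <- as.matrix(covariates)
    if (nrow(X) == n) X <- X[rep(seq_len(n), times = J), , drop = FALSE]
    if (nrow(X) != n * J || ncol(X) != p) {
      stop("covariate dimensions do not match beta", call. = FALSE)
    }
  }
  structure_ <- build_icar_structure(graph)
  kappa <- mixed_effect(truth$eta, truth$nu, truth$rho, structure_$s_area,
                        is_island = structure_$is_island)
  out <- data.frame(
    AREA_ID = rep(graph$nodes, times = J),
    YEAR = rep(as.integer(years), each = n),
    stringsAsFactors = FALSE
  )
  out$TIME <- out$YEAR - 2019L
  out$POPULATION <- as.vector(pop)
  out$E <- out$POPULATION / 1000
  xb <- if (p > 0L) as.vector(X %*% truth$beta) else 0
  mu <- truth$beta0 + xb + kappa[match(out$AREA_ID, graph$nodes)] * truth$sigma +
    truth$beta3 * out$TIME
  out$THETA <- exp(mu)
  out$Y <- withr::with_seed(seed, stats::rpois(n * J, out$E * out$THETA))
  if (p > 0L) {
    colnames(X) <- paste0("x", seq_len(p))
    out <- cbind(out, X)
  }
  out
}

#' Disaggregate area-year counts into practice-level prescribing records
#'
#' Produces the file set a prescribing pipeline ingests: monthly
#' practice-level prescription rows (with the drug's BNF code, strength and
#' integer quantity), a practice-to-area mapping, a quarterly demography
#' series and a per-area covariate table. The disaggregation works in DDD
#' units with largest-remainder apportionment so that re-aggregating the
#' rows with [ddd_equivalent()] and rounding half-up recovers every
#' area-year count `y_ij` exactly.
#'
#' Each area-year DDD total is split across `practices_per_area` practices,
#' 12 months and the drug's licensed strengths with uniform random weights.
#' Ideal mg allocations are floored to integer unit counts and the remaining
#' mg assigned, largest fractional remainder first; a final unit of the
#' smallest strength is added only if the shortfall would otherwise exceed
#' half a DDD. This keeps the per-area-year error strictly below DDD/2 (the
#' smallest licensed strength never exceeds the DDD for any registry drug),
#' so the half-up rounding in aggregation is exact.
#'
#' @param area_year Data frame from [gen_area_year_counts()].
#' @param drug A [drug_identifier()].
#' @param practices_per_area Positive integer.
#' @param seed Integer RNG seed.
#' @param imd_scores,ruc_classes Optional per-area covariate values written
#'   to the covariate table; sensible defaults are drawn when omitted.
#' @return List of data frames: `prescribing` (PRACTICE, BNF_CODE, BNF_NAME,
#'   STRENGTH_MG, QUANTITY, PERIOD), `mapping` (PRACTICE, AREA_ID),
#'   `demography` (AREA_ID, PERIOD, POPULATION, PROP_MALE, MEAN_AGE;
#'   quarterly), `covariates` (AREA_ID, IMD_SCORE, RUC_CLASS).
#' @export
gen_prescribing <- function(area_year, drug, practices_per_area = 3L,
                            seed = 1L, imd_scores = NULL, ruc_classes = NULL) {
  stopifnot(inherits(drug, "drug_identifier"))
  if (practices_per_area < 1L) {
    stop("practices_per_area must be at least 1", call. = FALSE)
  }
  if (min(drug$strengths_mg) > drug$ddd_mg) {
    stop("smallest licensed strength exceeds the DDD; exact disaggregation ",
         "is not possible", call. = FALSE)
  }
  areas <- unique(area_year$AREA_ID)
  years <- sort(unique(area_year$YEAR))
  practices <- data.frame(
    PRACTICE = sprintf("P%05d", seq_len(length(areas) * practices_per_area)),
    AREA_ID = rep(areas, each = practices_per_area),
    stringsAsFactors = FALSE
  )
  withr::with_seed(seed, {
    rows <- vector("list", nrow(area_year))
    for (r in seq_len(nrow(area_year))) {
      ay <- area_year[r, ]
      if (ay$Y == 0) next
      pr <- practices$PRACTICE[practices$AREA_ID == ay$AREA_ID]
      cells <- expand.grid(PRACTICE = pr, MONTH = 1:12,
                           stringsAsFactors = FALSE)
      # sample() treats a length-1 numeric as 1:n, so guard the single-
      # strength case
      cells$STRENGTH_MG <- if (length(drug$strengths_mg) == 1L) {
        rep(drug$strengths_mg, nrow(cells))
      } else {
        sample(drug$strengths_mg, nrow(cells), replace = TRUE)
      }
      w <- stats::runif(nrow(cells))
      q <- apportion_mg(ay$Y * drug$ddd_mg, w / sum(w), cells$STRENGTH_MG,
                        drug$ddd_mg, min(drug$strengths_mg))
      keep <- q > 0
      if (!any(keep)) next
      rows[[r]] <- data.frame(
        PRACTICE = cells$PRACTICE[keep],
        BNF_CODE = drug$bnf_code,
        BNF_NAME = drug$name,
        STRENGTH_MG = cells$STRENGTH_MG[keep],
        QUANTITY = q[keep],
        PERIOD = sprintf("%d%02d", ay$YEAR, cells$MONTH[keep]),
        stringsAsFactors = FALSE
      )
    }
    prescribing <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
    if (is.null(prescribing)) {
      prescribing <- data.frame(PRACTICE = character(0), BNF_CODE = character(0),
                                BNF_NAME = character(0), STRENGTH_MG = numeric(0),
                                QUANTITY = numeric(0), PERIOD = character(0))
    }
    # quarterly demography, constant within each year so the July (mid-year)
    # value equals the annual population exactly
    quarters <- c("01", "04", "07", "10")
    demo <- merge(area_year[, c("AREA_ID", "YEAR", "POPULATION")],
                  data.frame(Q = quarters), by = NULL)
    demography <- data.frame(
      AREA_ID = demo$AREA_ID,
      PERIOD = paste0(demo$YEAR, demo$Q),
      POPULATION = demo$POPULATION,
      PROP_MALE = round(stats::runif(nrow(demo), 0.47, 0.52), 4),
      MEAN_AGE = round(stats::runif(nrow(demo), 36, 48), 2),
      stringsAsFactors = FALSE
    )
    demography <- demography[order(demography$AREA_ID, demography$PERIOD), ]
    if (is.null(imd_scores)) {
      imd_scores <- round(stats::runif(length(areas), 5, 45), 2)
    }
    if (is.null(ruc_classes)) {
      ruc_classes <- sample(c("urban", "town", "rural"), length(areas),
                            replace = TRUE, prob = c(0.6, 0.25, 0.15))
    }
  })
  covariates <- data.frame(AREA_ID = areas, IMD_SCORE = imd_scores,
                           RUC_CLASS = ruc_classes, stringsAsFactors = FALSE)
  rownames(prescribing) <- NULL
  rownames(demography) <- NULL
  list(prescribing = prescribing, mapping = practices,
       demography = demography, covariates = covariates)
}

# Integer apportionment of total_mg across cells with given weights and
# per-cell strengths. Returns integer unit counts whose mg total differs from
# total_mg by strictly less than ddd_mg/2.
apportion_mg <- function(total_mg, weights, strengths, ddd_mg, s_min) {
  ideal_units <- total_mg * weights / strengths
  q <- floor(ideal_units)
  remainder_mg <- total_mg - sum(q * strengths)
  ord <- order(ideal_units - q, decreasing = TRUE)
  repeat {
    placed <- FALSE
    for (k in ord) {
      if (strengths[k] <= remainder_mg) {
        q[k] <- q[k] + 1
        remainder_mg <- remainder_mg - strengths[k]
        placed <- TRUE
      }
    }
    if (!placed) break
  }
  if (remainder_mg > ddd_mg / 2) {
    # overshoot with one smallest-strength unit; error becomes
    # s_min - remainder < ddd/2 because s_min <= ddd
    k <- which(strengths == s_min)[1]
    q[k] <- q[k] + 1
  }
  q
}

#' Write the synthetic file set to a directory
#'
#' @param files List from [gen_prescribing()].
#' @param graph The [adjacency_graph()] used to generate the data.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_synthetic_files <- function(files, graph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    prescribing = file.path(dir, "prescribing.csv"),
    mapping = file.path(dir, "practice_mapping.csv"),
    demography = file.path(dir, "demography.csv"),
    covariates = file.path(dir, "covariates.csv"),
    adjacency = file.path(dir, "adjacency.tsv")
  )
  utils::write.csv(files$prescribing, paths["prescribing"], row.names = FALSE)
  utils::write.csv(files$mapping, paths["mapping"], row.names = FALSE)
  utils::write.csv(files$demography, paths["demography"], row.names = FALSE)
  utils::write.csv(files$covariates, paths["covariates"], row.names = FALSE)
  write_adjacency(graph, paths["adjacency"])
  invisible(paths)
}
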