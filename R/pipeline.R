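#' Run configuration
#'
#' A plain-text `key = value` file fully determines a pipeline run; the
#' config round-trips through [read_run_config()] / [write_run_config()]
#' losslessly. Every random stage has an explicit seed.
#'
#' @param out_dir Run directory.
#' @param drug Registry drug name or code (default `"Apixaban"`).
#' @param n_areas,topology,years Simulation geometry and period.
#' @param practices_per_area Practices generated per area.
#' @param beta0,beta3,sigma,rho True generative parameters.
#' @param population Per-area annual population (scalar).
#' @param chains,iter_warmup,iter_sampling Sampler settings.
#' @param beta_sd,sigma_scale,rho_shape Prior hyperparameters.
#' @param validation_fraction Hold-out fraction.
#' @param seed Master seed; stage seeds derive from it deterministically.
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(out_dir, drug = "Apixaban", n_areas = 20,
                       topology = "grid", years = 2014:2019,
                       practices_per_area = 3, beta0 = log(5), beta3 = 0.05,
                       sigma = 0.5, rho = 0.7, population = 50000,
                       chains = 2, iter_warmup = 500, iter_sampling = 500,
                       beta_sd = 5, sigma_scale = 1, rho_shape = c(1, 1),
                       validation_fraction = 0.1, seed = 1L) {
  cfg <- list(out_dir = out_dir, drug = drug, n_areas = as.integer(n_areas),
              topology = topology, years = as.integer(years),
              practices_per_area = as.integer(practices_per_area),
              beta0 = beta0, beta3 = beta3, sigma = sigma, rho = rho,
              population = population, chains = as.integer(chains),
              iter_warmup = as.integer(iter_warmup),
              iter_sampling = as.integer(iter_sampling),
              beta_sd = beta_sd, sigma_scale = sigma_scale,
              rho_shape = as.numeric(rho_shape),
              validation_fraction = validation_fraction,
              seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path Config file path.
#' @export
write_run_config <- function(cfg, path) {
  lines <- vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    sprintf("%s = %s", k, paste(format(v, digits = 17, scientific = FALSE,
                                       trim = TRUE), collapse = ","))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "\\s*=\\s*")
  cfg <- stats::setNames(lapply(kv, function(x) {
    vals <- strsplit(x[2], ",")[[1]]
    num <- suppressWarnings(as.numeric(vals))
    if (anyNA(num)) vals else num
  }), vapply(kv, `[[`, "", 1))
  defaults <- run_config(out_dir = cfg$out_dir)
  for (k in names(cfg)) defaults[[k]] <- cfg[[k]]
  ints <- c("n_areas", "practices_per_area", "years", "chains",
            "iter_warmup", "iter_sampling", "seed")
  for (k in ints) defaults[[k]] <- as.integer(defaults[[k]])
  defaults
}

stage_seed <- function(cfg, stage) {
  # small fixed offsets keep every derived seed far below 2^31
  offs <- c(graph = 11L, truth = 23L, counts = 37L, csv = 53L,
            fit = 71L, validate = 89L)
  cfg$seed * 101L + offs[[stage]]
}

pipeline_log <- function(con, level, msg) {
  line <- sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  level, msg)
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the full pipeline
#'
#' Orchestrates simulate -> aggregate -> fit -> validate -> summarise in a
#' run directory: synthetic prescribing files, the aggregated model frame,
#' posterior parameter and area-year rate tables, convergence diagnostics,
#' the hold-out validation report, a run log and a manifest of every
#' output with its MD5 checksum. Rerunning with an identical config
#' reproduces identical file checksums.
#'
#' @param cfg A [run_config()].
#' @return Invisible list with the stage objects (`truth`, `frame`, `fit`,
#'   `validation`, `manifest`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(cfg$out_dir, "run.log"), "w")
  on.exit(close(log_con))
  stage <- "simulate"
  result <- tryCatch({
    pipeline_log(log_con, "INFO", sprintf("stage %s", stage))
    registry <- load_registry()
    drug <- if (cfg$drug %in% names(registry)) registry[[cfg$drug]] else
      lookup_identifier(cfg$drug, registry)
    graph <- gen_adjacency(cfg$n_areas, cfg$topology,
                           seed = stage_seed(cfg, "graph"))
    truth <- gen_truth(graph, list(beta0 = cfg$beta0, beta3 = cfg$beta3,
                                   sigma = cfg$sigma, rho = cfg$rho),
                       seed = stage_seed(cfg, "truth"))
    ay <- gen_area_year_counts(truth, graph, cfg$years, cfg$population,
                               seed = stage_seed(cfg, "counts"))
    files <- gen_prescribing(ay, drug, cfg$practices_per_area,
                             seed = stage_seed(cfg, "csv"))
    paths <- write_synthetic_files(files, graph, cfg$out_dir)
    utils::write.csv(data.frame(parameter = c("beta0", "beta3", "sigma", "rho"),
                                value = c(truth$beta0, truth$beta3,
                                          truth$sigma, truth$rho)),
                     file.path(cfg$out_dir, "truth_parameters.csv"),
                     row.names = FALSE)

    stage <- "aggregate"
    pipeline_log(log_con, "INFO", sprintf("stage %s", stage))
    frame <- aggregate_to_area_year(files$prescribing, files$mapping,
                                    files$demography, covariates = NULL,
                                    drug = drug, years = cfg$years)
    write_model_frame(frame, file.path(cfg$out_dir, "model_frame.csv"))

    stage <- "fit"
    pipeline_log(log_con, "INFO", sprintf("stage %s", stage))
    structure_ <- build_icar_structure(graph)
    write_structure_summary(structure_,
                            file.path(cfg$out_dir, "structure_summary.txt"))
    priors <- prior_spec(cfg$beta_sd, cfg$sigma_scale, cfg$rho_shape)
    fit <- fit_bym2(frame, structure_, priors, chains = cfg$chains,
                    iter_warmup = cfg$iter_warmup,
                    iter_sampling = cfg$iter_sampling,
                    seed = stage_seed(cfg, "fit"))
    utils::write.csv(fit$summary, file.path(cfg$out_dir, "parameters.csv"),
                     row.names = FALSE)
    utils::write.csv(compute_diagnostics(fit),
                     file.path(cfg$out_dir, "diagnostics.csv"),
                     row.names = FALSE)

    stage <- "validate"
    pipeline_log(log_con, "INFO", sprintf("stage %s", stage))
    report <- validate_holdout(frame, structure_, priors,
                               fraction = cfg$validation_fraction,
                               seed = stage_seed(cfg, "validate"),
                               chains = cfg$chains,
                               iter_warmup = cfg$iter_warmup,
                               iter_sampling = cfg$iter_sampling)
    write_validation_report(report,
                            csv_path = file.path(cfg$out_dir, "validation.csv"),
                            summary_path = file.path(cfg$out_dir,
                                                     "validation_summary.txt"))

    stage <- "summarize"
    pipeline_log(log_con, "INFO", sprintf("stage %s", stage))
    summ <- summarize_fit(fit)
    utils::write.csv(summ$theta, file.path(cfg$out_dir, "theta.csv"),
                     row.names = FALSE)

    cfg_path <- file.path(cfg$out_dir, "config.txt")
    write_run_config(cfg, cfg_path)
    outputs <- c(unname(paths),
                 file.path(cfg$out_dir,
                           c("truth_parameters.csv", "model_frame.csv",
                             "structure_summary.txt", "parameters.csv",
                             "diagnostics.csv", "validation.csv",
                             "validation_summary.txt", "theta.csv",
                             "config.txt")))
    manifest <- data.frame(
      file = basename(outputs),
      md5 = unname(tools::md5sum(outputs)),
      config_hash = unname(tools::md5sum(cfg_path)),
      seed = cfg$seed,
      stringsAsFactors = FALSE
    )
    utils::write.csv(manifest, file.path(cfg$out_dir, "manifest.csv"),
                     row.names = FALSE)
    pipeline_log(log_con, "INFO", "pipeline complete")
    list(truth = truth, frame = frame, fit = fit, validation = report,
         manifest = manifest)
  }, error = function(e) {
    pipeline_log(log_con, "ERROR", sprintf("stage=%s error=%s", stage,
                                           conditionMessage(e)))
    err <- data.frame(stage = stage, error = conditionMessage(e))
    utils::write.csv(err, file.path(cfg$out_dir, "error.csv"),
                     row.names = FALSE)
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}
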