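# End-to-end workflow: simulate-or-load -> scatter removal -> PARAFAC ->
# unfold/scale -> PLS calibration -> metrics/VIP/permutation -> report.

#' Pipeline configuration
#'
#' @param mode `"simulate"` (generate a synthetic dataset) or `"load"`
#'   (read a manifest directory written by [write_stack_csv()]).
#' @param input_dir directory with `manifest.csv` (+ `reference.csv`) for
#'   load mode.
#' @param sim a [serum_sim_config()] for simulate mode.
#' @param fluorophores fluorophore set for simulate mode.
#' @param scatter_parafac,scatter_pls [scatter_bands()] used before the two
#'   model branches; excision for PARAFAC (its masked ALS handles missing
#'   cells), interpolation for PLS (a dense matrix is required).
#' @param parafac list: `enabled`, `F_range` (candidates for
#'   [select_n_components()]), `n_comp` (fixed count, skips selection),
#'   `threshold` (core-consistency %), `config` (a [parafac_config()]).
#' @param pls list: `enabled`, `max_A`, `k_folds`, `n_perm`, `permutation`
#'   (run the Y-permutation test).
#' @param n_cal,n_val calibration/validation sizes in samples.
#' @param replicate_policy `"average"` (one averaged scan per sample enters
#'   PLS) or `"all"` (every replicate scan is a row, inheriting its
#'   sample's reference value).
#' @param seed master seed; stage seeds are derived from it and echoed in
#'   the report.
#' @param out_dir optional directory for the JSON report and CSV artifacts.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "load"), input_dir = NULL,
                            sim = serum_sim_config(),
                            fluorophores = default_fluorophores(),
                            scatter_parafac = scatter_bands(mode = "excise"),
                            scatter_pls = scatter_bands(mode = "interpolate"),
                            parafac = list(),
                            pls = list(),
                            n_cal = 145L, n_val = 63L,
                            replicate_policy = c("average", "all"),
                            seed = 1L, out_dir = NULL) {
  mode <- match.arg(mode)
  replicate_policy <- match.arg(replicate_policy)
  if (mode == "load" && is.null(input_dir))
    stopf("load mode needs input_dir")
  parafac <- utils::modifyList(
    list(enabled = TRUE, F_range = 2:7, n_comp = NULL, threshold = 60,
         config = parafac_config(seed = seed)), parafac)
  pls <- utils::modifyList(
    list(enabled = TRUE, max_A = 10L, k_folds = 7L, n_perm = 100L,
         permutation = TRUE), pls)
  structure(list(mode = mode, input_dir = input_dir, sim = sim,
                 fluorophores = fluorophores,
                 scatter_parafac = scatter_parafac, scatter_pls = scatter_pls,
                 parafac = parafac, pls = pls,
                 n_cal = as.integer(n_cal), n_val = as.integer(n_val),
                 replicate_policy = replicate_policy,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("stage %s: %s", name, conditionMessage(e)))
}

#' Run the full retinol-calibration workflow
#'
#' Executes, with stage-labelled errors: data acquisition (simulate or
#' load), scatter removal, PARAFAC component selection/fitting with peak
#' localisation and score-reference correlations, unfolding and
#' unit-variance scaling, cross-validated latent-variable selection, PLS
#' fitting and validation, metrics, VIP/coefficient maps, and the optional
#' Y-permutation test. When `config$out_dir` is set, writes `report.json`,
#' PARAFAC loading CSVs, coefficient/VIP map CSVs and per-set
#' predicted-vs-reference CSVs.
#'
#' @param config a [pipeline_config()].
#' @return The run report (list, JSON-serialisable), invisibly classed
#'   `run_report`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  report <- list(config = echo_config(config),
                 versions = list(serumEEM = as.character(
                   utils::packageVersion("serumEEM")),
                   r = R.version.string))

  dataset <- stage("input", {
    if (config$mode == "simulate")
      simulate_dataset(config$sim, config$fluorophores)$stack
    else read_stack_csv(config$input_dir)
  })
  message(sprintf("[%s] input: %d scans", format(Sys.time(), "%H:%M:%S"),
                  length(dataset)))

  pf_model <- NULL
  if (isTRUE(config$parafac$enabled)) {
    pf <- stage("parafac", {
      excised <- remove_scatter(dataset, config$scatter_parafac)
      n_comp <- config$parafac$n_comp
      selection <- NULL
      if (is.null(n_comp)) {
        # the rank scan runs unconstrained (constraints inflate core
        # consistency); the final model below is refit with the
        # configured constraints
        scan_cfg <- config$parafac$config
        scan_cfg$nonneg <- c(FALSE, FALSE, FALSE)
        n_comp <- select_n_components(excised, config$parafac$F_range,
                                      config$parafac$threshold, scan_cfg)
        selection <- attr(n_comp, "diagnostics")
      }
      model <- fit_parafac(excised, as.integer(n_comp),
                           config$parafac$config,
                           init_factors = attr(n_comp, "model"))
      corr <- NULL
      if (!is.null(dataset$reference)) {
        corr <- lapply(seq_len(model$n_components), function(f)
          score_reference_correlation(model, f, dataset$reference))
        corr <- data.frame(component = seq_along(corr),
                           r = vapply(corr, `[[`, numeric(1), "r"),
                           p = vapply(corr, `[[`, numeric(1), "p"))
      }
      list(model = model, selection = selection, correlations = corr)
    })
    pf_model <- pf$model
    report$parafac <- list(
      n_components = pf_model$n_components,
      corcondia = pf_model$corcondia,
      explained_pct = pf_model$explained_pct,
      converged = pf_model$converged,
      n_iter = pf_model$n_iter,
      peaks = component_peaks(pf_model),
      selection = pf$selection,
      score_correlations = pf$correlations)
    message(sprintf("[%s] parafac: %d components, corcondia %.1f%%",
                    format(Sys.time(), "%H:%M:%S"), pf_model$n_components,
                    pf_model$corcondia))
  }

  pls_out <- NULL
  if (isTRUE(config$pls$enabled)) {
    pls_out <- stage("pls", {
      if (is.null(dataset$reference))
        stopf("PLS calibration needs reference values")
      smooth <- remove_scatter(dataset, config$scatter_pls)
      if (config$replicate_policy == "average")
        smooth <- average_replicates(smooth)
      uf <- unfold(smooth, missing = "drop")
      split <- split_calibration_validation(smooth, config$n_cal,
                                            config$n_val,
                                            seed = config$seed + 1L)
      row_sid <- sample_ids(smooth)
      cal_rows <- row_sid %in% split$cal_ids
      val_rows <- row_sid %in% split$val_ids
      X_cal_raw <- uf$X[cal_rows, , drop = FALSE]
      X_val_raw <- uf$X[val_rows, , drop = FALSE]
      y_cal <- unname(dataset$reference[row_sid[cal_rows]])
      y_val <- unname(dataset$reference[row_sid[val_rows]])

      sc <- uv_scale(X_cal_raw)
      cv <- choose_components_cv(sc$X, y_cal, max_A = config$pls$max_A,
                                 k_folds = config$pls$k_folds,
                                 seed = config$seed + 2L)
      model <- fit_pls(sc$X, y_cal, cv$A, scaling = sc$params,
                       vmap = uf$vmap[sc$params$keep, , drop = FALSE],
                       ex_grid = smooth$ex_grid, em_grid = smooth$em_grid)
      yhat_cal <- predict(model, X_cal_raw)
      yhat_val <- predict(model, X_val_raw)
      metrics <- compute_metrics(y_cal, yhat_cal, y_val, yhat_val, model$n_lv)
      vip <- vip_scores(model)
      perm <- NULL
      if (isTRUE(config$pls$permutation))
        perm <- permutation_test(sc$X, y_cal, model$n_lv,
                                 n_perm = config$pls$n_perm,
                                 k_folds = config$pls$k_folds,
                                 seed = config$seed + 3L)
      list(model = model, metrics = metrics, vip = vip, perm = perm,
           q2 = cv$q2, y_cal = y_cal, yhat_cal = yhat_cal,
           y_val = y_val, yhat_val = yhat_val,
           cal_ids = row_sid[cal_rows], val_ids = row_sid[val_rows])
    })
    report$pls <- list(
      a_selected = pls_out$model$n_lv,
      q2_cv = unname(pls_out$q2[pls_out$model$n_lv]),
      q2_by_A = pls_out$q2,
      r2_cal = pls_out$metrics$r2_cal, r2_val = pls_out$metrics$r2_val,
      r2_alt_cal = pls_out$metrics$r2_alt_cal,
      r2_alt_val = pls_out$metrics$r2_alt_val,
      rmsee = pls_out$metrics$rmsee, rmsep = pls_out$metrics$rmsep,
      rpd = pls_out$metrics$rpd, rpd_band = pls_out$metrics$rpd_band,
      n_cal = pls_out$metrics$n_cal, n_val = pls_out$metrics$n_val,
      vip_peaks = pls_out$vip$peaks,
      permutation_intercepts = if (!is.null(pls_out$perm))
        list(r2 = pls_out$perm$r2_intercept, q2 = pls_out$perm$q2_intercept))
    message(sprintf(paste0("[%s] pls: A = %d, R2_val = %.3f, RMSEP = %.2f, ",
                           "RPD = %.2f"),
                    format(Sys.time(), "%H:%M:%S"), pls_out$model$n_lv,
                    pls_out$metrics$r2_val, pls_out$metrics$rmsep,
                    pls_out$metrics$rpd))
  }

  report$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  report$timestamp <- format(t0, "%Y-%m-%dT%H:%M:%S%z")

  if (!is.null(config$out_dir))
    stage("output", write_report(report, pf_model, pls_out, config$out_dir))
  invisible(structure(report, class = c("run_report", "list")))
}

echo_config <- function(config) {
  list(mode = config$mode, input_dir = config$input_dir,
       sim = if (config$mode == "simulate")
         unclass(config$sim)[c("n_samples", "replicates", "conc_mean",
                               "conc_sd", "conc_range", "noise_sd",
                               "replicate_jitter", "scatter", "seed")],
       scatter_parafac = unclass(config$scatter_parafac),
       scatter_pls = unclass(config$scatter_pls),
       parafac = list(enabled = config$parafac$enabled,
                      F_range = config$parafac$F_range,
                      n_comp = config$parafac$n_comp,
                      threshold = config$parafac$threshold,
                      n_starts = config$parafac$config$n_starts,
                      max_iter = config$parafac$config$max_iter,
                      rel_tol = config$parafac$config$rel_tol),
       pls = config$pls, n_cal = config$n_cal, n_val = config$n_val,
       replicate_policy = config$replicate_policy, seed = config$seed)
}

write_report <- function(report, pf_model, pls_out, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE, force = TRUE)
  if (!is.null(pf_model))
    write_parafac_csv(pf_model, file.path(out_dir, "parafac"))
  if (!is.null(pls_out)) {
    m <- pls_out$model
    utils::write.csv(cbind(m$vmap, coefficient = m$coefficients,
                           vip = pls_out$vip$vip),
                     file.path(out_dir, "pls_variables.csv"),
                     row.names = FALSE)
    utils::write.csv(coefficient_map(m),
                     file.path(out_dir, "coefficient_map.csv"))
    utils::write.csv(pls_out$vip$vip_map, file.path(out_dir, "vip_map.csv"))
    utils::write.csv(data.frame(sample_id = pls_out$cal_ids,
                                reference = pls_out$y_cal,
                                predicted = pls_out$yhat_cal),
                     file.path(out_dir, "predicted_calibration.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(sample_id = pls_out$val_ids,
                                reference = pls_out$y_val,
                                predicted = pls_out$yhat_val),
                     file.path(out_dir, "predicted_validation.csv"),
                     row.names = FALSE)
  }
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  if (!is.null(x$parafac))
    cat(sprintf("  PARAFAC: %d components, corcondia %.1f%%\n",
                x$parafac$n_components, x$parafac$corcondia))
  if (!is.null(x$pls))
    cat(sprintf("  PLS: A = %d, R2_val = %.3f, RMSEP = %.2f IU/dl, RPD = %.2f (%s)\n",
                x$pls$a_selected, x$pls$r2_val, x$pls$rmsep, x$pls$rpd,
                x$pls$rpd_band))
  invisible(x)
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat keys mirror the [pipeline_config()] arguments; nested blocks `sim`,
#' `parafac`, `pls`, `scatter_parafac`, `scatter_pls` override individual
#' fields of the corresponding defaults.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  y <- yaml::read_yaml(path)
  seed <- as.integer(y$seed %||% 1L)
  sim_args <- y$sim %||% list()
  if (is.null(sim_args$seed)) sim_args$seed <- seed
  sb <- function(block, mode) {
    args <- y[[block]] %||% list()
    args$mode <- args$mode %||% mode
    do.call(scatter_bands, args)
  }
  pf <- y$parafac %||% list()
  if (!is.null(pf$F_range)) pf$F_range <- as.integer(pf$F_range)
  if (!is.null(pf$config)) pf$config <- do.call(parafac_config, pf$config)
  pipeline_config(
    mode = y$mode %||% "simulate",
    input_dir = y$input_dir,
    sim = do.call(serum_sim_config, sim_args),
    scatter_parafac = sb("scatter_parafac", "excise"),
    scatter_pls = sb("scatter_pls", "interpolate"),
    parafac = pf, pls = y$pls %||% list(),
    n_cal = y$n_cal %||% 145L, n_val = y$n_val %||% 63L,
    replicate_policy = y$replicate_policy %||% "average",
    seed = seed, out_dir = y$out_dir)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic dataset to disk), `run` (full
#' pipeline), `parafac` / `pls` (single-branch runs), `report` (re-print an
#' existing report). Shared flags: `--config FILE`, `--seed INT`,
#' `--out DIR`, `--input DIR`, `--n-samples INT`, `--scatter`.
#' A thin wrapper script is installed at
#' `system.file("cli", "serum-eem", package = "serumEEM")`.
#'
#' @param argv character vector of arguments (excluding the program name).
#' @return Integer exit code (0 on success), invisibly.
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: serum-eem <simulate|run|parafac|pls|report> [options]",
    "  --config FILE   YAML pipeline configuration",
    "  --seed INT      master seed (default 1)",
    "  --out DIR       output directory",
    "  --input DIR     manifest directory (load mode)",
    "  --n-samples INT simulated sample count",
    "  --scatter       add scatter ridges when simulating", sep = "\n")
  fail <- function(msg) {
    message(msg, "\n", usage)
    return(invisible(1L))
  }
  if (!length(argv)) return(fail("no subcommand given"))
  cmd <- argv[1L]
  argv <- argv[-1L]
  opts <- list(seed = 1L, scatter = FALSE)
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    need_val <- function() {
      if (i + 1L > length(argv)) stopf("flag %s needs a value", a)
      argv[i + 1L]
    }
    handled <- TRUE
    switch(a,
      "--config" = { opts$config <- need_val(); i <- i + 1L },
      "--seed" = { opts$seed <- as.integer(need_val()); i <- i + 1L },
      "--out" = { opts$out <- need_val(); i <- i + 1L },
      "--input" = { opts$input <- need_val(); i <- i + 1L },
      "--n-samples" = { opts$n_samples <- as.integer(need_val()); i <- i + 1L },
      "--scatter" = { opts$scatter <- TRUE },
      handled <- FALSE)
    if (!handled) return(fail(sprintf("unknown flag: %s", a)))
    i <- i + 1L
  }

  result <- tryCatch({
    cfg <- if (!is.null(opts$config)) read_pipeline_config(opts$config)
           else pipeline_config(
             mode = if (!is.null(opts$input)) "load" else "simulate",
             input_dir = opts$input, seed = opts$seed,
             sim = serum_sim_config(
               n_samples = opts$n_samples %||% 208L,
               scatter = opts$scatter, seed = opts$seed))
    if (!is.null(opts$out)) cfg$out_dir <- opts$out
    if (!is.null(opts$seed) && is.null(opts$config)) cfg$seed <- opts$seed

    switch(cmd,
      simulate = {
        if (is.null(cfg$out_dir)) stopf("simulate needs --out DIR")
        ds <- simulate_dataset(cfg$sim, cfg$fluorophores)
        write_dataset_csv(ds, cfg$out_dir)
        message(sprintf("wrote %d scans to %s", length(ds$stack), cfg$out_dir))
        0L
      },
      run = { run_pipeline(cfg); 0L },
      parafac = { cfg$pls$enabled <- FALSE; run_pipeline(cfg); 0L },
      pls = { cfg$parafac$enabled <- FALSE; run_pipeline(cfg); 0L },
      report = {
        path <- file.path(cfg$out_dir %||% ".", "report.json")
        if (!file.exists(path)) stopf("no report at %s", path)
        rep <- jsonlite::read_json(path, simplifyVector = TRUE)
        print(structure(rep, class = c("run_report", "list")))
        0L
      },
      stopf("unknown subcommand: %s", cmd))
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(result)
}

#' Contour plot of an EEM or a refolded map
#'
#' Convenience wrapper around [graphics::filled.contour()] for intensity
#' matrices in this package's `[em x ex]` orientation. Figures are optional
#' byproducts; the CSV matrices are the contract.
#'
#' @param x an [eem()] object or a numeric `[em x ex]` matrix with grid
#'   dimnames (e.g. from [coefficient_map()]).
#' @param main plot title.
#' @param ... passed to [graphics::filled.contour()].
#' @return `NULL`, invisibly.
#' @export
plot_contour <- function(x, main = "", ...) {
  if (inherits(x, "eem")) {
    z <- x$intensity
    ex <- as.numeric(x$ex_grid); em <- as.numeric(x$em_grid)
  } else {
    z <- as.matrix(x)
    em <- as.numeric(rownames(z)); ex <- as.numeric(colnames(z))
  }
  z[is.na(z)] <- 0
  graphics::filled.contour(ex, em, t(z), xlab = "Excitation (nm)",
                           ylab = "Emission (nm)", main = main,
                           color.palette = grDevices::hcl.colors, ...)
  invisible(NULL)
}
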