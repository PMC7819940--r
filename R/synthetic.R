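# Synthetic serum-EEM generator.
#
# Emulates the reference study design the pipeline targets: ~200 cattle serum
# samples scanned in three analytical replicates on a 250-450/5 nm
# excitation x 250-600/1 nm emission grid, with serum fluorescence modelled
# as a trilinear mixture of Gaussian-band fluorophores -- three protein-like
# components (tryptophan/tyrosine region) whose amounts vary independently
# of retinol, a free-retinol band whose amount is proportional to the true
# concentration, and a retinol-binding-protein band tied to concentration
# with extra scatter. Known ground truth makes recovery testable.

#' Define a fluorophore for the simulator
#'
#' @param name label.
#' @param ex_center,em_center band centres (nm); must lie on/within the grids.
#' @param ex_width,em_width Gaussian standard deviations (nm).
#' @param brightness emitted intensity (arbitrary units) per unit amount.
#' @param concentration_model how the per-sample amount is generated:
#'   `"independent_lognormal"` (protein-like, uncorrelated with retinol),
#'   `"retinol_linked"` (amount = concentration in IU/dl),
#'   `"retinol_linked_secondary"` (amount = `link_coef` x concentration plus
#'   small seeded scatter, the bound-retinol/RBP signal).
#' @param link_coef linkage coefficient for the secondary model.
#' @param link_sd standard deviation of the secondary model's scatter.
#' @return An object of class `fluorophore`.
#' @export
fluorophore <- function(name, ex_center, em_center, ex_width = 18,
                        em_width = 28, brightness = 1,
                        concentration_model = c("independent_lognormal",
                                                "retinol_linked",
                                                "retinol_linked_secondary"),
                        link_coef = 0.6, link_sd = 2) {
  concentration_model <- match.arg(concentration_model)
  stopifnot(ex_width > 0, em_width > 0, brightness > 0)
  structure(list(name = name, ex_center = ex_center, em_center = em_center,
                 ex_width = ex_width, em_width = em_width,
                 brightness = brightness,
                 concentration_model = concentration_model,
                 link_coef = link_coef, link_sd = link_sd),
            class = "fluorophore")
}

#' Gaussian spectral band sampled on a grid
#'
#' `exp(-(lambda - center)^2 / (2 width^2))`; unit maximum when the centre
#' lies on the grid, argmax at the nearest grid point otherwise.
#'
#' @param grid a [make_grid()] object.
#' @param center band centre (nm).
#' @param width Gaussian standard deviation (nm), > 0.
#' @return Numeric vector over the grid.
#' @export
gaussian_band <- function(grid, center, width) {
  if (width <= 0) stopf("band width must be > 0")
  exp(-(as.numeric(grid) - center)^2 / (2 * width^2))
}

#' Default serum fluorophore set
#'
#' Five components at the excitation/emission peak positions characteristic
#' of cattle serum: three protein-like bands (`trp_1` 285/342, dominant;
#' `trp_2` 300/350; `tyr_like` 270/320) with retinol-independent lognormal
#' amounts, the free-retinol band (`retinol_free` 325/447, amount equal to
#' the true concentration), and the retinol-binding-protein band
#' (`rbp_bound` 330/520, amount 0.6 x concentration plus seeded scatter).
#'
#' @return List of five [fluorophore()] objects.
#' @export
default_fluorophores <- function() {
  list(
    fluorophore("trp_1", 285, 342, brightness = 1000,
                concentration_model = "independent_lognormal"),
    fluorophore("trp_2", 300, 350, brightness = 400,
                concentration_model = "independent_lognormal"),
    fluorophore("tyr_like", 270, 320, brightness = 250,
                concentration_model = "independent_lognormal"),
    fluorophore("retinol_free", 325, 447, brightness = 0.35,
                concentration_model = "retinol_linked"),
    fluorophore("rbp_bound", 330, 520, brightness = 0.5,
                concentration_model = "retinol_linked_secondary"))
}

#' Simulator configuration
#'
#' Defaults reproduce the reference study conditions: 208 samples x 3 analytical
#' replicates on the 250-450/5 x 250-600/1 nm grids; retinol concentrations
#' from a truncated normal with mean 46.7, SD 25.8, range 11.0-124.0 IU/dl
#' (the calibration-set descriptive statistics); 2% additive noise and 1%
#' multiplicative replicate jitter.
#'
#' @param n_samples number of samples (>= 4).
#' @param replicates analytical replicates per sample.
#' @param conc_mean,conc_sd,conc_range truncated-normal parameters, IU/dl.
#' @param noise_sd additive Gaussian noise SD as a fraction of the median
#'   noiseless signal.
#' @param replicate_jitter SD of the per-replicate multiplicative factor.
#' @param scatter add Rayleigh scatter ridges (first and second order) to
#'   every scan.
#' @param ex_grid,em_grid wavelength grids.
#' @param seed RNG seed; everything downstream is reproducible from it.
#' @return Object of class `serum_sim_config`.
#' @export
serum_sim_config <- function(n_samples = 208L, replicates = 3L,
                             conc_mean = 46.7, conc_sd = 25.8,
                             conc_range = c(11.0, 124.0),
                             noise_sd = 0.02, replicate_jitter = 0.01,
                             scatter = FALSE,
                             ex_grid = make_grid(250, 450, 5),
                             em_grid = make_grid(250, 600, 1),
                             seed = 1L) {
  if (n_samples < 4L) stopf("n_samples must be >= 4 (got %d)", n_samples)
  stopifnot(replicates >= 1L, conc_sd >= 0, noise_sd >= 0,
            replicate_jitter >= 0, length(conc_range) == 2L,
            conc_range[1] > 0, conc_range[2] > conc_range[1])
  structure(list(n_samples = as.integer(n_samples),
                 replicates = as.integer(replicates),
                 conc_mean = conc_mean, conc_sd = conc_sd,
                 conc_range = conc_range, noise_sd = noise_sd,
                 replicate_jitter = replicate_jitter, scatter = scatter,
                 ex_grid = ex_grid, em_grid = em_grid,
                 seed = as.integer(seed)),
            class = "serum_sim_config")
}

# unseeded truncated-normal sampler (rejection)
rtruncnorm_impl <- function(n, mean, sd, lower, upper) {
  if (sd == 0) {
    if (mean < lower || mean > upper)
      stopf("empty truncation region: mean %g outside [%g, %g]",
            mean, lower, upper)
    return(rep(mean, n))
  }
  if (stats::pnorm(upper, mean, sd) - stats::pnorm(lower, mean, sd) < 1e-12)
    stopf("empty truncation region [%g, %g]", lower, upper)
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(2L * (n - length(out)) + 10L, mean, sd)
    out <- c(out, draw[draw >= lower & draw <= upper])
  }
  out[seq_len(n)]
}

#' Draw true retinol concentrations
#'
#' Seeded truncated-normal draws: `normal(conc_mean, conc_sd)` rejected
#' outside `conc_range`.
#'
#' @param config a [serum_sim_config()].
#' @return Numeric vector of `n_samples` concentrations (IU/dl).
#' @export
draw_concentrations <- function(config) {
  stopifnot(inherits(config, "serum_sim_config"))
  with_seed(config$seed,
            rtruncnorm_impl(config$n_samples, config$conc_mean, config$conc_sd,
                            config$conc_range[1], config$conc_range[2]))
}

#' Simulate a serum EEM dataset with known trilinear ground truth
#'
#' Noiseless cell intensity is
#' `sum_f amount_f(sample) * brightness_f * em_band_f(em) * ex_band_f(ex)`;
#' each replicate scan is the sample's noiseless EEM times a multiplicative
#' jitter factor plus additive Gaussian noise whose SD is
#' `noise_sd x median(noiseless signal)`. Optional Rayleigh ridges (first
#' and second order) are superimposed. Fully reproducible from
#' `config$seed`.
#'
#' @param config a [serum_sim_config()].
#' @param fluorophores list of [fluorophore()] objects.
#' @return Object of class `simulated_dataset`: `stack` (an `eem_stack`
#'   with reference values attached), `reference` (named vector, IU/dl),
#'   `truth` (list: `em_profiles`, `ex_profiles` — unit-max band shapes —,
#'   `scores` `[sample x F]` already including brightness, `names`),
#'   `config`, `fluorophores`.
#' @export
simulate_dataset <- function(config = serum_sim_config(),
                             fluorophores = default_fluorophores()) {
  stopifnot(inherits(config, "serum_sim_config"), length(fluorophores) >= 1L)
  nf <- length(fluorophores)
  n <- config$n_samples
  em <- config$em_grid; ex <- config$ex_grid
  for (fl in fluorophores)
    if (fl$ex_center < min(ex) || fl$ex_center > max(ex) ||
        fl$em_center < min(em) || fl$em_center > max(em))
      stopf("fluorophore '%s' centre lies outside the grids", fl$name)
  em_prof <- vapply(fluorophores, function(fl)
    gaussian_band(em, fl$em_center, fl$em_width), numeric(length(em)))
  ex_prof <- vapply(fluorophores, function(fl)
    gaussian_band(ex, fl$ex_center, fl$ex_width), numeric(length(ex)))
  colnames(em_prof) <- colnames(ex_prof) <-
    vapply(fluorophores, `[[`, character(1), "name")

  with_seed(config$seed, {
    conc <- rtruncnorm_impl(n, config$conc_mean, config$conc_sd,
                            config$conc_range[1], config$conc_range[2])
    amounts <- matrix(0, n, nf, dimnames = list(NULL, colnames(em_prof)))
    for (f in seq_len(nf)) {
      fl <- fluorophores[[f]]
      amounts[, f] <- switch(fl$concentration_model,
        independent_lognormal = stats::rlnorm(n, meanlog = 0, sdlog = 0.25),
        retinol_linked = conc,
        retinol_linked_secondary =
          pmax(fl$link_coef * conc + stats::rnorm(n, 0, fl$link_sd), 0))
    }
    scores <- sweep(amounts, 2L,
                    vapply(fluorophores, `[[`, numeric(1), "brightness"), "*")

    # noiseless per-sample EEMs. The noise scale is anchored to the median
    # of the signal-bearing cells (above 1% of the stack maximum): most of
    # an EEM is empty, so the plain all-cell median would be pulled toward
    # zero and make the relative noise setting meaningless
    noiseless <- lapply(seq_len(n), function(s)
      em_prof %*% (t(ex_prof) * scores[s, ]))
    vals <- unlist(lapply(noiseless, as.vector))
    signal_cells <- vals[vals > 0.01 * max(vals)]
    med_signal <- if (length(signal_cells)) stats::median(signal_cells) else 0
    noise_abs <- config$noise_sd * med_signal

    ridge <- NULL
    if (config$scatter) {
      amp <- 2 * max(vapply(noiseless, max, numeric(1)))
      EM <- matrix(as.numeric(em), length(em), length(ex))
      EX <- matrix(as.numeric(ex), length(em), length(ex), byrow = TRUE)
      ridge <- amp * exp(-(EM - EX)^2 / (2 * 5^2)) +
        0.5 * amp * exp(-(EM - 2 * EX)^2 / (2 * 5^2))
    }

    ids <- sprintf("S%03d", seq_len(n))
    eems <- vector("list", n * config$replicates)
    k <- 0L
    for (s in seq_len(n)) {
      for (r in seq_len(config$replicates)) {
        k <- k + 1L
        jit <- 1 + stats::rnorm(1L, 0, config$replicate_jitter)
        z <- jit * noiseless[[s]]
        if (!is.null(ridge)) z <- z + ridge
        if (noise_abs > 0)
          z <- z + stats::rnorm(length(z), 0, noise_abs)
        eems[[k]] <- eem(z, ex, em, sample_id = ids[s], replicate_id = r)
      }
    }
    reference <- stats::setNames(conc, ids)
    structure(list(stack = build_stack(eems, reference = reference),
                   reference = reference,
                   truth = list(em_profiles = em_prof, ex_profiles = ex_prof,
                                scores = scores, names = colnames(em_prof)),
                   config = config, fluorophores = fluorophores),
              class = "simulated_dataset")
  })
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf(paste0("<simulated_dataset> %d samples x %d replicates, ",
                     "%d fluorophores, seed %d\n"),
              x$config$n_samples, x$config$replicates,
              length(x$fluorophores), x$config$seed))
  invisible(x)
}

#' Split a dataset into calibration and validation stacks
#'
#' The split is at sample level (replicate scans never straddle the two
#' sets) and seeded; reference values are carried along.
#'
#' @param ds a [simulate_dataset()] result or an `eem_stack`.
#' @param n_cal,n_val set sizes in samples; `n_cal + n_val` must not exceed
#'   the number of distinct samples.
#' @param seed split seed.
#' @return List with `calibration` and `validation` stacks and the drawn
#'   `cal_ids` / `val_ids`.
#' @export
split_calibration_validation <- function(ds, n_cal, n_val, seed = 1L) {
  stack <- if (inherits(ds, "simulated_dataset")) ds$stack else ds
  stopifnot(inherits(stack, "eem_stack"))
  ids <- unique(sample_ids(stack))
  if (n_cal + n_val > length(ids))
    stopf("n_cal + n_val = %d exceeds the %d available samples",
          n_cal + n_val, length(ids))
  picked <- with_seed(seed, sample(ids, n_cal + n_val))
  cal_ids <- picked[seq_len(n_cal)]
  val_ids <- picked[n_cal + seq_len(n_val)]
  subset_stack <- function(keep_ids) {
    keep <- sample_ids(stack) %in% keep_ids
    ref <- if (!is.null(stack$reference)) stack$reference[keep_ids]
    build_stack(stack$eems[keep], reference = ref)
  }
  list(calibration = subset_stack(cal_ids), validation = subset_stack(val_ids),
       cal_ids = cal_ids, val_ids = val_ids)
}

#' Write a simulated dataset to disk
#'
#' Emits the manifest + per-scan EEM CSVs + reference CSV via
#' [write_stack_csv()], plus `truth.json` with the generator's ground-truth
#' profiles and scores, so the pipeline can run on disk-backed synthetic
#' data exactly as on instrument exports.
#'
#' @param ds a `simulated_dataset`.
#' @param dir destination directory.
#' @return `dir`, invisibly.
#' @export
write_dataset_csv <- function(ds, dir) {
  stopifnot(inherits(ds, "simulated_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_stack_csv(ds$stack, dir)
  jsonlite::write_json(
    list(names = ds$truth$names,
         em_profiles = ds$truth$em_profiles,
         ex_profiles = ds$truth$ex_profiles,
         scores = ds$truth$scores),
    file.path(dir, "truth.json"), digits = NA)
  invisible(dir)
}
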