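# Scatter-region handling and unit-variance scaling.
#
# Serum EEMs carry three physical scatter ridges that are not trilinear and
# must be removed before PARAFAC/PLS: first-order Rayleigh (em = ex),
# second-order Rayleigh (em = 2 ex), and the water Raman band, red-shifted
# from the excitation line by a fixed energy (~3400 cm^-1 for the O-H
# stretch).

#' Scatter-band settings
#'
#' @param rayleigh1_halfwidth half-width (nm) of the excised band around the
#'   first-order Rayleigh line em = ex.
#' @param rayleigh2_halfwidth half-width (nm) around the second-order line
#'   em = 2 ex.
#' @param raman_shift Raman shift of the solvent band in cm^-1 (3400 for
#'   water's O-H stretch).
#' @param raman_halfwidth half-width (nm) around the Raman ridge.
#' @param mode `"excise"` sets ridge cells missing (preferred before PARAFAC,
#'   whose masked ALS handles missingness); `"interpolate"` replaces them by
#'   linear interpolation along the emission axis (preferred before PLS,
#'   which needs a dense matrix).
#' @return An object of class `scatter_bands`.
#' @export
scatter_bands <- function(rayleigh1_halfwidth = 15, rayleigh2_halfwidth = 15,
                          raman_shift = 3400, raman_halfwidth = 10,
                          mode = c("excise", "interpolate")) {
  mode <- match.arg(mode)
  if (rayleigh1_halfwidth < 0 || rayleigh2_halfwidth < 0 || raman_halfwidth < 0)
    stopf("scatter half-widths must be >= 0")
  if (raman_shift <= 0) stopf("raman_shift must be > 0")
  structure(list(rayleigh1_halfwidth = rayleigh1_halfwidth,
                 rayleigh2_halfwidth = rayleigh2_halfwidth,
                 raman_shift = raman_shift, raman_halfwidth = raman_halfwidth,
                 mode = mode),
            class = "scatter_bands")
}

#' Emission wavelength of the solvent Raman ridge
#'
#' Converts an excitation wavelength and a Raman shift to the emission
#' wavelength of the scattered band:
#' `em = 1 / (1/ex - shift * 1e-7)` with wavelengths in nm and the shift in
#' cm^-1 (the 1e-7 factor converts nm^-1 to cm^-1).
#'
#' @param ex excitation wavelength(s), nm.
#' @param shift Raman shift, cm^-1.
#' @return Emission wavelength(s), nm.
#' @examples
#' raman_center(350, 3400)  # ~397.3 nm, water Raman band
#' @export
raman_center <- function(ex, shift = 3400) {
  if (any(ex <= 0)) stopf("excitation wavelength must be > 0")
  inv <- 1 / ex - shift * 1e-7
  if (any(inv <= 0))
    stopf("nonphysical Raman shift: 1/ex <= shift for ex = %g nm", ex[inv <= 0][1])
  1 / inv
}

#' Remove scatter ridges from an EEM
#'
#' Cells within the configured half-widths of the first-order Rayleigh
#' (`em = ex`), second-order Rayleigh (`em = 2 ex`) or solvent Raman ridge
#' are excised (set missing) or replaced by linear interpolation along the
#' emission axis between the nearest flanking non-ridge cells (nearest
#' retained value is extended at the grid edges). All other cells are
#' untouched; excision is idempotent.
#'
#' @param x an [eem()] or `eem_stack`.
#' @param bands a [scatter_bands()] object.
#' @return Object of the same class as `x` with ridge cells handled.
#' @export
remove_scatter <- function(x, bands = scatter_bands()) {
  stopifnot(inherits(bands, "scatter_bands"))
  if (inherits(x, "eem_stack")) {
    out <- x
    mask <- scatter_mask(x$ex_grid, x$em_grid, bands)
    out$eems <- lapply(x$eems, remove_scatter_one, bands = bands, mask = mask)
    return(out)
  }
  stopifnot(inherits(x, "eem"))
  remove_scatter_one(x, bands, scatter_mask(x$ex_grid, x$em_grid, bands))
}

# logical [em x ex] matrix: TRUE where a cell sits on a scatter ridge
scatter_mask <- function(ex_grid, em_grid, bands) {
  ex <- as.numeric(ex_grid)
  em <- as.numeric(em_grid)
  EM <- matrix(em, length(em), length(ex))
  EX <- matrix(ex, length(em), length(ex), byrow = TRUE)
  m <- abs(EM - EX) <= bands$rayleigh1_halfwidth |
       abs(EM - 2 * EX) <= bands$rayleigh2_halfwidth
  rc <- raman_center(ex, bands$raman_shift)
  m | abs(EM - matrix(rc, length(em), length(ex), byrow = TRUE)) <=
      bands$raman_halfwidth
}

remove_scatter_one <- function(e, bands, mask) {
  z <- e$intensity
  z[mask] <- NA_real_
  if (bands$mode == "interpolate") {
    em <- as.numeric(e$em_grid)
    for (j in seq_len(ncol(z))) {
      col_mask <- mask[, j]
      if (!any(col_mask)) next
      known <- which(!is.na(z[, j]))
      if (length(known) < 2L) next  # nothing to interpolate from
      fill <- which(col_mask & is.na(z[, j]))
      z[fill, j] <- stats::approx(em[known], z[known, j], xout = em[fill],
                                  method = "linear", rule = 2)$y
    }
  }
  e$intensity <- z
  e
}

#' Unit-variance scale a sample x variable matrix
#'
#' Centres every column and divides by its sample standard deviation
#' (`n - 1` denominator). Zero-variance columns cannot be scaled; they are
#' dropped and recorded in the returned parameters so that
#' [apply_scaling()] treats held-out data identically.
#'
#' @param X numeric matrix `[sample x variable]`, at least two rows, no
#'   missing entries.
#' @return List of class `scaling_params` elements: `X` (scaled matrix),
#'   `mean`, `sd` (statistics of the retained columns), `keep` (logical,
#'   which input columns survive), `dropped` (indices of zero-variance
#'   columns).
#' @export
uv_scale <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stopf("unit-variance scaling needs at least 2 rows")
  if (anyNA(X)) stopf("unit-variance scaling requires a dense matrix (no NA)")
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  keep <- sdv > 0
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2L, mu[keep], "-"),
              2L, sdv[keep], "/")
  params <- structure(list(mean = mu[keep], sd = sdv[keep], keep = keep,
                           dropped = which(!keep)),
                      class = "scaling_params")
  list(X = Xs, params = params)
}

#' Apply stored calibration scaling to new data
#'
#' Validation rows must be scaled with the calibration set's statistics;
#' this applies `(x - mean) / sd` columnwise using the parameters from
#' [uv_scale()], dropping the same zero-variance columns.
#'
#' @param params `scaling_params` from [uv_scale()].
#' @param X matrix with the same column count as the matrix the parameters
#'   were estimated on.
#' @return Scaled matrix restricted to the retained columns.
#' @export
apply_scaling <- function(params, X) {
  stopifnot(inherits(params, "scaling_params"))
  X <- as.matrix(X)
  if (ncol(X) != length(params$keep))
    stopf("column mismatch: scaling fitted on %d columns, data has %d",
          length(params$keep), ncol(X))
  sweep(sweep(X[, params$keep, drop = FALSE], 2L, params$mean, "-"),
        2L, params$sd, "/")
}
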