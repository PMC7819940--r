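# NIPALS PLS1 calibration of retinol concentration from unfolded EEMs.
#
# X is the unit-variance-scaled sample x variable matrix from
# unfold() + uv_scale(); y the HPLC reference concentrations (IU/dl).
# The response is centred and scaled internally and restored at prediction.

#' Fit a PLS1 regression by NIPALS
#'
#' Extracts `A` latent variables by the classical NIPALS recursion with
#' X-deflation: `w = X'y / ||X'y||`, `t = Xw`, `p = X't / t't`,
#' `q = y't / t't`, `X <- X - tp'`. Regression coefficients on the scaled
#' variables are assembled as `b = W (P'W)^-1 q`. If a score vector's norm
#' collapses (`A` exceeds the effective rank) the model is truncated to the
#' attained number of latent variables and flagged.
#'
#' @param X scaled predictor matrix `[n x p]` (see [uv_scale()]).
#' @param y response vector (IU/dl), length `n`, non-constant.
#' @param A number of latent variables; needs `n >= A + 2` and `p >= A`.
#' @param scaling optional `scaling_params` used to build `X`; stored so
#'   [predict.pls_model()] can accept raw unfolded matrices.
#' @param vmap optional variable map from [unfold()] (post scaling-drop; see
#'   Details) for refolding coefficients and VIP into contour maps.
#' @param ex_grid,em_grid optional grids for refolding.
#' @details When `scaling` drops zero-variance columns, pass the variable
#'   map already restricted to the retained columns
#'   (`vmap[scaling$keep, ]`): `fit_pls` checks `nrow(vmap) == ncol(X)`.
#' @return Object of class `pls_model` with elements `n_lv`, `weights` (W),
#'   `x_loadings` (P), `y_loadings` (q), `scores` (T, training),
#'   `coefficients` (b, scaled-variable scale), `fitted` (training
#'   predictions, IU/dl), `y_mean`, `y_sd`, `scaling`, `vmap`, `truncated`.
#' @export
fit_pls <- function(X, y, A, scaling = NULL, vmap = NULL,
                    ex_grid = NULL, em_grid = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  A <- as.integer(A)
  if (length(y) != n) stopf("length(y) = %d but X has %d rows", length(y), n)
  if (n < A + 2L) stopf("need n >= A + 2 (n = %d, A = %d)", n, A)
  if (p < A) stopf("need p >= A (p = %d, A = %d)", p, A)
  y_mean <- mean(y); y_sd <- stats::sd(y)
  if (y_sd == 0) stopf("zero-variance response")
  if (!is.null(vmap) && nrow(vmap) != p)
    stopf("variable map rows (%d) must match ncol(X) (%d); restrict the map to the columns retained by scaling",
          nrow(vmap), p)
  u <- (y - y_mean) / y_sd

  W <- matrix(0, p, A); P <- matrix(0, p, A); Tm <- matrix(0, n, A)
  q <- numeric(A)
  Xa <- X; ya <- u
  attained <- 0L
  for (a in seq_len(A)) {
    w <- crossprod(Xa, ya)
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) break
    w <- w / wn
    t_a <- Xa %*% w
    tt <- sum(t_a^2)
    if (tt < 1e-12) break
    P[, a] <- crossprod(Xa, t_a) / tt
    q[a] <- sum(ya * t_a) / tt
    W[, a] <- w
    Tm[, a] <- t_a
    Xa <- Xa - tcrossprod(t_a, P[, a])
    ya <- ya - q[a] * t_a
    attained <- a
  }
  if (attained == 0L) stopf("no latent variable could be extracted")
  truncated <- attained < A
  W <- W[, seq_len(attained), drop = FALSE]
  P <- P[, seq_len(attained), drop = FALSE]
  Tm <- Tm[, seq_len(attained), drop = FALSE]
  q <- q[seq_len(attained)]
  b <- W %*% solve(crossprod(P, W), q)
  fitted_scaled <- as.vector(X %*% b)
  structure(list(n_lv = attained, weights = W, x_loadings = P, y_loadings = q,
                 scores = Tm, coefficients = as.vector(b),
                 fitted = y_mean + y_sd * fitted_scaled,
                 y_mean = y_mean, y_sd = y_sd, scaling = scaling,
                 vmap = vmap, ex_grid = ex_grid, em_grid = em_grid,
                 truncated = truncated),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d latent variables, %d variables%s\n",
              x$n_lv, length(x$coefficients),
              if (x$truncated) " (rank-truncated)" else ""))
  invisible(x)
}

#' Predict concentrations from a fitted PLS model
#'
#' @param object a [fit_pls()] model.
#' @param newdata raw unfolded matrix (scaled internally with the stored
#'   calibration parameters when the model carries them, otherwise assumed
#'   already scaled). Column count must match what the model was built from.
#' @param ... unused.
#' @return Numeric vector of predicted concentrations (IU/dl).
#' @export
predict.pls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  Xs <- if (!is.null(object$scaling)) apply_scaling(object$scaling, newdata)
        else newdata
  if (ncol(Xs) != length(object$coefficients))
    stopf("newdata has %d usable columns but the model expects %d",
          ncol(Xs), length(object$coefficients))
  as.vector(object$y_mean + object$y_sd * (Xs %*% object$coefficients))
}

# truncated coefficient vectors b_(1..a) for every a <= n_lv, as a p x A
# matrix (used by cross-validation to score all component counts per fold)
pls_coef_path <- function(model) {
  p <- nrow(model$weights)
  out <- matrix(0, p, model$n_lv)
  for (a in seq_len(model$n_lv)) {
    Wa <- model$weights[, seq_len(a), drop = FALSE]
    Pa <- model$x_loadings[, seq_len(a), drop = FALSE]
    out[, a] <- Wa %*% solve(crossprod(Pa, Wa), model$y_loadings[seq_len(a)])
  }
  out
}

# seeded k-fold assignment stratified by y quantile: samples are sorted by
# y and fold labels shuffled within consecutive blocks of k
stratified_folds <- function(y, k, seed) {
  n <- length(y)
  if (k < 2L) stopf("need at least 2 folds")
  if (n < 2L * k) stopf("too few samples (%d) for %d-fold cross-validation", n, k)
  ord <- order(y)
  folds <- integer(n)
  with_seed(seed, {
    for (start in seq(1L, n, by = k)) {
      block <- ord[start:min(start + k - 1L, n)]
      folds[block] <- sample(seq_len(k))[seq_along(block)]
    }
  })
  folds
}

# Q^2 = 1 - PRESS/SS_tot for every component count 1..max_A
pls_cv_q2 <- function(X, y, max_A, k_folds, seed) {
  n <- nrow(X)
  folds <- stratified_folds(y, k_folds, seed)
  press <- numeric(max_A)
  for (k in seq_len(k_folds)) {
    tr <- folds != k
    A_eff <- min(max_A, sum(tr) - 2L, ncol(X))
    m <- fit_pls(X[tr, , drop = FALSE], y[tr], A_eff)
    bpath <- pls_coef_path(m)
    pred <- X[!tr, , drop = FALSE] %*% bpath  # scaled-y predictions per A
    pred <- m$y_mean + m$y_sd * pred
    for (a in seq_len(max_A)) {
      a_use <- min(a, m$n_lv)
      press[a] <- press[a] + sum((y[!tr] - pred[, a_use])^2)
    }
  }
  1 - press / sum((y - mean(y))^2)
}

#' Cross-validated choice of the number of latent variables
#'
#' Computes `Q^2 = 1 - PRESS / SS_tot` from seeded, y-quantile-stratified
#' k-fold cross-validation for every candidate component count. The
#' selected count is the smallest one whose `Q^2` lies within `tol` of the
#' maximum — a parsimony rule: a component is only worth keeping when it
#' buys a non-negligible gain in predictive ability.
#'
#' @param X scaled calibration matrix.
#' @param y reference concentrations.
#' @param max_A largest candidate number of latent variables.
#' @param k_folds number of folds (7 by default, the SIMCA convention).
#' @param seed fold-assignment seed.
#' @param tol absolute `Q^2` slack for the parsimony rule.
#' @return List `A` (selected count) and `q2` (named vector over candidates).
#' @export
choose_components_cv <- function(X, y, max_A = 10L, k_folds = 7L, seed = 1L,
                                 tol = 0.01) {
  X <- as.matrix(X)
  max_A <- min(as.integer(max_A), ncol(X), nrow(X) - 2L -
                 ceiling(nrow(X) / k_folds))
  if (max_A < 1L) stopf("too few samples to cross-validate any component count")
  q2 <- pls_cv_q2(X, y, max_A, k_folds, seed)
  names(q2) <- seq_len(max_A)
  list(A = unname(which(q2 >= max(q2) - tol)[1L]), q2 = q2)
}

#' Calibration and validation metrics
#'
#' `RMSEE` (root mean square error of estimation) uses the
#' degrees-of-freedom-corrected denominator `n_cal - 1 - A`; `RMSEP` is the
#' plain root mean square prediction error on the validation set; `R^2` is
#' the squared Pearson correlation of observed versus predicted per set
#' (with the `1 - SSE/SST` variant reported as `r2_alt_*`); `RPD` is the
#' validation reference standard deviation (`n - 1` denominator) over RMSEP.
#'
#' @param y_cal,yhat_cal observed and predicted concentrations, calibration.
#' @param y_val,yhat_val observed and predicted, validation.
#' @param A number of latent variables in the model.
#' @return Object of class `calibration_metrics`: `r2_cal`, `r2_val`,
#'   `r2_alt_cal`, `r2_alt_val`, `rmsee`, `rmsep`, `rpd` (`Inf` with
#'   `rpd_infinite = TRUE` when RMSEP is 0), `rpd_band`, `n_cal`, `n_val`,
#'   `A`.
#' @examples
#' # the published headline: validation sd 26.8 IU/dl over RMSEP 6.4 IU/dl
#' round(26.8 / 6.4, 1)  # RPD 4.2
#' @export
compute_metrics <- function(y_cal, yhat_cal, y_val, yhat_val, A) {
  stopifnot(length(y_cal) == length(yhat_cal),
            length(y_val) == length(yhat_val),
            length(y_cal) > 0, length(y_val) > 0)
  n_cal <- length(y_cal); n_val <- length(y_val)
  if (n_cal <= A + 1L)
    stopf("RMSEE undefined: n_cal = %d <= A + 1 = %d", n_cal, A + 1L)
  rmsee <- sqrt(sum((y_cal - yhat_cal)^2) / (n_cal - 1L - A))
  rmsep <- sqrt(mean((y_val - yhat_val)^2))
  rpd <- if (rmsep == 0) Inf else stats::sd(y_val) / rmsep
  out <- structure(list(
    r2_cal = stats::cor(y_cal, yhat_cal)^2,
    r2_val = stats::cor(y_val, yhat_val)^2,
    r2_alt_cal = 1 - sum((y_cal - yhat_cal)^2) / sum((y_cal - mean(y_cal))^2),
    r2_alt_val = 1 - sum((y_val - yhat_val)^2) / sum((y_val - mean(y_val))^2),
    rmsee = rmsee, rmsep = rmsep, rpd = rpd,
    rpd_infinite = is.infinite(rpd),
    rpd_band = if (is.infinite(rpd)) "good" else interpret_rpd(rpd),
    n_cal = n_cal, n_val = n_val, A = A),
    class = "calibration_metrics")
  out
}

#' @export
print.calibration_metrics <- function(x, ...) {
  cat(sprintf("<calibration_metrics> A = %d\n", x$A))
  cat(sprintf("  calibration (n = %d): R2 = %.3f, RMSEE = %.2f IU/dl\n",
              x$n_cal, x$r2_cal, x$rmsee))
  cat(sprintf("  validation  (n = %d): R2 = %.3f, RMSEP = %.2f IU/dl, RPD = %.2f (%s)\n",
              x$n_val, x$r2_val, x$rmsep, x$rpd, x$rpd_band))
  invisible(x)
}

#' Interpret an RPD value
#'
#' Band convention for the ratio of performance to deviation: below 1.5 the
#' model is only good for preliminary screening, 2.0-2.5 gives satisfactory
#' prediction, above 2.5 good prediction. The 1.5-2.0 gap that this
#' convention leaves open is labelled `"intermediate"`.
#'
#' @param rpd positive RPD value.
#' @return One of `"preliminary"`, `"intermediate"`, `"satisfactory"`,
#'   `"good"`.
#' @export
interpret_rpd <- function(rpd) {
  stopifnot(is.numeric(rpd), rpd > 0)
  if (rpd < 1.5) "preliminary"
  else if (rpd < 2.0) "intermediate"
  else if (rpd <= 2.5) "satisfactory"
  else "good"
}

#' Variable importance in projection (VIP)
#'
#' `VIP_j = sqrt(p * sum_a(w_ja^2 SSY_a) / sum_a SSY_a)` where
#' `SSY_a = q_a^2 t_a' t_a` is the response variation explained by latent
#' variable `a`; the normalisation makes `mean(VIP^2) = 1` exactly, so
#' variables with VIP above 1 carry more than average importance. When the
#' model carries a variable map the VIP vector is refolded into an
#' emission x excitation contour map and its local maxima above 1 are
#' extracted as peaks, merged within a 15 nm (ex) x 30 nm (em)
#' neighbourhood and sorted by VIP descending.
#'
#' @param model a [fit_pls()] model.
#' @param merge_ex,merge_em peak-merging neighbourhood half-sizes, nm.
#' @return Object of class `vip_result`: `vip` (per variable),
#'   `important_mask` (`vip > 1`), and, when a map is available, `vip_map`
#'   and `peaks` (data frame `ex`, `em`, `vip`).
#' @export
vip_scores <- function(model, merge_ex = 15, merge_em = 30) {
  stopifnot(inherits(model, "pls_model"))
  W <- model$weights
  ssy <- model$y_loadings^2 * colSums(model$scores^2)
  p <- nrow(W)
  vip <- sqrt(p * as.vector(W^2 %*% ssy) / sum(ssy))
  out <- list(vip = vip, important_mask = vip > 1, vip_map = NULL,
              peaks = NULL)
  if (!is.null(model$vmap)) {
    out$vip_map <- fold(vip, model$vmap, model$ex_grid, model$em_grid)
    out$peaks <- map_peaks(out$vip_map, model$ex_grid, model$em_grid,
                           floor = 1, merge_ex = merge_ex,
                           merge_em = merge_em)
  }
  structure(out, class = "vip_result")
}

# local maxima of an [em x ex] map above `floor`, merged within a
# merge_ex x merge_em rectangle, strongest first
map_peaks <- function(map, ex_grid, em_grid, floor = 1,
                      merge_ex = 15, merge_em = 30) {
  ex <- as.numeric(ex_grid); em <- as.numeric(em_grid)
  z <- map
  z[is.na(z)] <- -Inf
  nr <- nrow(z); nc <- ncol(z)
  cand <- which(z > floor, arr.ind = TRUE)
  is_local_max <- function(i, j) {
    nb <- z[max(1L, i - 1L):min(nr, i + 1L), max(1L, j - 1L):min(nc, j + 1L)]
    z[i, j] >= max(nb)
  }
  keep <- cand[apply(cand, 1L, function(rc) is_local_max(rc[1L], rc[2L])), ,
               drop = FALSE]
  if (!nrow(keep)) return(data.frame(ex = numeric(0), em = numeric(0),
                                     vip = numeric(0)))
  pk <- data.frame(ex = ex[keep[, 2L]], em = em[keep[, 1L]],
                   vip = z[keep])
  pk <- pk[order(-pk$vip), ]
  merged <- pk[0, ]
  for (i in seq_len(nrow(pk))) {
    if (!nrow(merged) ||
        all(abs(merged$ex - pk$ex[i]) > merge_ex |
            abs(merged$em - pk$em[i]) > merge_em))
      merged <- rbind(merged, pk[i, ])
  }
  rownames(merged) <- NULL
  merged
}

#' Regression-coefficient contour map
#'
#' Refolds the PLS coefficient vector (on unit-variance-scaled variables)
#' into an emission x excitation map, preserving sign: negative and
#' positive regions show wavelengths pulling the prediction down or up.
#'
#' @param model a [fit_pls()] model carrying a variable map.
#' @return Numeric matrix `[em x ex]` with `NA` at dropped cells.
#' @export
coefficient_map <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  if (is.null(model$vmap)) stopf("model carries no variable map to refold with")
  fold(model$coefficients, model$vmap, model$ex_grid, model$em_grid)
}

#' Response-permutation validation of a PLS calibration
#'
#' Refits the model on `n_perm` seeded random permutations of the response,
#' recording for each the correlation of the permuted with the original
#' response, the training `R^2` and the cross-validated `Q^2`. Regression
#' lines of `R^2` (and `Q^2`) on the absolute correlation — through the
#' permuted points plus the unpermuted model at correlation 1 — give the
#' intercepts at correlation 0; a valid model shows small intercepts
#' (conventional bands: `R^2` intercept below 0.3-0.4, `Q^2` intercept
#' below 0.05).
#'
#' @param X scaled calibration matrix.
#' @param y response.
#' @param A number of latent variables.
#' @param n_perm number of permutations (>= 20).
#' @param k_folds folds for the per-permutation `Q^2`.
#' @param seed RNG seed for permutations and folds.
#' @return Object of class `permutation_result`: `r2_intercept`,
#'   `q2_intercept`, `n_perm` and `table` (per-permutation `cor_abs`, `r2`,
#'   `q2`; the final row is the unpermuted model).
#' @export
permutation_test <- function(X, y, A, n_perm = 100L, k_folds = 7L, seed = 1L) {
  X <- as.matrix(X)
  n_perm <- as.integer(n_perm)
  if (n_perm < 20L)
    stopf("need at least 20 permutations for a stable intercept (got %d)",
          n_perm)
  if (stats::sd(y) == 0) stopf("zero-variance response")
  perms <- with_seed(seed, replicate(n_perm, sample(length(y)),
                                     simplify = FALSE))
  one <- function(y_use) {
    m <- fit_pls(X, y_use, A)
    q2 <- pls_cv_q2(X, y_use, m$n_lv, k_folds, seed)[m$n_lv]
    c(r2 = stats::cor(m$fitted, y_use)^2, q2 = unname(q2))
  }
  rows <- lapply(perms, function(pm) {
    y_p <- y[pm]
    if (all(y_p == y)) y_p <- rev(y_p)  # exclude the identity permutation
    c(cor_abs = abs(stats::cor(y_p, y)), one(y_p))
  })
  unperm <- c(cor_abs = 1, one(y))
  tab <- as.data.frame(do.call(rbind, c(rows, list(unperm))))
  r2_int <- unname(stats::coef(stats::lm(r2 ~ cor_abs, data = tab))[1L])
  q2_int <- unname(stats::coef(stats::lm(q2 ~ cor_abs, data = tab))[1L])
  structure(list(r2_intercept = r2_int, q2_intercept = q2_int,
                 n_perm = n_perm, table = tab),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(paste0("<permutation_result> %d permutations: R2 intercept ",
                     "%.3f, Q2 intercept %.3f\n"),
              x$n_perm, x$r2_intercept, x$q2_intercept))
  invisible(x)
}
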