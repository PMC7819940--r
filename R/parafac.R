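# Trilinear PARAFAC decomposition of an EEM stack.
#
# The stack is modelled as X[i,j,k] ~ sum_f em[i,f] * ex[j,f] * score[k,f]:
# each component is one fluorophore with a fixed emission profile, a fixed
# excitation profile, and a per-scan amount. Fitting is alternating least
# squares with hierarchical (columnwise) nonnegative updates; missing cells
# (scatter-excised regions) are handled EM-style by imputing them from the
# current model each sweep. Spectral loadings are returned unit-norm with
# all magnitude in the sample scores, components ordered by explained
# variation.

#' PARAFAC fitting configuration
#'
#' @param nonneg logical length-3 vector: nonnegativity constraints for the
#'   emission, excitation and sample modes. Fluorescence spectra and
#'   concentrations are physically nonnegative, so all three default on.
#' @param n_starts number of seeded random initialisations; the best final
#'   fit (lowest residual sum of squares, ties broken by fewer iterations)
#'   is kept.
#' @param max_iter maximum ALS sweeps per start.
#' @param rel_tol convergence threshold on the relative change of the
#'   observed-cell residual sum of squares between sweeps.
#' @param seed integer; start `s` uses seed `seed + s - 1`.
#' @param init `"svd"` seeds the first start from the leading singular
#'   vectors of the three unfoldings (magnitudes, to respect
#'   nonnegativity), which converges far faster than random starts when
#'   spectral profiles overlap; remaining starts are random. `"random"`
#'   makes every start random.
#' @return An object of class `parafac_config`.
#' @export
parafac_config <- function(nonneg = c(em = TRUE, ex = TRUE, sample = TRUE),
                           n_starts = 10L, max_iter = 2500L, rel_tol = 1e-8,
                           seed = 1L, init = c("svd", "random")) {
  if (length(nonneg) == 1L) nonneg <- rep(nonneg, 3L)
  init <- match.arg(init)
  stopifnot(length(nonneg) == 3L, n_starts >= 1L, max_iter >= 1L, rel_tol > 0)
  structure(list(nonneg = as.logical(nonneg), n_starts = as.integer(n_starts),
                 max_iter = as.integer(max_iter), rel_tol = rel_tol,
                 seed = as.integer(seed), init = init),
            class = "parafac_config")
}

# khatri-rao column f = vec(outer(u_f, v_f)) with u varying fastest
khatri_rao <- function(U, V) {
  F <- ncol(U)
  out <- matrix(0, nrow(U) * nrow(V), F)
  for (f in seq_len(F)) out[, f] <- as.vector(outer(U[, f], V[, f]))
  out
}

# columnwise (hierarchical) least-squares update of factor M:
# minimises ||X(n) - M KR^T||^2 column by column; gram = KR^T KR, mtx = X(n) KR
hals_update <- function(M, gram, mtx, nonneg, inner = 10L) {
  # unconstrained mode: the block update has a closed form (joint
  # normal-equations solve), which converges much faster than columnwise
  # sweeps when components are collinear
  if (!nonneg) {
    ridge <- 1e-12 * max(diag(gram))
    return(t(solve(gram + diag(ridge, ncol(gram)), t(mtx))))
  }
  # gram and mtx are fixed while this mode is optimised, so repeating the
  # cheap columnwise sweeps solves the mode's (nonnegative) least-squares
  # subproblem much more tightly at negligible extra cost
  for (sweep_i in seq_len(inner)) {
    delta <- 0
    for (f in seq_len(ncol(M))) {
      denom <- gram[f, f]
      if (denom < 1e-12) denom <- 1e-12
      newcol <- M[, f] + (mtx[, f] - M %*% gram[, f]) / denom
      if (nonneg) {
        newcol <- pmax(newcol, 0)
        if (all(newcol == 0)) newcol[] <- 1e-12  # revive a dead component
      }
      delta <- delta + sum((newcol - M[, f])^2)
      M[, f] <- newcol
    }
    if (delta <= 1e-16 * sum(M^2)) break
  }
  M
}

# leading-singular-vector initialisation: |top-F eigenvectors| of each
# mode's unfolding gram; far better conditioned than random starts
svd_init <- function(Tarr, F) {
  Tc <- Tarr
  if (anyNA(Tc)) Tc[is.na(Tc)] <- mean(Tc, na.rm = TRUE)
  d <- dim(Tc)
  mode_vectors <- function(mat) {
    g <- tcrossprod(mat)
    ev <- eigen(g, symmetric = TRUE)$vectors[, seq_len(F), drop = FALSE]
    abs(ev) + 1e-6
  }
  X1 <- Tc; dim(X1) <- c(d[1L], d[2L] * d[3L])
  X2 <- matrix(aperm(Tc, c(2L, 1L, 3L)), d[2L], d[1L] * d[3L])
  X3 <- Tc; dim(X3) <- c(d[1L] * d[2L], d[3L])
  list(B = mode_vectors(X1), A = mode_vectors(X2), C = mode_vectors(t(X3)))
}

# single ALS run on tensor array Tarr [I em x J ex x K sample]
parafac_als <- function(Tarr, F, nonneg, max_iter, rel_tol, init_seed,
                        init_fac = NULL) {
  dims <- dim(Tarr)
  I <- dims[1L]; J <- dims[2L]; K <- dims[3L]
  miss <- is.na(Tarr)
  has_missing <- any(miss)
  Tmat <- Tarr
  dim(Tmat) <- c(I * J, K)              # rows: em fastest within ex
  if (has_missing) {
    midx <- which(miss)                 # array-order linear indices
    mi <- ((midx - 1L) %% I) + 1L                 # em index
    mj <- (((midx - 1L) %/% I) %% J) + 1L         # ex index
    mk <- ((midx - 1L) %/% (I * J)) + 1L          # scan index
    # the same cells in the ex-mode unfolding X2 [J x I*K]
    midx2 <- mj + (mi - 1L) * J + (mk - 1L) * (I * J)
    # start the completed tensor from the observed-cell mean
    imputed <- rep(mean(Tmat[-midx]), length(midx))
    Tmat[midx] <- imputed
  }
  X1 <- Tmat; dim(X1) <- c(I, J * K)    # em-mode unfolding
  arr <- Tmat; dim(arr) <- c(I, J, K)
  X2 <- matrix(aperm(arr, c(2L, 1L, 3L)), J, I * K)  # ex-mode unfolding
  norm2_completed <- sum(Tmat^2)

  fac <- init_fac %||% with_seed(init_seed, list(
    B = matrix(stats::runif(I * F), I, F),   # emission loadings
    A = matrix(stats::runif(J * F), J, F),   # excitation loadings
    C = matrix(stats::runif(K * F), K, F)))  # sample scores
  B <- fac$B; A <- fac$A; C <- fac$C

  norm_obs2 <- if (has_missing) sum(Tarr[!miss]^2) else sum(Tmat^2)
  sse <- Inf
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    # emission mode
    kr <- khatri_rao(A, C)
    B <- hals_update(B, crossprod(A) * crossprod(C), X1 %*% kr, nonneg[1L])
    # excitation mode
    kr <- khatri_rao(B, C)
    A <- hals_update(A, crossprod(B) * crossprod(C), X2 %*% kr, nonneg[2L])
    # sample mode
    kr3 <- khatri_rao(B, A)
    mtx3 <- crossprod(Tmat, kr3)
    C <- hals_update(C, crossprod(B) * crossprod(A), mtx3, nonneg[3L])

    if (has_missing) {
      # residual over the COMPLETED tensor via the factor grams, then
      # subtract the residual at the imputed cells to get the observed SSE
      sse_completed <- max(0, norm2_completed - 2 * sum(C * mtx3) +
        sum(crossprod(C) * (crossprod(B) * crossprod(A))))
      recon_miss <- rowSums(B[mi, , drop = FALSE] * A[mj, , drop = FALSE] *
                            C[mk, , drop = FALSE])
      sse_new <- max(0, sse_completed - sum((imputed - recon_miss)^2))
      # EM imputation: write the model values into every unfolding in place
      norm2_completed <- norm2_completed + sum(recon_miss^2) - sum(imputed^2)
      imputed <- recon_miss
      Tmat[midx] <- recon_miss
      X1[midx] <- recon_miss   # X1 shares Tmat's element order
      X2[midx2] <- recon_miss
    } else {
      # ||X - recon||^2 via the factor grams; kr3 and Tmat are unchanged by
      # the C update, so mtx3 still equals X(3) KR and no reconstruction is
      # needed
      sse_new <- norm_obs2 - 2 * sum(C * mtx3) +
        sum(crossprod(C) * (crossprod(B) * crossprod(A)))
      sse_new <- max(sse_new, 0)
    }
    trace <- c(trace, sse_new)
    if (is.finite(sse) && abs(sse - sse_new) <= rel_tol * max(sse, 1e-30)) {
      sse <- sse_new
      converged <- TRUE
      break
    }
    sse <- sse_new
  }
  list(B = B, A = A, C = C, sse = sse, n_iter = it, converged = converged,
       trace = trace, norm_obs2 = norm_obs2)
}

#' Fit a PARAFAC model to an EEM stack
#'
#' Decomposes the stack's three-way array (excitation x emission x scan)
#' into `n_comp` trilinear components by alternating least squares with,
#' by default, nonnegativity on all modes, multiple seeded random starts,
#' and EM-style imputation of missing (scatter-excised) cells. Emission and
#' excitation loadings are returned with unit Euclidean norm, sample scores
#' carry the magnitude, and components are ordered by explained variation.
#'
#' @param stack an [build_stack()] object.
#' @param n_comp number of components F (>= 1, no larger than any mode).
#' @param config a [parafac_config()].
#' @param init_factors optional list `B` (em), `A` (ex), `C` (scores), or a
#'   fitted `parafac_model` of the same rank (its factor magnitudes are
#'   used), taken as the first start in place of the SVD/random
#'   initialisation. [select_n_components()] warm-starts each candidate
#'   from the previous rank this way, and a constrained final fit is best
#'   warm-started from the unconstrained scan solution.
#' @return An object of class `parafac_model`: `n_components`,
#'   `sample_scores` `[scan x F]` (rownames are scan ids), `em_loadings`
#'   `[em x F]`, `ex_loadings` `[ex x F]`, `sse` (residual sum of squares
#'   over observed cells), `explained_pct`, `corcondia`, `converged`,
#'   `n_iter`, `sse_trace`, plus the grids and scan sample ids.
#' @export
fit_parafac <- function(stack, n_comp, config = parafac_config(),
                        init_factors = NULL) {
  stopifnot(inherits(stack, "eem_stack"), inherits(config, "parafac_config"))
  n_comp <- as.integer(n_comp)
  if (n_comp < 1L) stopf("n_comp must be >= 1")
  d <- stack_dims(stack)
  if (n_comp > min(d))
    stopf("n_comp = %d exceeds smallest tensor mode (%d)", n_comp, min(d))
  Tarr <- as_array(stack)
  obs <- !is.na(Tarr)
  if (!any(obs)) stopf("tensor has no observed cells")
  if (all(Tarr[obs] == 0))
    stopf("all-zero tensor: PARAFAC components are undefined")
  # identifiability: every slice of every mode needs more observed cells
  # than components
  slice_obs <- list(em = apply(obs, 1L, sum), ex = apply(obs, 2L, sum),
                    sample = apply(obs, 3L, sum))
  for (m in names(slice_obs))
    if (min(slice_obs[[m]]) <= n_comp)
      stopf("a %s-mode slice has only %d observed cells (need > %d)",
            m, min(slice_obs[[m]]), n_comp)

  if (inherits(init_factors, "parafac_model")) {
    stopifnot(init_factors$n_components == n_comp)
    init_factors <- list(B = abs(init_factors$em_loadings) + 1e-9,
                         A = abs(init_factors$ex_loadings) + 1e-9,
                         C = abs(init_factors$sample_scores) + 1e-9)
  }
  best <- NULL
  first_fac <- init_factors %||%
    (if (config$init == "svd") svd_init(Tarr, n_comp))
  for (s in seq_len(config$n_starts)) {
    run <- parafac_als(Tarr, n_comp, config$nonneg, config$max_iter,
                       config$rel_tol, init_seed = config$seed + s - 1L,
                       init_fac = if (s == 1L) first_fac)
    if (is.null(best) || run$sse < best$sse - 1e-12 * max(best$sse, 1) ||
        (abs(run$sse - best$sse) <= 1e-12 * max(best$sse, 1) &&
         run$n_iter < best$n_iter))
      best <- run
  }

  # normalise: unit-norm spectral loadings, magnitude into the scores
  B <- best$B; A <- best$A; C <- best$C
  for (f in seq_len(n_comp)) {
    nb <- sqrt(sum(B[, f]^2)); na_ <- sqrt(sum(A[, f]^2))
    if (nb > 0) { B[, f] <- B[, f] / nb; C[, f] <- C[, f] * nb }
    if (na_ > 0) { A[, f] <- A[, f] / na_; C[, f] <- C[, f] * na_ }
    if (!config$nonneg[3L] && sum(C[, f]) < 0) {
      # fix sign indeterminacy when scores are unconstrained
      C[, f] <- -C[, f]; B[, f] <- -B[, f]
    }
  }
  ord <- order(colSums(C^2), decreasing = TRUE)
  B <- B[, ord, drop = FALSE]; A <- A[, ord, drop = FALSE]
  C <- C[, ord, drop = FALSE]
  colnames(B) <- colnames(A) <- colnames(C) <- paste0("comp", seq_len(n_comp))
  rownames(C) <- vapply(stack$eems, function(e)
    paste(e$sample_id, e$replicate_id, sep = "."), character(1))

  model <- structure(list(
    n_components = n_comp, sample_scores = C, em_loadings = B,
    ex_loadings = A, sse = best$sse,
    explained_pct = 100 * (1 - best$sse / best$norm_obs2),
    corcondia = NA_real_, converged = best$converged, n_iter = best$n_iter,
    sse_trace = best$trace, ex_grid = stack$ex_grid, em_grid = stack$em_grid,
    scan_sample_ids = sample_ids(stack)),
    class = "parafac_model")
  # a collapsed (rank-deficient) solution has no defined core; keep NA so
  # model selection can treat the candidate as disqualified
  model$corcondia <- tryCatch(corcondia(model, stack),
                              error = function(e) NA_real_)
  model
}

#' @export
print.parafac_model <- function(x, ...) {
  cat(sprintf(paste0("<parafac_model> %d components, %.2f%% explained, ",
                     "core consistency %.1f%%, %s in %d iterations\n"),
              x$n_components, x$explained_pct, x$corcondia,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  pk <- component_peaks(x)
  for (f in seq_len(x$n_components))
    cat(sprintf("  comp%d: ex/em %g/%g nm\n", f, pk$ex[f], pk$em[f]))
  invisible(x)
}

# tensor-times-matrix along mode n of a 3-way array
ttm3 <- function(arr, M, mode) {
  d <- dim(arr)
  perm <- switch(mode, `1` = c(1L, 2L, 3L), `2` = c(2L, 1L, 3L),
                 `3` = c(3L, 1L, 2L))
  a <- aperm(arr, perm)
  mat <- matrix(a, d[mode], prod(d[-mode]))
  out <- M %*% mat
  res <- array(out, c(nrow(M), d[-mode]))
  aperm(res, order(perm))
}

#' Core consistency diagnostic (CORCONDIA)
#'
#' Measures how close the least-squares Tucker core of the data, given the
#' fitted PARAFAC loadings, is to the superdiagonal identity the trilinear
#' model implies: `100 * (1 - sum((g - t)^2) / sum(t^2))`. Values near 100
#' support the chosen component number; large drops indicate too many
#' components. Missing cells are imputed from the model before the core is
#' computed.
#'
#' @param model a fitted [fit_parafac()] model.
#' @param stack the stack it was fitted to.
#' @return Core consistency in percent (can be negative; at most 100).
#' @export
corcondia <- function(model, stack) {
  stopifnot(inherits(model, "parafac_model"), inherits(stack, "eem_stack"))
  Tarr <- as_array(stack)
  B <- model$em_loadings; A <- model$ex_loadings; C <- model$sample_scores
  F <- model$n_components
  if (anyNA(Tarr)) {
    miss <- is.na(Tarr)
    recon <- array(khatri_rao(B, A) %*% t(C), dim(Tarr))
    Tarr[miss] <- recon[miss]
  }
  # Moore-Penrose: a collapsed component (rank-deficient loadings) still
  # yields a defined core, which then sits far from the superidentity
  pinv <- function(M) {
    sv <- svd(M)
    keep <- sv$d > max(dim(M)) * max(sv$d) * 1e-12
    if (!any(keep)) stopf("singular loading matrix in core computation")
    sv$v[, keep, drop = FALSE] %*%
      (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
  }
  G <- ttm3(ttm3(ttm3(Tarr, pinv(B), 1L), pinv(A), 2L), pinv(C), 3L)
  superid <- array(0, c(F, F, F))
  for (f in seq_len(F)) superid[f, f, f] <- 1
  100 * (1 - sum((G - superid)^2) / F)
}

#' Tucker congruence between two loading vectors
#'
#' Cosine similarity `|a.b| / (||a|| ||b||)`; 1 means identical up to scale.
#' Used to match fitted components to ground truth and to flag degenerate
#' (two-factor) solutions.
#'
#' @param a,b numeric vectors of equal length.
#' @return Congruence coefficient in `[0, 1]`.
#' @export
tucker_congruence <- function(a, b) {
  abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
}

# greedy 1-1 matching of fitted components to reference profiles by the
# product of em- and ex-mode congruences; returns per-reference indices and
# congruences
match_components <- function(model, em_ref, ex_ref) {
  Fr <- ncol(em_ref)
  sim <- matrix(0, Fr, model$n_components)
  for (r in seq_len(Fr)) for (f in seq_len(model$n_components))
    sim[r, f] <- tucker_congruence(em_ref[, r], model$em_loadings[, f]) *
                 tucker_congruence(ex_ref[, r], model$ex_loadings[, f])
  match <- integer(Fr)
  work <- sim
  for (step in seq_len(min(Fr, model$n_components))) {
    best <- which(work == max(work), arr.ind = TRUE)[1L, ]
    match[best[1L]] <- best[2L]
    work[best[1L], ] <- -Inf   # reference row consumed
    work[, best[2L]] <- -Inf   # fitted component consumed
  }
  data.frame(reference = seq_len(Fr), fitted = match,
             em_congruence = vapply(seq_len(Fr), function(r)
               tucker_congruence(em_ref[, r], model$em_loadings[, match[r]]),
               numeric(1)),
             ex_congruence = vapply(seq_len(Fr), function(r)
               tucker_congruence(ex_ref[, r], model$ex_loadings[, match[r]]),
               numeric(1)))
}

#' Choose the PARAFAC component number by core consistency
#'
#' Fits every candidate component count and returns the largest one whose
#' core consistency stays at or above `threshold` and whose solution is not
#' degenerate (no component pair with Tucker congruence above
#' `degeneracy_cutoff` in both spectral modes). When no candidate
#' qualifies, the smallest candidate is returned carrying a
#' `warning = TRUE` attribute.
#'
#' @param stack an `eem_stack`.
#' @param F_range ascending integer candidates.
#' @param threshold core-consistency acceptance level in percent.
#' @param config a [parafac_config()].
#' @param degeneracy_cutoff congruence above which two components in both
#'   spectral modes mark a degenerate fit.
#' @param warm_start warm-start every candidate after the first from the
#'   previous rank's solution plus one seeded random component. With
#'   strongly collinear spectra (the protein bands of serum) cold starts
#'   routinely spend the added component refining the dominant subspace —
#'   a local minimum — instead of extracting the next dim fluorophore;
#'   growing the rank avoids that trap.
#' @return Integer component count, with attributes `diagnostics` (data
#'   frame of F, corcondia, degenerate, sse), `warning` (logical) and
#'   `model` (the fitted model at the returned count, handy as a warm
#'   start for a constrained refit).
#' @export
select_n_components <- function(stack, F_range = 2:7, threshold = 60,
                                config = parafac_config(),
                                degeneracy_cutoff = 0.95,
                                warm_start = TRUE) {
  F_range <- as.integer(F_range)
  if (!length(F_range) || is.unsorted(F_range))
    stopf("F_range must be a non-empty ascending sequence")
  prev <- NULL
  models <- list()
  diag_rows <- lapply(F_range, function(F) {
    init <- NULL
    if (warm_start && !is.null(prev) && ncol(prev$em_loadings) < F) {
      pad <- F - ncol(prev$em_loadings)
      init <- with_seed(config$seed + F, list(
        B = cbind(prev$em_loadings,
                  matrix(stats::runif(nrow(prev$em_loadings) * pad),
                         ncol = pad)),
        A = cbind(prev$ex_loadings,
                  matrix(stats::runif(nrow(prev$ex_loadings) * pad),
                         ncol = pad)),
        C = cbind(prev$sample_scores,
                  matrix(stats::runif(nrow(prev$sample_scores) * pad, 0,
                                      mean(abs(prev$sample_scores))),
                         ncol = pad))))
    }
    m <- fit_parafac(stack, F, config, init_factors = init)
    prev <<- m
    models[[as.character(F)]] <<- m
    degenerate <- FALSE
    if (F >= 2L) {
      for (f1 in seq_len(F - 1L)) for (f2 in (f1 + 1L):F) {
        if (tucker_congruence(m$em_loadings[, f1], m$em_loadings[, f2]) >
              degeneracy_cutoff &&
            tucker_congruence(m$ex_loadings[, f1], m$ex_loadings[, f2]) >
              degeneracy_cutoff)
          degenerate <- TRUE
      }
    }
    data.frame(F = F, corcondia = m$corcondia, degenerate = degenerate,
               sse = m$sse)
  })
  diagnostics <- do.call(rbind, diag_rows)
  ok <- !is.na(diagnostics$corcondia) &
    diagnostics$corcondia >= threshold & !diagnostics$degenerate
  if (any(ok)) {
    chosen <- max(diagnostics$F[ok])
    warn <- FALSE
  } else {
    chosen <- min(F_range)
    warn <- TRUE
    warning("no candidate component count reached the core-consistency ",
            "threshold; returning the smallest candidate")
  }
  structure(chosen, diagnostics = diagnostics, warning = warn,
            model = models[[as.character(chosen)]])
}

#' Excitation/emission peak positions of fitted components
#'
#' @param model a `parafac_model`.
#' @return Data frame with one row per component: `component`, `ex`, `em`
#'   (nm, the grid wavelengths of the loading maxima; ties break to the
#'   lowest wavelength via the first maximum).
#' @export
component_peaks <- function(model) {
  stopifnot(inherits(model, "parafac_model"))
  data.frame(
    component = seq_len(model$n_components),
    ex = as.numeric(model$ex_grid)[apply(model$ex_loadings, 2L, which.max)],
    em = as.numeric(model$em_grid)[apply(model$em_loadings, 2L, which.max)])
}

#' Pearson correlation between component scores and reference values
#'
#' Tests whether a component's per-scan scores track an external reference
#' (HPLC retinol, or the simulator's ground truth). Replicate scans inherit
#' their sample's reference value when a named per-sample vector is given.
#'
#' @param model a `parafac_model`.
#' @param component component index.
#' @param reference either a numeric vector with one value per scan (stack
#'   order) or a named vector keyed by `sample_id`.
#' @return List `r`, `p` (two-sided, from the t distribution with n-2
#'   degrees of freedom), `n`.
#' @export
score_reference_correlation <- function(model, component, reference) {
  stopifnot(inherits(model, "parafac_model"))
  scores <- model$sample_scores[, component]
  if (!is.null(names(reference))) {
    miss <- setdiff(unique(model$scan_sample_ids), names(reference))
    if (length(miss))
      stopf("reference lacks sample(s): %s", paste(miss, collapse = ", "))
    reference <- unname(reference[model$scan_sample_ids])
  }
  if (length(reference) != length(scores))
    stopf("reference length %d does not match %d scans",
          length(reference), length(scores))
  n <- length(scores)
  if (n < 3L) stopf("need at least 3 scans for a correlation test")
  if (stats::sd(scores) == 0 || stats::sd(reference) == 0)
    stopf("zero-variance scores or reference")
  ct <- stats::cor.test(scores, reference, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Write PARAFAC loadings and scores as CSV files
#'
#' One file per mode (`em_loadings.csv`, `ex_loadings.csv`,
#' `sample_scores.csv`), wavelength or scan id in the first column and one
#' column per component.
#'
#' @param model a `parafac_model`.
#' @param dir destination directory.
#' @return `dir`, invisibly.
#' @export
write_parafac_csv <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(em_nm = as.numeric(model$em_grid),
                              model$em_loadings),
                   file.path(dir, "em_loadings.csv"), row.names = FALSE)
  utils::write.csv(data.frame(ex_nm = as.numeric(model$ex_grid),
                              model$ex_loadings),
                   file.path(dir, "ex_loadings.csv"), row.names = FALSE)
  utils::write.csv(data.frame(scan = rownames(model$sample_scores),
                              model$sample_scores),
                   file.path(dir, "sample_scores.csv"), row.names = FALSE)
  invisible(dir)
}
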