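# Independent oracles and small fixture builders shared across tests.

# small wavelength grids for fast fixtures
tiny_ex <- function() make_grid(250, 450, 25)   # 9 points
tiny_em <- function() make_grid(250, 600, 10)   # 36 points

# an EEM with reproducible random intensities
random_eem <- function(seed = 1, ex = tiny_ex(), em = tiny_em(),
                       sample_id = "S1", replicate_id = 1L, na_frac = 0) {
  set.seed(seed)
  z <- matrix(stats::runif(length(em) * length(ex), 0, 100),
              length(em), length(ex))
  if (na_frac > 0)
    z[sample(length(z), round(na_frac * length(z)))] <- NA
  eem(z, ex, em, sample_id = sample_id, replicate_id = replicate_id)
}

# exact trilinear tensor stack from given factor matrices
# (B [em x F], A [ex x F], C [scan x F])
trilinear_stack <- function(B, A, C, ex, em) {
  eems <- lapply(seq_len(nrow(C)), function(k) {
    z <- B %*% (t(A) * C[k, ])
    eem(z, ex, em, sample_id = sprintf("S%02d", k))
  })
  build_stack(eems)
}

# --- independent PARAFAC oracle -------------------------------------------
# plain unconstrained ALS via normal equations (a different algorithm from
# the package's columnwise HALS updates); returns the final residual SSE
naive_parafac_sse <- function(Tarr, F, n_iter = 500, seed = 1) {
  d <- dim(Tarr)
  unfoldings <- list(
    matrix(Tarr, d[1], d[2] * d[3]),
    matrix(aperm(Tarr, c(2, 1, 3)), d[2], d[1] * d[3]),
    matrix(aperm(Tarr, c(3, 1, 2)), d[3], d[1] * d[2]))
  set.seed(seed)
  fac <- lapply(d, function(n) matrix(stats::rnorm(n * F), n, F))
  kr <- function(U, V) {
    out <- matrix(0, nrow(U) * nrow(V), F)
    for (f in seq_len(F)) out[, f] <- as.vector(outer(V[, f], U[, f]))
    out
  }
  for (it in seq_len(n_iter)) {
    # mode 1: columns of unfolding 1 ordered (j fastest, then k)
    Z <- kr(fac[[3]], fac[[2]])
    fac[[1]] <- t(solve(crossprod(Z), crossprod(Z, t(unfoldings[[1]]))))
    Z <- kr(fac[[3]], fac[[1]])
    fac[[2]] <- t(solve(crossprod(Z), crossprod(Z, t(unfoldings[[2]]))))
    Z <- kr(fac[[2]], fac[[1]])
    fac[[3]] <- t(solve(crossprod(Z), crossprod(Z, t(unfoldings[[3]]))))
  }
  Z <- kr(fac[[2]], fac[[1]])
  sum((unfoldings[[3]] - fac[[3]] %*% t(Z))^2)
}

# --- independent least-squares oracle for PLS at full rank ----------------
ols_fitted <- function(X, y) {
  Xi <- cbind(1, X)
  as.vector(Xi %*% solve(crossprod(Xi), crossprod(Xi, y)))
}

# closed-form mean of a normal truncated to [a, b]
truncnorm_mean <- function(mu, sd, a, b) {
  al <- (a - mu) / sd; be <- (b - mu) / sd
  mu + sd * (stats::dnorm(al) - stats::dnorm(be)) /
    (stats::pnorm(be) - stats::pnorm(al))
}

# scaled random regression fixture shared by the PLS tests
random_pls_data <- function(seed, n = 30, p = 8, noise = 0.1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  beta <- rnorm(p)
  y <- as.vector(X %*% beta) + rnorm(n, 0, noise)
  list(X = scale(X)[, ], y = y)
}

# two-step serum fit: unconstrained warm-started rank scan up to F, then a
# nonnegative refit from that solution -- the reliable route to isolating
# the dim retinol component from the collinear protein bands
fit_parafac_twostep <- function(stack, F, seed = 1) {
  # threshold -Inf and an unreachable degeneracy cutoff force the scan to
  # settle on F itself, so its attribute carries the rank-F warm start
  scan <- suppressWarnings(select_n_components(
    stack, 2:F, threshold = -Inf, degeneracy_cutoff = 2,
    config = parafac_config(nonneg = c(FALSE, FALSE, FALSE), n_starts = 1,
                            max_iter = 250, rel_tol = 1e-7, seed = seed)))
  fit_parafac(stack, F,
              parafac_config(n_starts = 1, max_iter = 300, rel_tol = 1e-8,
                             seed = seed),
              init_factors = attr(scan, "model"))
}
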