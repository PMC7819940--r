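fast_cfg <- function(...) parafac_config(n_starts = 2, max_iter = 500,
                                         rel_tol = 1e-10, ...)

test_that("a noiseless rank-1 tensor is recovered exactly", {
  ex <- tiny_ex(); em <- tiny_em()
  B <- cbind(gaussian_band(em, 447, 28))
  A <- cbind(gaussian_band(ex, 325, 18))
  C <- cbind(seq(10, 100, length.out = 8))
  st <- trilinear_stack(B, A, C, ex, em)
  m <- fit_parafac(st, 1, fast_cfg())
  expect_gt(tucker_congruence(m$em_loadings[, 1], B[, 1]), 0.999)
  expect_gt(tucker_congruence(m$ex_loadings[, 1], A[, 1]), 0.999)
  expect_gt(tucker_congruence(m$sample_scores[, 1], C[, 1]), 0.999)
  expect_lt(m$sse / sum(as_array(st)^2, na.rm = TRUE), 1e-8)
  expect_equal(m$corcondia, 100, tolerance = 1e-6)
})

test_that("noiseless four-fluorophore data are recovered per component", {
  ds <- simulate_dataset(
    serum_sim_config(n_samples = 24, replicates = 1, noise_sd = 0,
                     replicate_jitter = 0, seed = 7),
    default_fluorophores()[1:4])
  # the three protein bands overlap, so the tail of the optimisation is
  # slow: exact recovery needs a tight tolerance and patience
  m <- fit_parafac(ds$stack, 4,
                   parafac_config(n_starts = 4, max_iter = 2000,
                                  rel_tol = 1e-12))
  mt <- serumEEM:::match_components(m, ds$truth$em_profiles,
                                    ds$truth$ex_profiles)
  expect_true(all(mt$em_congruence > 0.99))
  expect_true(all(mt$ex_congruence > 0.99))
  expect_equal(sort(mt$fitted), 1:4)
})

test_that("degenerate inputs are rejected", {
  ex <- make_grid(300, 320, 10); em <- make_grid(300, 340, 10)
  zero <- build_stack(list(eem(matrix(0, 5, 3), ex, em, "z")))
  expect_error(fit_parafac(zero, 1, fast_cfg()), "all-zero")
  small <- build_stack(list(eem(matrix(1:15, 5, 3), ex, em, "s")))
  expect_error(fit_parafac(small, 2, fast_cfg()), "exceeds")
})

test_that("observed-cell SSE is monotone across ALS sweeps", {
  set.seed(11)
  ex <- tiny_ex(); em <- tiny_em()
  eems <- lapply(1:6, function(k) {
    z <- matrix(runif(length(em) * length(ex), 0, 10), length(em))
    z[sample(length(z), 40)] <- NA   # exercise the EM-imputation path
    eem(z, ex, em, sprintf("S%d", k))
  })
  m <- fit_parafac(build_stack(eems), 2,
                   parafac_config(n_starts = 1, max_iter = 120,
                                  rel_tol = 1e-14))
  tr <- m$sse_trace
  expect_true(all(diff(tr) <= 1e-8 * pmax(tr[-length(tr)], 1)))

  # and on the dense path
  dense <- lapply(eems, function(e) { e$intensity[is.na(e$intensity)] <- 5; e })
  m2 <- fit_parafac(build_stack(dense), 2,
                    parafac_config(n_starts = 1, max_iter = 120,
                                   rel_tol = 1e-14))
  tr2 <- m2$sse_trace
  expect_true(all(diff(tr2) <= 1e-8 * pmax(tr2[-length(tr2)], 1)))
})

test_that("the fitted SSE matches an independent ALS oracle", {
  # rank-2 structure with mild noise; both algorithms should reach the same
  # optimum on this well-conditioned problem
  ex <- make_grid(250, 450, 25); em <- make_grid(250, 600, 25)
  B <- cbind(gaussian_band(em, 340, 30), gaussian_band(em, 460, 35))
  A <- cbind(gaussian_band(ex, 285, 20), gaussian_band(ex, 330, 20))
  set.seed(3)
  C <- matrix(runif(10 * 2, 10, 100), 10, 2)
  st <- trilinear_stack(B, A, C, ex, em)
  arr <- as_array(st)
  arr <- arr + array(rnorm(length(arr), 0, 0.05 * stats::median(arr)),
                     dim(arr))
  noisy <- build_stack(lapply(seq_len(dim(arr)[3]), function(k)
    eem(arr[, , k], ex, em, sprintf("S%d", k))))
  m <- fit_parafac(noisy, 2,
                   parafac_config(nonneg = c(FALSE, FALSE, FALSE),
                                  n_starts = 4, max_iter = 2000,
                                  rel_tol = 1e-13))
  oracle <- min(vapply(1:3, function(s)
    naive_parafac_sse(arr, 2, n_iter = 600, seed = s), numeric(1)))
  expect_equal(m$sse, oracle, tolerance = 1e-6)
})

test_that("core consistency is 100 for exact-rank models and collapses when
           overfitting", {
  ex <- tiny_ex(); em <- tiny_em()
  B <- cbind(gaussian_band(em, 340, 30), gaussian_band(em, 500, 40))
  A <- cbind(gaussian_band(ex, 280, 20), gaussian_band(ex, 350, 25))
  set.seed(5)
  C <- matrix(runif(12 * 2, 5, 50), 12, 2)
  st <- trilinear_stack(B, A, C, ex, em)

  # model built directly from the generating factors: core must be the
  # exact superidentity
  truth_model <- structure(list(
    n_components = 2L,
    em_loadings = sweep(B, 2, sqrt(colSums(B^2)), "/"),
    ex_loadings = sweep(A, 2, sqrt(colSums(A^2)), "/"),
    sample_scores = sweep(C, 2, sqrt(colSums(B^2)) * sqrt(colSums(A^2)), "*"),
    ex_grid = ex, em_grid = em), class = "parafac_model")
  expect_equal(corcondia(truth_model, st), 100, tolerance = 1e-6)

  m2 <- fit_parafac(st, 2, fast_cfg())
  expect_equal(m2$corcondia, 100, tolerance = 1e-3)
  m3 <- fit_parafac(st, 3, fast_cfg())
  expect_lt(m3$corcondia, 90)
})

test_that("component-count selection finds the true rank", {
  ex <- tiny_ex(); em <- tiny_em()
  B <- cbind(gaussian_band(em, 340, 30))
  A <- cbind(gaussian_band(ex, 280, 20))
  C <- cbind(seq(5, 50, length.out = 10))
  st <- trilinear_stack(B, A, C, ex, em)
  sel <- select_n_components(st, 1:3, threshold = 60, config = fast_cfg())
  expect_equal(as.integer(sel), 1L)
  expect_false(attr(sel, "warning"))

  # when every candidate over-factors a rank-1 tensor, the extra components
  # split one band (degenerate pair), no candidate qualifies, and the
  # smallest is returned with a warning
  expect_warning(
    sel2 <- select_n_components(st, 2:3, threshold = 60,
                                config = fast_cfg()),
    "smallest")
  expect_equal(as.integer(sel2), 2L)
  expect_true(attr(sel2, "warning"))
})

test_that("component peaks read off the loading maxima with low-wavelength
           ties", {
  ex <- make_grid(250, 450, 5); em <- make_grid(250, 600, 1)
  model <- structure(list(
    n_components = 2L,
    ex_loadings = cbind(gaussian_band(ex, 325, 18), rep(1, length(ex))),
    em_loadings = cbind(gaussian_band(em, 447, 28), rep(1, length(em))),
    ex_grid = ex, em_grid = em), class = "parafac_model")
  pk <- component_peaks(model)
  expect_equal(pk$ex, c(325, 250))   # flat loading ties to first grid point
  expect_equal(pk$em, c(447, 250))
})

test_that("score-reference correlation matches its closed forms", {
  model <- structure(list(
    n_components = 1L,
    sample_scores = cbind(c(1, 2, 3, 4, 5)),
    scan_sample_ids = paste0("S", 1:5)), class = "parafac_model")
  expect_equal(score_reference_correlation(model, 1, c(1, 2, 3, 4, 5))$r, 1)
  expect_equal(score_reference_correlation(model, 1, -c(1, 2, 3, 4, 5))$r, -1)
  named <- setNames(c(5, 4, 3, 2, 1), paste0("S", 1:5))
  expect_equal(score_reference_correlation(model, 1, named)$r, -1)
  expect_error(score_reference_correlation(model, 1, rep(1, 5)),
               "zero-variance")
  expect_error(score_reference_correlation(model, 1, 1:3), "match")
})
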