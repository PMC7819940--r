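
test_that("a single latent variable captures a one-factor response", {
  set.seed(1)
  n <- 40; p <- 6
  # centred orthogonal columns (orthogonalised against the intercept too),
  # so the first weight vector is exactly the signal axis
  X <- qr.Q(qr(cbind(1, matrix(rnorm(n * p), n, p))))[, -1] * sqrt(n - 1)
  y <- 2 * X[, 1]
  m <- fit_pls(X, y, 1)
  expect_lt(max(abs(m$fitted - y)), 1e-8)
  expect_gt(abs(m$coefficients[1]), 1e3 * max(abs(m$coefficients[-1])))
})

test_that("full-rank PLS1 equals the least-squares oracle", {
  for (seed in 1:3) {
    d <- random_pls_data(seed, n = 20, p = 5)
    m <- fit_pls(d$X, d$y, 5)
    expect_equal(m$fitted, ols_fitted(d$X, d$y), tolerance = 1e-8)
  }
})

test_that("a response orthogonal to X yields a null model", {
  set.seed(2)
  n <- 24
  X <- scale(matrix(rnorm(n * 4), n, 4))[, ]
  y0 <- rnorm(n)
  # project y onto the orthogonal complement of the columns of X (with a
  # whisper of noise so the first weight vector is numerically defined)
  y <- as.vector(y0 - X %*% solve(crossprod(X), crossprod(X, y0))) +
    1e-7 * rnorm(n)
  m <- fit_pls(X, y, 2)
  expect_lt(max(abs(m$coefficients)), 1e-4)
  expect_equal(m$fitted, rep(mean(y), n), tolerance = 1e-4)
})

test_that("NIPALS scores are orthogonal and coefficients reproduce the
           deflation recursion", {
  for (seed in 4:6) {
    d <- random_pls_data(seed, n = 25, p = 10, noise = 0.5)
    m <- fit_pls(d$X, d$y, 4)
    G <- crossprod(m$scores)
    offdiag <- G - diag(diag(G))
    expect_lt(max(abs(offdiag)),
              1e-8 * max(sqrt(outer(diag(G), diag(G)))))
    # prediction via T q equals prediction via assembled b
    recursion <- m$y_mean + m$y_sd * as.vector(m$scores %*% m$y_loadings)
    expect_equal(m$fitted, recursion, tolerance = 1e-10)
  }
})

test_that("rank-deficient requests truncate with a flag", {
  set.seed(7)
  X <- scale(matrix(rnorm(20 * 2), 20, 2))[, ]
  X <- cbind(X, X[, 1] + X[, 2])      # rank 2, p = 3
  y <- X[, 1] - X[, 2] + rnorm(20, 0, .01)
  m <- fit_pls(X, y, 3)
  expect_true(m$truncated)
  expect_lte(m$n_lv, 2L)
})

test_that("prediction is consistent on training rows and affine in shifts", {
  d <- random_pls_data(8, n = 30, p = 6)
  sc <- uv_scale(d$X)
  m <- fit_pls(sc$X, d$y, 3, scaling = sc$params)
  expect_equal(predict(m, d$X), m$fitted, tolerance = 1e-10)
  shift <- rep(0, 6); shift[2] <- 1.5
  delta <- predict(m, d$X[1, , drop = FALSE] + rep(shift, each = 1)) -
    predict(m, d$X[1, , drop = FALSE])
  expect_equal(as.vector(delta),
               m$y_sd * 1.5 / sc$params$sd[2] * m$coefficients[2],
               tolerance = 1e-8)
  expect_error(predict(m, d$X[, 1:3]), "mismatch")
})

test_that("cross-validation picks one component for one-factor data and
           rejects pure noise", {
  set.seed(9)
  n <- 100
  X <- qr.Q(qr(cbind(1, matrix(rnorm(n * 6), n, 6))))[, -1] * sqrt(n - 1)
  y1 <- 3 * X[, 2]
  cv <- choose_components_cv(X, y1, max_A = 4, k_folds = 5, seed = 1)
  expect_equal(cv$A, 1L)
  expect_gt(cv$q2[1], 0.99)

  # under the null (response pure noise) Q^2 is negative in expectation;
  # individual draws fluctuate, so the property is asserted on the average
  q2_null <- rowMeans(vapply(1:10, function(i)
    choose_components_cv(X, rnorm(n), max_A = 4, k_folds = 5,
                         seed = 1)$q2, numeric(4)))
  expect_true(all(q2_null <= 0))
})

test_that("calibration metrics follow their definitions", {
  # validation set engineered to sd 26.8 and RMSEP 6.4
  y_val <- 46.7 + 26.8 * c(-1, 1) / sqrt(2)
  yhat_val <- y_val + c(6.4, -6.4)
  y_cal <- c(20, 40, 60, 80); yhat_cal <- c(22, 38, 61, 79)
  met <- compute_metrics(y_cal, yhat_cal, y_val, yhat_val, A = 1)
  expect_equal(sd(y_val), 26.8, tolerance = 1e-12)
  expect_equal(met$rmsep, 6.4, tolerance = 1e-12)
  expect_equal(met$rpd, 4.1875, tolerance = 1e-12)
  expect_equal(round(met$rpd, 1), 4.2)
  expect_equal(met$rpd_band, "good")
  expect_equal(met$rmsee, sqrt(sum((y_cal - yhat_cal)^2) / (4 - 1 - 1)))

  perfect <- compute_metrics(y_cal, y_cal, y_val, y_val, A = 1)
  expect_true(perfect$rpd_infinite)
  unit <- compute_metrics(y_cal, yhat_cal,
                          46.7 + c(-1, 1) / sqrt(2),
                          46.7 + c(-1, 1) / sqrt(2) + c(1, -1), A = 1)
  expect_equal(unit$rpd, 1, tolerance = 1e-12)
  expect_error(compute_metrics(y_cal[1:2], yhat_cal[1:2], y_val, yhat_val, 1),
               "RMSEE undefined")
})

test_that("RPD bands label the published convention", {
  expect_equal(interpret_rpd(4.2), "good")
  expect_equal(interpret_rpd(1.4), "preliminary")
  expect_equal(interpret_rpd(2.2), "satisfactory")
  expect_equal(interpret_rpd(1.7), "intermediate")
  expect_equal(interpret_rpd(2.5), "satisfactory")
  expect_error(interpret_rpd(-1))
})

test_that("VIP is unit-normalised and flat weights give VIP = 1", {
  # two anti-correlated copies of the signal: equal weight magnitudes
  set.seed(10)
  z <- rnorm(30)
  X <- cbind(z, -z) + matrix(rnorm(60, 0, 1e-8), 30, 2)
  y <- z
  m1 <- fit_pls(scale(X)[, ], y, 1)
  v1 <- vip_scores(m1)
  expect_equal(v1$vip, c(1, 1), tolerance = 1e-6)

  for (seed in 11:13) {
    d <- random_pls_data(seed, n = 25, p = 12, noise = 0.5)
    m <- fit_pls(d$X, d$y, 3)
    v <- vip_scores(m)
    expect_equal(mean(v$vip^2), 1, tolerance = 1e-10)
    expect_true(all(v$important_mask == (v$vip > 1)))
  }
})

test_that("VIP and coefficient maps refold through the variable map", {
  ex <- tiny_ex(); em <- tiny_em()
  set.seed(14)
  eems <- lapply(1:12, function(k) random_eem(300 + k,
                                              sample_id = sprintf("S%d", k)))
  st <- build_stack(eems)
  uf <- unfold(st)
  y <- rnorm(12, 50, 20)
  sc <- uv_scale(uf$X)
  m <- fit_pls(sc$X, y, 2, scaling = sc$params,
               vmap = uf$vmap[sc$params$keep, , drop = FALSE],
               ex_grid = ex, em_grid = em)
  cmap <- coefficient_map(m)
  idx <- cbind(match(m$vmap$em, as.numeric(em)),
               match(m$vmap$ex, as.numeric(ex)))
  expect_equal(unname(cmap[idx]), unname(m$coefficients))
  v <- vip_scores(m)
  expect_equal(unname(v$vip_map[idx]), unname(v$vip))
  if (nrow(v$peaks)) {
    # peaks are important cells and local maxima of the map
    expect_true(all(v$peaks$vip > 1))
  }
})

test_that("permutation intercepts are near zero for a genuine calibration", {
  set.seed(15)
  n <- 36; p <- 10
  X <- scale(matrix(rnorm(n * p), n, p))[, ]
  y <- as.vector(X %*% c(3, 2, rep(0, p - 2))) + rnorm(n, 0, 0.5)
  pr <- permutation_test(X, y, A = 2, n_perm = 30, k_folds = 5, seed = 4)
  expect_lt(pr$q2_intercept, 0.05)
  expect_lt(pr$r2_intercept, 0.4)
  expect_equal(nrow(pr$table), 31L)
  expect_equal(pr$table$cor_abs[31], 1)
  expect_error(permutation_test(X, y, A = 2, n_perm = 5), "at least 20")
  expect_error(permutation_test(X, rep(1, n), A = 2, n_perm = 30),
               "zero-variance")
})
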