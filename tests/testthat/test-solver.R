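# BCGD group-lasso solver and entry-path computation.

test_that("penalty at or above lambda_max yields the zero solution", {
  set.seed(1)
  x <- std_cols(matrix(rnorm(20 * 8), 20, 8))
  y <- rnorm(20); y <- y - mean(y)
  grp <- rep(1:4, each = 2)
  lm0 <- lambda_max(x, y, grp)
  fit <- group_lasso(x, y, grp, lambda = lm0 * 1.0000001)
  expect_true(all(fit$coefficients == 0))
  expect_length(fit$active, 0)
})

test_that("unpenalized full-rank fit is ordinary least squares", {
  set.seed(2)
  x <- std_cols(matrix(rnorm(30 * 6), 30, 6))
  y <- rnorm(30); y <- y - mean(y)
  fit <- group_lasso(x, y, rep(1:3, each = 2), lambda = 0, tol = 1e-10)
  expect_equal(fit$coefficients, as.numeric(qr.solve(x, y)),
               tolerance = 1e-7)
})

test_that("solutions match an independent proximal-gradient oracle", {
  set.seed(3)
  for (rep in 1:4) {
    n <- 20; pc <- 8
    x <- std_cols(matrix(rnorm(n * pc), n, pc))
    y <- rnorm(n); y <- y - mean(y)
    grp <- rep(1:4, each = 2)
    lam <- 0.3 * lambda_max(x, y, grp)
    fit <- group_lasso(x, y, grp, lambda = lam, tol = 1e-10)
    # oracle minimises RSS + 2*lam*pen, the same minimiser as
    # 0.5*RSS + lam*pen
    b_or <- prox_oracle(x, y, grp, lam1 = 2 * lam)
    expect_lt(max(abs(fit$coefficients - b_or)), 1e-6)
    expect_equal(fit$objective,
                 oracle_objective(b_or, x, y, grp, lam1 = 2 * lam) / 2,
                 tolerance = 1e-8)
  }
})

test_that("solution is invariant to the ordering of the groups", {
  set.seed(4)
  x <- std_cols(matrix(rnorm(25 * 9), 25, 9))
  y <- rnorm(25); y <- y - mean(y)
  gl <- list(1:3, 4:6, 7:9)
  lam <- 0.2 * lambda_max(x, y, gl)
  f1 <- group_lasso(x, y, gl, lambda = lam, tol = 1e-10)
  f2 <- group_lasso(x, y, gl[c(3, 1, 2)], lambda = lam, tol = 1e-10)
  expect_lt(max(abs(f1$coefficients - f2$coefficients)), 1e-7)
})

test_that("singleton groups with unit weights recover lasso solutions", {
  set.seed(5)
  n <- 40; p <- 10
  x <- std_cols(matrix(rnorm(n * p), n, p))
  y <- x[, 1] - 2 * x[, 2] + rnorm(n, sd = 0.5); y <- y - mean(y)
  lam <- 0.25 * max(abs(crossprod(x, y)))
  fit <- group_lasso(x, y, seq_len(p), lambda = lam,
                     weights = rep(1, p), tol = 1e-10)
  gn <- glmnet::glmnet(x, y, lambda = lam / n, standardize = FALSE,
                       intercept = FALSE, thresh = 1e-14)
  expect_lt(max(abs(fit$coefficients - as.numeric(gn$beta))), 1e-6)
})

test_that("warm-started path matches cold-start objectives", {
  set.seed(6)
  x <- std_cols(matrix(rnorm(30 * 8), 30, 8))
  y <- x[, 1] + x[, 4] + rnorm(30, sd = 0.3); y <- y - mean(y)
  grp <- rep(1:4, each = 2)
  path <- entry_path(x, y, grp, n_lambda = 12, lambda_min_ratio = 0.05,
                     tol = 1e-10, stop_when_all = FALSE)
  for (k in c(3, 7, 12)) {
    lam <- path$lambda[k]
    cold <- group_lasso(x, y, grp, lambda = lam, tol = 1e-10)
    expect_setequal(path$active_sets[[k]], cold$active)
  }
})

test_that("entry order: strong groups first, empty above lambda_max,
           orthonormal designs sorted by gradient norm", {
  set.seed(7)
  n <- 32
  x <- qr.Q(qr(matrix(rnorm(n * 8), n, 8)))   # orthonormal columns
  grp <- rep(1:4, each = 2)
  b <- c(3, 3, 0, 0, 1, 1, 0.3, 0.3)
  y <- as.numeric(x %*% b)                     # noiseless
  path <- entry_path(x, y, grp, n_lambda = 80, tol = 1e-9)
  gnorm <- vapply(split(seq_len(8), grp),
                  function(i) sqrt(sum(crossprod(x[, i], y)^2)) / sqrt(2),
                  numeric(1))
  expect_equal(path$full_order, order(-gnorm))
  expect_equal(path$order[1], 1L)

  empty <- entry_path(x, y, grp,
                      lambda_grid = max(gnorm) * c(3, 2, 1.5, 1.0001))
  expect_length(empty$order, 0)
  expect_error(entry_path(x, y, grp, lambda_grid = c(1, 2)), "decreasing")
})

test_that("bisection separates groups entering between grid points", {
  set.seed(8)
  n <- 40
  x <- qr.Q(qr(matrix(rnorm(n * 6), n, 6)))
  grp <- rep(1:3, each = 2)
  # two close (but distinct) entry levels and one far
  y <- as.numeric(x %*% c(2, 2, 1.9, 1.9, 0.5, 0.5))
  coarse <- entry_path(x, y, grp, n_lambda = 4, lambda_min_ratio = 0.05,
                       tol = 1e-9)
  expect_equal(coarse$order, c(1L, 2L, 3L))
  expect_true(coarse$first_entry[1] > coarse$first_entry[2])
})
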