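# Laplacian operator, incidence decomposition, augmentation, criterion.

test_that("Laplacian core matches the normalized-graph convention", {
  op <- laplacian_operator(trait_network(cbind(1, 2), 2), p = 1)
  expect_equal(op$core, rbind(c(1, -1), c(-1, 1)))
  expect_equal(sort(eigen(op$core)$values), c(0, 2))

  tri <- laplacian_operator(trait_network(rbind(c(1, 2), c(2, 3), c(1, 3)), 3),
                            p = 2)
  expect_equal(tri$core[1, 2], -0.5)   # -(2*2)^(-1/2)
  expect_error(laplacian_operator(trait_network(cbind(1, 2), 3), p = 1),
               "degree 0")
})

test_that("S S^T = L exactly and L is non-negative definite", {
  set.seed(5)
  for (rep in 1:5) {
    G <- sample(2:5, 1)
    all_e <- t(combn(G, 2))
    # random connected-enough subset: keep each vertex covered
    repeat {
      keep <- sort(sample(nrow(all_e), sample(seq_len(nrow(all_e)), 1)))
      if (all(tabulate(all_e[keep, ], G) > 0)) break
    }
    net <- trait_network(all_e[keep, , drop = FALSE], G)
    p <- sample(1:3, 1)
    op <- laplacian_operator(net, p)
    S <- incidence_matrix(op)
    L <- laplacian_matrix(op)
    expect_equal(S %*% t(S), L, tolerance = 1e-14, ignore_attr = TRUE)
    expect_gt(min(eigen(op$core, symmetric = TRUE)$values), -1e-10)
  }
})

test_that("network quadratic equals the degree-scaled difference form", {
  op <- laplacian_operator(trait_network(cbind(1, 2), 2), p = 1)
  expect_equal(network_quadratic(c(1, -1), op), 4)
  expect_equal(network_quadratic(c(0, 0), op), 0)
  # equal coefficients on an edge with equal degrees contribute zero
  op3 <- laplacian_operator(trait_network(rbind(c(1, 2)), 2), p = 3)
  b <- rep(rnorm(3), 2)
  expect_equal(network_quadratic(b, op3), 0, tolerance = 1e-12)
  # random agreement with the dense quadratic form
  set.seed(8)
  net <- trait_network(rbind(c(1, 2), c(2, 3)), 3)
  op_r <- laplacian_operator(net, p = 4)
  beta <- rnorm(12)
  expect_equal(network_quadratic(beta, op_r),
               as.numeric(t(beta) %*% laplacian_matrix(op_r) %*% beta),
               tolerance = 1e-12)
  expect_error(network_quadratic(rnorm(5), op_r), "length")
})

test_that("augmentation has Gn + Ep rows and reproduces the penalty", {
  set.seed(2)
  inst <- random_instance(G = 2, p = 3, n = 5)
  aug <- augment_dataset(inst$x, inst$yv, inst$op, lambda1 = 1.5, lambda2 = 4)
  expect_equal(nrow(aug$x_star), 2 * 5 + 1 * 3)   # Gn + Ep = 13
  expect_equal(aug$lambda_star, 1.5 / sqrt(5))
  expect_equal(aug$debias, 5)
  # identity: ||Y* - X* b*||^2 = ||Y - X b||^2 + lambda2 b' L b
  b <- rnorm(6)
  bs <- sqrt(5) * b
  lhs <- sum((aug$y_star - as.numeric(aug$x_star %*% bs))^2)
  rhs <- sum((inst$yv - as.numeric(inst$x %*% b))^2) +
    4 * network_quadratic(b, inst$op)
  expect_equal(lhs, rhs, tolerance = 1e-12)
  # lambda2 = 0 reduces to the original dataset
  aug0 <- augment_dataset(inst$x, inst$yv, inst$op, lambda1 = 2, lambda2 = 0)
  expect_equal(dim(aug0$x_star), dim(inst$x))
  expect_equal(aug0$lambda_star, 2)
  expect_equal(aug0$rescale, 1)
})

test_that("criterion value agrees with term-by-term evaluation", {
  set.seed(4)
  geno <- genotype_matrix(random_geno(15, 4))
  expr <- matrix(rnorm(30), 15, 2)
  pr <- ngvs_problem(encode_two_effect(geno), expr,
                     trait_network(cbind(1, 2), 2),
                     lambda1 = 0.7, lambda2 = 2)
  expect_equal(ngvs_criterion(numeric(16), pr), sum(pr$y^2))
  beta <- rnorm(16)
  pen <- sum(pr$weights * vapply(pr$groups,
                                 function(i) sqrt(sum(beta[i]^2)), 1))
  expect_equal(ngvs_criterion(beta, pr),
               sum((pr$y - as.numeric(pr$x %*% beta))^2) + 0.7 * pen +
                 2 * network_quadratic(beta, pr$op),
               tolerance = 1e-12)
  # unpenalized least squares attains the residual sum of squares
  xd <- as.matrix(pr$x)
  bls <- qr.solve(xd, pr$y)
  expect_equal(ngvs_criterion(bls, pr, lambda1 = 0, lambda2 = 0),
               sum((pr$y - xd %*% bls)^2), tolerance = 1e-10)
})

test_that("saturation is lifted by the augmented rows", {
  # Gp = 12 > Gn = 8, but Gn + Ep = 14 > 12: with the network active the
  # fit can carry more than Gn nonzero coefficients
  set.seed(10)
  inst <- random_instance(G = 2, p = 6, n = 4, n_groups = 6)
  aug <- augment_dataset(inst$x, inst$yv, inst$op, lambda1 = 1, lambda2 = 1)
  lm0 <- lambda_max(aug$x_star, aug$y_star, inst$groups, inst$weights)
  fit <- group_lasso(aug$x_star, aug$y_star, inst$groups,
                     lambda = 0.001 * lm0, weights = inst$weights,
                     tol = 1e-8)
  expect_gt(sum(fit$coefficients != 0), 8)
})
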