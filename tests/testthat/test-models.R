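# Model builders: interactions, covariate groups, the six variants.

test_that("adjacent interactions append one product column per adjacent
           pair inside a set", {
  set.seed(1)
  geno <- genotype_matrix(random_geno(20, 4))
  part <- marker_partition(c(1, 1, 1, 2))   # set of 3 + singleton
  d <- add_adjacent_interactions(encode_additive(geno, part))
  expect_equal(ncol(d$values), 4 + 2)       # pairs (1,2), (2,3); set 2 alone
  expect_equal(d$values[, 5], as.numeric(geno[, 1]) * as.numeric(geno[, 2]),
               ignore_attr = TRUE)
  # interaction columns join the set's existing group (weight grows)
  expect_equal(d$group[5], d$group[1])
  # singleton sets unchanged
  d1 <- add_adjacent_interactions(
    encode_additive(geno, marker_partition(1:4)))
  expect_equal(ncol(d1$values), 4)
  # product of codes (1,-1) and (-1,1) is (-1,-1)
  g2 <- genotype_matrix(rbind(c(1L, -1L), c(-1L, 1L)), chrom = NULL)
  d2 <- add_adjacent_interactions(encode_additive(g2, marker_partition(c(1, 1))))
  expect_equal(unname(d2$values[, 3]), c(-1, -1))
})

test_that("two-effect designs gain additive-coded products too", {
  set.seed(2)
  geno <- genotype_matrix(random_geno(15, 3))
  part <- marker_partition(c(1, 1, 1))
  d <- add_adjacent_interactions(encode_two_effect(geno, part))
  expect_equal(ncol(d$values), 6 + 2)
  expect_equal(d$values[, 7], as.numeric(geno[, 1]) * as.numeric(geno[, 2]),
               ignore_attr = TRUE)
})

test_that("covariate group construction", {
  set.seed(3)
  geno <- genotype_matrix(random_geno(40, 6))
  part <- marker_partition(rep(1:3, each = 2))
  sex <- rep(c(0, 1), each = 20)
  d0 <- encode_two_effect(geno, part)
  d1 <- add_covariate_group(d0, sex, with_interactions = FALSE)
  expect_equal(max(d1$group), max(d0$group) + 1L)
  d2 <- add_covariate_group(d0, sex, with_interactions = TRUE)
  expect_equal(max(d2$group), max(d0$group) + 1L + 3L)   # 1 + one per set
  expect_error(add_covariate_group(d0, rep(1, 40)), "constant")
  # centered two-level covariate points along (1,...,1,-1,...,-1)/2
  s <- standardize(d1)
  cv <- s$design$values[, ncol(s$design$values)]
  expect_equal(cv, rep(c(-1, 1), each = 20) / sqrt(40), ignore_attr = TRUE)
})

test_that("the six variants produce the documented column counts", {
  set.seed(4)
  n <- 20
  geno <- genotype_matrix(random_geno(n, 6))
  expr <- matrix(rnorm(n * 2), n, 2)
  part <- marker_partition(rep(1:3, each = 2))
  net <- trait_network(cbind(1, 2), 2)
  expect_equal(build_model(geno, expr, 1, part, net)$P, 6L)
  expect_equal(build_model(geno, expr, 2, part, net)$P, 12L)
  expect_equal(build_model(geno, expr, 3, part, net)$P, 6L + 3L)
  expect_equal(build_model(geno, expr, 4, part, net)$P, 12L + 3L)
  p5 <- build_model(geno, expr, 5, part, net,
                    covariate = rep(c(0, 1), 10))
  expect_equal(p5$P, 13L)
  p6 <- build_model(geno, expr, 6, part, net,
                    kernel = kernel_spec("gaussian", d = 1))
  expect_equal(p6$P, 3L * n)
  expect_error(build_model(geno, expr, 5, part, net), "covariate")
  expect_error(build_model(geno, expr, 6, part, net), "kernel")
  # every variant passes the standardization invariants
  for (pr in list(build_model(geno, expr, 3, part, net), p5, p6)) {
    v <- pr$design$values
    expect_lt(max(abs(colMeans(v))), 1e-12)
    expect_lt(max(abs(colSums(v^2) - 1)), 1e-12)
  }
})

test_that("with purely additive truth the two codings agree on the
           causal set", {
  set.seed(5)
  sim <- simulate_large_n(n = 150, snr = 5,
                          effects = list(additive = 1, dominant = 0),
                          seed = 99)
  o1 <- lasso_entry_order(sim$expression[, 1], sim$genotypes)
  o2 <- glasso_entry_order(sim$expression[, 1], sim$genotypes)
  expect_setequal(head(o1, 3), 1:3)
  expect_setequal(head(o2, 3), 1:3)
})
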