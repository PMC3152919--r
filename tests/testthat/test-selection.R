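# Three-stage selection: small-scale orders, single-QTL p-values, the
# three-criteria combination, consensus sets, epistasis scan.

test_that("small-scale order ranks the strong locus first", {
  set.seed(1)
  n <- 60
  geno <- random_geno(n, 2)
  y <- 10 * (geno[, 1] == 1) + 10 * (geno[, 1] == 0) * 0.5 +
    1 * (geno[, 2] == 1) + rnorm(n, sd = 0.3)
  o <- small_scale_order(y, geno, loci = c(11L, 12L))
  expect_equal(o$order[1], 11L)
  # singleton set is trivially rank 1
  expect_equal(small_scale_order(y, geno[, 1, drop = FALSE],
                                 loci = 5L)$order, 5L)
  # noiseless fit on locus A only: A first
  y2 <- 2 * geno[, 1]
  o2 <- small_scale_order(y2, geno, coding = "additive")
  expect_equal(o2$order[1], 1L)
})

test_that("single-QTL likelihood-ratio p-values match the lm likelihood
           oracle and are calibrated under the null", {
  set.seed(2)
  n <- 8
  geno <- random_geno(n, 3)
  y <- rnorm(n)
  p <- suppressWarnings(single_qtl_pvalues(y, geno))
  for (k in 1:3) {
    if (var(geno[, k]) == 0) next
    full <- lm(y ~ geno[, k]); null <- lm(y ~ 1)
    stat <- 2 * (as.numeric(logLik(full)) - as.numeric(logLik(null)))
    expect_equal(p[k], pchisq(stat, 1, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
  # perfect linear relation
  g1 <- cbind(rep(c(-1L, 0L, 1L), length.out = 10))
  expect_lt(single_qtl_pvalues(as.numeric(g1) * 2, g1), 1e-12)
  # zero-variance locus gets p = 1 with a warning
  expect_warning(pz <- single_qtl_pvalues(rnorm(10), cbind(rep(0L, 10))),
                 "zero-variance")
  expect_equal(unname(pz), 1)
  # null calibration: approximately Uniform(0,1)
  set.seed(3)
  gN <- random_geno(400, 60)
  pN <- single_qtl_pvalues(rnorm(400), gN)
  expect_gt(stats::ks.test(pN, "punif")$p.value, 0.01)
})

test_that("combine_orders satisfies the three criteria", {
  # single set: final = small order
  expect_equal(combine_orders(1, list(`1` = c(3, 1, 2)),
                              pvalues = c(0.5, 0.9, 0.1)),
               c(3, 1, 2))
  # two sets, big order (B=2, A=1): the top set's leader goes first
  p <- c(0.01, 0.5, 0.02, 0.9)
  f <- combine_orders(big = c(2, 1),
                      small = list(`1` = c(1, 2), `2` = c(3, 4)),
                      pvalues = p)
  expect_equal(f[1], 3)                     # leader of the top set
  expect_true(which(f == 1) < which(f == 2))  # within-set order kept
  expect_true(which(f == 3) < which(f == 4))
  # leaders appear in big-scale order
  expect_true(which(f == 3) < which(f == 1))

  # swapping within-set ranks swaps the loci's final ranks
  f2 <- combine_orders(c(2, 1), list(`1` = c(2, 1), `2` = c(3, 4)), p)
  expect_true(which(f2 == 2) < which(f2 == 1))
  # swapping big-scale ranks reorders the set leaders
  f3 <- combine_orders(c(1, 2), list(`1` = c(1, 2), `2` = c(3, 4)), p)
  expect_true(which(f3 == 1) < which(f3 == 3))

  # loci tied under the first two criteria resolve by ascending p-value:
  # after leader 1, the follower 2 (p = .05) beats set 2's leader (p = .5)
  p4 <- c(0.9, 0.05, 0.5, 0.2)
  f4 <- combine_orders(c(1, 2), list(`1` = c(1, 2), `2` = c(3, 4)), p4)
  expect_equal(f4, c(1, 2, 3, 4))
  p5 <- c(0.9, 0.5, 0.05, 0.2)
  f5 <- combine_orders(c(1, 2), list(`1` = c(1, 2), `2` = c(3, 4)), p5)
  expect_equal(f5, c(1, 3, 4, 2))

  expect_error(combine_orders(c(1, 2), list(`1` = 1:2), p), "different sets")
  expect_error(combine_orders(1, list(`1` = 1:5), p), "p-values")
  expect_equal(combine_orders(c(2, 1),
                              list(`1` = c(1, 2), `2` = c(3, 4)),
                              p, top_k = 2), c(3, 1))
})

test_that("a locus with a small p-value can interleave ahead of another
           set's later loci", {
  # set 1 holds two strong loci; the second one beats set 2's leader on p
  p <- c(1e-6, 1e-5, 1e-4, 0.9)
  f <- combine_orders(c(1, 2), list(`1` = c(1, 2), `2` = c(3, 4)), p)
  expect_equal(f[1:3], c(1, 2, 3))
})

test_that("single-trait decoupled big scale equals the single-trait
           entry path", {
  set.seed(4)
  geno <- genotype_matrix(random_geno(40, 8))
  y <- 2 * (geno[, 2] == 1) + 1.5 * (geno[, 2] == 0) + rnorm(40, sd = 0.5)
  part <- marker_partition(rep(1:4, each = 2))
  pr <- ngvs_problem(encode_two_effect(geno, part),
                     matrix(y, ncol = 1), network = NULL, lambda2 = 0)
  big <- big_scale_order(pr, lambda2 = 0, tol = 1e-9,
                         stop_when_all = FALSE)
  d <- encode_two_effect(geno, part)
  std <- standardize(d, matrix(y, ncol = 1))
  path <- entry_path(std$design$values, std$responses[, 1],
                     groups = std$design$group, tol = 1e-9,
                     stop_when_all = FALSE)
  expect_equal(big$orders[[1]], path$full_order)
})

test_that("consensus sets respect the support threshold", {
  big <- c(replicate(13, c(7, 1, 2), simplify = FALSE),
           replicate(3, c(5, 4, 3), simplify = FALSE))
  cs <- consensus_sets(big, m = 3, threshold = 0.5)
  expect_true(all(c(7, 1, 2) %in% cs))
  expect_false(any(c(3, 4, 5) %in% cs))
  expect_equal(attr(cs, "support")[match(7, cs)], 13L)
  # full agreement required: disagreement empties the list
  expect_length(consensus_sets(list(c(1, 2), c(3, 4)), m = 2,
                               threshold = 1), 0)
  # single trait: its own top-m
  expect_setequal(consensus_sets(list(c(9, 8, 7, 6)), m = 3), c(9, 8, 7))
})

test_that("epistasis scan recovers a planted adjacent interaction", {
  set.seed(5)
  n <- 80
  geno <- genotype_matrix(random_geno(n, 6))
  part <- marker_partition(rep(1:2, each = 3))
  G <- 6
  inter <- as.numeric(geno[, 4]) * as.numeric(geno[, 5])
  expr <- sapply(seq_len(G), function(g)
    1.5 * inter + 0.5 * (geno[, 1] == 1) + rnorm(n, sd = 0.4))
  sc <- epistasis_scan(expr, geno, part, sets_to_scan = c(1, 2), top_k = 3)
  hit <- sc[sc$locus_a == 4 & sc$locus_b == 5, ]
  expect_gte(hit$support, G - 1)
  # a pure-noise response yields weak support for any single pair
  set.seed(6)
  expr0 <- matrix(rnorm(n * G), n, G)
  sc0 <- epistasis_scan(expr0, geno, part, sets_to_scan = c(1, 2), top_k = 1)
  expect_lt(max(sc0$support), G)
})
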