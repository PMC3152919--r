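# Genotype encoding, standardization, marker sets, trait networks.

test_that("two-effect dummy coding maps AA/Aa/aa to the documented pairs", {
  g <- genotype_matrix(rbind(c(1L), c(0L), c(-1L), c(1L)))
  d <- encode_two_effect(g)
  expect_equal(unname(d$values[1, ]), c(1, 0))   # AA
  expect_equal(unname(d$values[2, ]), c(0, 1))   # Aa
  expect_equal(unname(d$values[3, ]), c(0, 0))   # aa baseline
  # reconstruction: 2*AA + Aa - 1 recovers the codes exactly
  set.seed(7)
  g2 <- genotype_matrix(random_geno(25, 6))
  d2 <- encode_two_effect(g2)
  aa <- d2$values[, seq(1, 12, 2)]; het <- d2$values[, seq(2, 12, 2)]
  expect_equal(2 * aa + het - 1, matrix(as.numeric(g2), 25, 6),
               ignore_attr = TRUE)
  # both columns of a marker share its group
  expect_equal(d2$group[1], d2$group[2])
})

test_that("additive coding keeps raw codes and rejects invalid genotypes", {
  g <- genotype_matrix(cbind(c(-1L, 0L, 1L)), marker_names = "m1")
  expect_equal(as.numeric(encode_additive(g)$values), c(-1, 0, 1))
  expect_error(genotype_matrix(cbind(c(0L, 2L, 1L))), "invalid genotype")
  expect_error(genotype_matrix(cbind(c(0L, NA, 1L))), "missing")
})

test_that("standardization centers, scales to unit norm, and flags
           degenerate columns by name", {
  set.seed(1)
  g <- genotype_matrix(random_geno(12, 4))
  s <- standardize(encode_additive(g), matrix(c(2, 4, 6, rep(0, 9)), 12, 1))
  expect_lt(max(abs(colMeans(s$design$values))), 1e-12)
  expect_lt(max(abs(colSums(s$design$values^2) - 1)), 1e-12)
  expect_equal(s$responses[1:3, 1], c(1, 3, 5), ignore_attr = TRUE,
               tolerance = 1e-12)
  # an all-heterozygote marker has a zero-variance additive code
  codes <- random_geno(10, 3); codes[, 2] <- 0L
  g2 <- genotype_matrix(codes, marker_names = c("a", "zv", "c"))
  expect_error(standardize(encode_additive(g2)), "zv")
})

test_that("response centering is exact", {
  g <- genotype_matrix(random_geno(3, 2))
  s <- standardize(encode_additive(g), matrix(c(2, 4, 6), 3, 1))
  expect_equal(as.numeric(s$responses), c(-2, 0, 2))
})

test_that("fixed-size marker sets cover all markers, remainder in the
           trailing set", {
  g <- genotype_matrix(random_geno(10, 200))
  p2 <- form_marker_sets(g, "fixed_size", r = 2)
  expect_equal(p2$n_sets, 100L)
  expect_true(all(p2$sizes == 2L))
  p1 <- form_marker_sets(g, "fixed_size", r = 1)
  expect_equal(p1$n_sets, 200L)
  g7 <- genotype_matrix(random_geno(10, 7))
  p3 <- form_marker_sets(g7, "fixed_size", r = 3)
  expect_equal(p3$sizes, c(3L, 3L, 1L))
  # disjoint and exhaustive
  expect_equal(sort(unique(p3$set_of)), 1:3)
  expect_equal(sum(p3$sizes), 7L)
})

test_that("chromosome and correlation-boundary grouping", {
  set.seed(42)
  codes <- random_geno(200, 4)
  codes[, 2] <- ifelse(runif(200) < 0.9, codes[, 1], codes[, 2])
  codes[, 4] <- ifelse(runif(200) < 0.9, codes[, 3], codes[, 4])
  cors <- sapply(1:3, function(k) abs(cor(codes[, k], codes[, k + 1])))
  expect_true(cors[1] > 0.5 && cors[2] < 0.5 && cors[3] > 0.5)
  g <- genotype_matrix(codes)
  pb <- form_marker_sets(g, "correlation_boundary", threshold = 0.5)
  expect_equal(pb$set_of, c(1L, 1L, 2L, 2L))

  gc <- genotype_matrix(codes, chrom = c("1", "1", "2", "2"))
  expect_equal(form_marker_sets(gc, "by_chromosome")$set_of,
               c(1L, 1L, 2L, 2L))
  expect_error(form_marker_sets(g, "by_chromosome"), "chromosome")
})

test_that("co-expression network construction and feasibility flag", {
  set.seed(3)
  z <- rnorm(60)
  expr <- cbind(z, z + rnorm(60, sd = 1e-6), rnorm(60))
  net <- build_network(expr[, 1:2], cutoff = 0.8)
  expect_equal(net$n_edges, 1L)
  expect_equal(net$degrees, c(1L, 1L))

  # G = 5 full network: E = 10 > 5 * (200 - 60) / 200 = 3.5
  expr5 <- matrix(rnorm(60 * 5), 60) + rnorm(60)  # shared component
  net5 <- build_network(expr5, cutoff = 1e-6, p = 200)
  expect_equal(net5$n_edges, 10L)
  expect_true(attr(net5, "feasible"))

  ind <- matrix(rnorm(60 * 3), 60)
  net0 <- build_network(ind, cutoff = 0.99, p = 200)
  expect_equal(net0$n_edges, 0L)
  expect_false(attr(net0, "feasible"))
  expect_equal(attr(net0, "zero_degree"), 1:3)
  expect_error(build_network(ind, cutoff = 0), "cutoff")
  expect_error(build_network(ind, cutoff = 1.2), "cutoff")
})

test_that("network construction is invariant to trait permutation", {
  set.seed(11)
  expr <- matrix(rnorm(40 * 4), 40) + 0.8 * rnorm(40)
  net <- build_network(expr, cutoff = 0.3)
  perm <- c(3L, 1L, 4L, 2L)
  net_p <- build_network(expr[, perm], cutoff = 0.3)
  # map permuted edges back and compare as sets
  back <- order(perm)
  e1 <- apply(net$edges, 1, function(e) paste(sort(e), collapse = "-"))
  e2 <- apply(net_p$edges, 1, function(e)
    paste(sort(perm[e]), collapse = "-"))
  expect_setequal(e1, e2)
})
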