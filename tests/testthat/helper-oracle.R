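# Independent proximal-gradient (FISTA) solver, used as a convex oracle
# against the BCGD implementation.  It minimises
#
#   ||y - X b||^2 + lam1 * sum_j w_j ||b_j||_2 + lam2 * b' L b
#
# directly (no data augmentation, no block co-ordinate structure), so it
# shares no code path with the package solver.
prox_oracle <- function(x, y, groups, weights = NULL, lam1, lam2 = 0,
                        L = NULL, max_iter = 100000L, tol = 1e-13) {
  x <- as.matrix(x)
  p <- ncol(x)
  gl <- if (is.list(groups)) groups else split(seq_len(p), groups)
  if (is.null(weights)) weights <- sqrt(vapply(gl, length, 1L))
  A <- 2 * crossprod(x)
  if (lam2 > 0) A <- A + 2 * lam2 * L
  c2 <- 2 * as.numeric(crossprod(x, y))
  step <- 1 / max(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
  prox <- function(z, t) {
    for (j in seq_along(gl)) {
      i <- gl[[j]]
      nz <- sqrt(sum(z[i]^2))
      thr <- t * lam1 * weights[j]
      z[i] <- if (nz > thr) (1 - thr / nz) * z[i] else 0
    }
    z
  }
  b <- numeric(p); v <- b; th <- 1
  for (it in seq_len(max_iter)) {
    grad <- as.numeric(A %*% v) - c2
    bn <- prox(v - step * grad, step)
    th_new <- (1 + sqrt(1 + 4 * th^2)) / 2
    v <- bn + ((th - 1) / th_new) * (bn - b)
    if (max(abs(bn - b)) < tol * max(1, max(abs(bn)))) return(bn)
    b <- bn; th <- th_new
  }
  b
}

oracle_objective <- function(b, x, y, groups, weights = NULL, lam1,
                             lam2 = 0, L = NULL) {
  gl <- if (is.list(groups)) groups else split(seq_along(b), groups)
  if (is.null(weights)) weights <- sqrt(vapply(gl, length, 1L))
  pen <- sum(weights * vapply(gl, function(i) sqrt(sum(b[i]^2)), numeric(1)))
  quad <- if (lam2 > 0) as.numeric(t(b) %*% L %*% b) else 0
  sum((y - as.matrix(x) %*% b)^2) + lam1 * pen + lam2 * quad
}

# Random tiny multi-trait instance for the equivalence checks.
random_instance <- function(G = 2L, p = 3L, n = 6L, edges = NULL,
                            n_groups = 2L) {
  xm <- matrix(rnorm(n * p), n, p)
  y <- matrix(rnorm(n * G), n, G)
  grp1 <- sort(rep_len(seq_len(n_groups), p))
  if (is.null(edges)) {
    edges <- if (G == 2L) cbind(1L, 2L) else rbind(c(1L, 2L), c(2L, 3L))
  }
  net <- trait_network(edges, G)
  op <- laplacian_operator(net, p)
  x <- Matrix::bdiag(rep(list(Matrix::Matrix(xm, sparse = TRUE)), G))
  groups <- lapply(seq_len(G * n_groups), function(k) {
    g <- (k - 1L) %/% n_groups + 1L
    j <- (k - 1L) %% n_groups + 1L
    which(grp1 == j) + (g - 1L) * p
  })
  weights <- rep(sqrt(table(grp1)), G)
  joint_groups_flat <- integer(G * p)
  for (k in seq_along(groups)) joint_groups_flat[groups[[k]]] <- k
  list(xm = xm, y = y, x = x, yv = as.numeric(y), groups = groups,
       groups_flat = joint_groups_flat, weights = as.numeric(weights),
       op = op, net = net, G = G, p = p, n = n)
}

# Standardized single-trait design matrix (centered, unit-norm columns).
std_cols <- function(x) {
  x <- sweep(x, 2L, colMeans(x), "-")
  sweep(x, 2L, sqrt(colSums(x^2)), "/")
}

# Small random genotype code matrix.
random_geno <- function(n, p) {
  matrix(sample(c(-1L, 0L, 1L), n * p, replace = TRUE,
                prob = c(0.25, 0.5, 0.25)), n, p)
}
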