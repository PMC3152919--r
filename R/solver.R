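# Group-lasso solver (block co-ordinate gradient descent) and
# regularization-path / entry-order computation.

as_group_list <- function(groups, ncols) {
  if (is.list(groups)) {
    gl <- lapply(groups, as.integer)
  } else {
    gl <- split(seq_len(ncols), groups)
  }
  if (any(vapply(gl, length, 1L) == 0L)) stop("groups must be nonempty")
  idx <- unlist(gl)
  if (anyDuplicated(idx) || length(idx) != ncols ||
      !setequal(idx, seq_len(ncols)))
    stop("groups must partition the design columns")
  gl
}

as_sparse <- function(x) {
  as(as(as(x, "CsparseMatrix"), "generalMatrix"), "dMatrix")
}

#' Penalty level that zeroes every group
#'
#' `lambda_max = max_j ||X_j' y|| / w_j`: at or above this level the
#' all-zero vector satisfies the group-lasso optimality conditions.
#'
#' @param x design matrix.
#' @param y response vector.
#' @param groups column groups (integer vector per column, or list of
#'   column index vectors).
#' @param weights per-group penalty weights; default
#'   `sqrt(group size)`.
#' @return A scalar.
#' @export
lambda_max <- function(x, y, groups, weights = NULL) {
  x <- as_sparse(x)
  gl <- as_group_list(groups, ncol(x))
  if (is.null(weights)) weights <- sqrt(vapply(gl, length, 1L))
  g0 <- lapply(gl, function(i) i - 1L)
  max(.group_grad_norms(x, as.numeric(y), g0, weights))
}

#' Group lasso by block co-ordinate gradient descent
#'
#' Minimises `0.5 * ||y - X b||^2 + lambda * sum_j w_j ||b_j||` starting
#' from the zero vector (or `beta0`).  Each block step minimises a
#' quadratic surrogate with Hessian `h_j I` (`h_j` the largest
#' eigenvalue of `X_j' X_j`), whose solution is a group soft-threshold,
#' followed by an Armijo line search (halving, sufficient-decrease
#' constant 0.1).  Either a new group enters or the coefficients of
#' already-selected groups move slightly; the objective never increases.
#' Convergence is declared when the Karush-Kuhn-Tucker residual falls
#' below `tol` (relative to the penalty level): inactive groups must
#' satisfy `||X_j' r|| <= lambda w_j (1 + tol)` and active groups the
#' stationarity condition within `tol`.
#'
#' @param x design matrix (dense or sparse), columns standardized.
#' @param y response vector.
#' @param groups integer vector (one group id per column) or list of
#'   column index vectors.
#' @param lambda penalty level, >= 0.
#' @param weights per-group weights; default `sqrt(group size)`.
#' @param tol KKT tolerance (default `1e-8`).
#' @param max_iter maximum number of block sweeps (default `10000`).
#' @param beta0 optional warm start.
#' @param lipschitz,grams optional precomputed per-group `h_j` and Gram
#'   matrices (path drivers compute them once and reuse them).
#' @return An object of class `group_lasso_fit`: `coefficients`,
#'   `active` (group ids with nonzero blocks), `objective`,
#'   `iterations`, `converged`, plus the call ingredients.
#' @examples
#' set.seed(1)
#' x <- scale(matrix(rnorm(40), 10, 4)); x <- sweep(x, 2, sqrt(colSums(x^2)), "/")
#' y <- x[, 1] - x[, 2] + rnorm(10, sd = .1)
#' fit <- group_lasso(x, y - mean(y), groups = c(1, 1, 2, 2), lambda = 0.2)
#' fit$active
#' @export
group_lasso <- function(x, y, groups, lambda, weights = NULL,
                        tol = 1e-8, max_iter = 10000L,
                        beta0 = NULL, lipschitz = NULL, grams = NULL) {
  stopifnot(lambda >= 0)
  x <- as_sparse(x)
  y <- as.numeric(y)
  gl <- as_group_list(groups, ncol(x))
  J <- length(gl)
  if (is.null(weights)) weights <- sqrt(vapply(gl, length, 1L))
  stopifnot(length(weights) == J)
  g0 <- lapply(gl, function(i) i - 1L)
  if (is.null(grams)) grams <- .group_grams(x, g0)
  if (is.null(lipschitz))
    lipschitz <- vapply(grams, function(G)
      max(max(eigen(G, symmetric = TRUE, only.values = TRUE)$values), 1e-12),
      numeric(1))
  if (is.null(beta0)) beta0 <- numeric(ncol(x))
  res <- .bcgd_fit(x, y, g0, weights, lipschitz, grams, lambda, beta0,
                   tol, as.integer(max_iter))
  if (!res$converged)
    warning("BCGD did not reach the KKT tolerance within ", max_iter,
            " sweeps (violation ", signif(res$kkt_violation, 3), ")")
  beta <- as.numeric(res$beta)
  active <- unname(which(vapply(gl, function(i) any(beta[i] != 0),
                               logical(1))))
  structure(list(coefficients = beta,
                 active = active,
                 objective = res$objective,
                 iterations = res$iterations,
                 converged = res$converged,
                 kkt_violation = res$kkt_violation,
                 lambda = lambda, weights = weights, groups = gl),
            class = "group_lasso_fit")
}

#' @export
print.group_lasso_fit <- function(x, ...) {
  cat("Group-lasso fit: lambda =", signif(x$lambda, 4), "-",
      length(x$active), "of", length(x$groups), "groups active;",
      "objective", signif(x$objective, 6),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

#' Regularization path and group entry order
#'
#' Fits the group lasso along a decreasing `lambda` grid with warm
#' starts and records when each group first becomes active.  Whenever
#' two or more groups enter between consecutive grid points the
#' interval is bisected recursively (geometric midpoints, up to
#' `max_bisect` levels) so that entries are separated; groups still
#' tied after refinement are ordered by the gradient norm
#' `||X_j' r|| / w_j` measured at the last point where both were
#' inactive.
#'
#' @inheritParams group_lasso
#' @param lambda_grid decreasing grid; default `n_lambda` log-spaced
#'   points from `lambda_max` down to `lambda_min_ratio * lambda_max`.
#' @param n_lambda,lambda_min_ratio grid controls.
#' @param max_bisect bisection depth per multi-entry interval.
#' @param stop_when_all stop descending the grid once every group has
#'   entered (the remaining fits cannot change the entry order).
#' @param refine_classes optional integer vector (one class per group):
#'   bisection is only spent on simultaneous entries within the same
#'   class.  The multi-trait path uses the trait as the class, since
#'   only the relative order of one trait's marker sets is consumed
#'   downstream; cross-class ties are ranked by gradient norm.
#' @param stop_per_class stop descending the grid once every class has
#'   at least this many entered groups (default `Inf`); groups still
#'   outside get ranked by end-of-path gradient norm.  Caps the
#'   expensive weakly-penalized fits when only the top of each order is
#'   consumed.
#' @return An object of class `entry_path`: `first_entry` (per-group
#'   entry `lambda`, `NA` if the group never enters), `order` (groups
#'   sorted by entry, earliest first), `full_order` (`order` followed by
#'   the never-entering groups ranked by end-of-path gradient norm),
#'   `lambda` (the grid), `active_sets` (per grid point) and `grad_end`.
#' @export
entry_path <- function(x, y, groups, weights = NULL, lambda_grid = NULL,
                       n_lambda = 100L, lambda_min_ratio = 0.001,
                       max_bisect = 12L, tol = 1e-8, max_iter = 10000L,
                       stop_when_all = TRUE, refine_classes = NULL,
                       stop_per_class = Inf) {
  x <- as_sparse(x)
  y <- as.numeric(y)
  gl <- as_group_list(groups, ncol(x))
  J <- length(gl)
  if (is.null(weights)) weights <- sqrt(vapply(gl, length, 1L))
  g0 <- lapply(gl, function(i) i - 1L)
  grams <- .group_grams(x, g0)
  h <- vapply(grams, function(G)
    max(max(eigen(G, symmetric = TRUE, only.values = TRUE)$values), 1e-12),
    numeric(1))

  lmax <- max(.group_grad_norms(x, y, g0, weights))
  if (is.null(lambda_grid)) {
    if (lmax <= 0) lambda_grid <- 1  # degenerate: y orthogonal to all groups
    else lambda_grid <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                                length.out = n_lambda))
  }
  if (any(diff(lambda_grid) >= 0)) stop("lambda grid must be strictly decreasing")

  entry <- rep(NA_real_, J)
  tie_break <- rep(NA_real_, J)   # gradient norm just before entry, for ties
  active_of <- function(beta)
    unname(which(vapply(gl, function(i) any(beta[i] != 0), logical(1))))
  fit_at <- function(lam, b0) {
    as.numeric(.bcgd_fit(x, y, g0, weights, h, grams, lam, b0, tol,
                         as.integer(max_iter))$beta)
  }
  grad_norms <- function(beta) {
    r <- y - as.numeric(x %*% beta)
    .group_grad_norms(x, r, g0, weights)
  }
  record <- function(new, lam, beta_above) {
    gn <- grad_norms(beta_above)
    entry[new] <<- lam
    tie_break[new] <<- gn[new]
  }
  # Assign entry lambdas to `new` groups known to enter inside (l_lo, l_hi).
  refine <- function(l_hi, b_hi, l_lo, b_lo, new, depth) {
    if (length(new) <= 1L || depth <= 0L) {
      record(new, l_lo, b_hi)
      return(invisible())
    }
    l_mid <- sqrt(l_hi * l_lo)
    b_mid <- fit_at(l_mid, b_hi)
    a_mid <- active_of(b_mid)
    in_mid <- intersect(new, a_mid)
    rest <- setdiff(new, in_mid)
    if (length(in_mid) > 0L) refine(l_hi, b_hi, l_mid, b_mid, in_mid, depth - 1L)
    if (length(rest) > 0L) refine(l_mid, b_mid, l_lo, b_lo, rest, depth - 1L)
    invisible()
  }

  beta <- numeric(ncol(x))
  seen <- integer(0)
  active_sets <- vector("list", length(lambda_grid))
  b_prev <- beta
  l_prev <- Inf
  for (k in seq_along(lambda_grid)) {
    lam <- lambda_grid[k]
    beta <- fit_at(lam, beta)
    act <- active_of(beta)
    active_sets[[k]] <- act
    new <- setdiff(act, seen)
    if (length(new) == 1L) {
      record(new, lam, b_prev)
    } else if (length(new) > 1L) {
      if (!is.finite(l_prev)) {
        record(new, lam, b_prev)
      } else if (is.null(refine_classes)) {
        refine(l_prev, b_prev, lam, beta, new, max_bisect)
      } else {
        # separate only same-class collisions; singleton classes are
        # recorded directly (their cross-class rank is never consumed)
        for (cls in unique(refine_classes[new])) {
          sub <- new[refine_classes[new] == cls]
          if (length(sub) > 1L) refine(l_prev, b_prev, lam, beta, sub,
                                       max_bisect)
          else record(sub, lam, b_prev)
        }
      }
    }
    seen <- union(seen, new)
    b_prev <- beta
    l_prev <- lam
    done <- (stop_when_all && length(seen) == J)
    if (!done && is.finite(stop_per_class) && !is.null(refine_classes)) {
      per_class <- table(factor(refine_classes[seen],
                                levels = unique(refine_classes)))
      done <- all(per_class >= stop_per_class)
    }
    if (done) {
      active_sets <- active_sets[seq_len(k)]
      lambda_grid <- lambda_grid[seq_len(k)]
      break
    }
  }
  grad_end <- grad_norms(beta)

  entered <- which(!is.na(entry))
  ord <- entered[order(-entry[entered], -tie_break[entered])]
  never <- setdiff(seq_len(J), entered)
  full_order <- c(ord, never[order(-grad_end[never])])
  structure(list(first_entry = entry, order = ord, full_order = full_order,
                 lambda = lambda_grid, active_sets = active_sets,
                 grad_end = grad_end, tie_break = tie_break,
                 lambda_max = lmax),
            class = "entry_path")
}

#' @export
print.entry_path <- function(x, ...) {
  cat("Entry path over", length(x$lambda), "lambda values:",
      length(x$order), "of", length(x$first_entry), "groups entered\n")
  if (length(x$order) > 0L)
    cat("entry order:", paste(head(x$order, 10L), collapse = ", "),
        if (length(x$order) > 10L) "..." else "", "\n")
  invisible(x)
}
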