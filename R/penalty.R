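#' Network Laplacian penalty operator
#'
#' Builds the normalized graph Laplacian of the trait network in the
#' block form used by the multi-trait penalty: the `Gp x Gp` matrix `L`
#' has block `(u, u) = I_p` and block `(u, v) = -(d_u d_v)^{-1/2} I_p`
#' for linked traits.  Because every block is a scalar multiple of the
#' identity, only the `G x G` scalar core is stored together with `p`
#' (the number of regressors per trait); `L` is never densified for
#' large problems.  The incidence factor `S` with `S S^T = L` is stored
#' the same way: its block column for edge `u ~ v` carries
#' `d_u^{-1/2} I_p` at row `u` and `-d_v^{-1/2} I_p` at row `v`.
#'
#' @param net a [trait_network()]; every trait must have degree > 0.
#' @param p number of regressor columns per trait.
#' @return An object of class `ngvs_laplacian` with fields `core`
#'   (`G x G`), `s_core` (`G x E`), `p`, `edges`, `degrees`.
#' @examples
#' net <- trait_network(cbind(1, 2), n_traits = 2)
#' op <- laplacian_operator(net, p = 1)
#' op$core                      # rbind(c(1,-1), c(-1,1))
#' eigen(op$core)$values        # 2, 0
#' @export
laplacian_operator <- function(net, p) {
  if (any(net$degrees == 0L))
    stop("trait(s) ", paste(which(net$degrees == 0L), collapse = ", "),
         " have degree 0; lower the correlation cutoff or supply a ",
         "larger network so every trait is linked")
  G <- net$n_traits
  E <- net$n_edges
  core <- diag(G)
  s_core <- matrix(0, G, max(E, 0L))
  d <- net$degrees
  if (E > 0L) {
    for (e in seq_len(E)) {
      u <- net$edges[e, 1L]; v <- net$edges[e, 2L]
      core[u, v] <- core[v, u] <- -1 / sqrt(d[u] * d[v])
      s_core[u, e] <- 1 / sqrt(d[u])
      s_core[v, e] <- -1 / sqrt(d[v])
    }
  }
  structure(list(core = core, s_core = s_core, p = as.integer(p),
                 edges = net$edges, degrees = d,
                 n_traits = G, n_edges = E),
            class = "ngvs_laplacian")
}

#' @export
print.ngvs_laplacian <- function(x, ...) {
  cat("Laplacian penalty operator: ", x$n_traits, " traits, ", x$n_edges,
      " edges, ", x$p, " columns/trait (", x$n_traits * x$p, " x ",
      x$n_traits * x$p, " blockwise)\n", sep = "")
  invisible(x)
}

#' Dense Laplacian and incidence matrices
#'
#' Expand the block-scalar operator to its full `Gp x Gp` (or `Gp x Ep`)
#' form.  Intended for small problems and verification; the solver never
#' materialises these for large `p`.
#'
#' @param op an [laplacian_operator()].
#' @return A dense matrix.
#' @export
laplacian_matrix <- function(op) {
  kronecker(op$core, diag(op$p))
}

#' @rdname laplacian_matrix
#' @export
incidence_matrix <- function(op) {
  if (op$n_edges == 0L) return(matrix(0, op$n_traits * op$p, 0L))
  kronecker(op$s_core, diag(op$p))
}

#' Network smoothness quadratic form
#'
#' Evaluates `beta' L beta`, equal to the sum over linked trait pairs of
#' `|| beta_u / sqrt(d_u) - beta_v / sqrt(d_v) ||^2`: it vanishes when
#' linked traits carry identical degree-scaled coefficient blocks, which
#' encodes the assumption that co-expressed traits regulated by the same
#' QTLs have similar effects.
#'
#' @param beta coefficient vector of length `G * p`, trait blocks
#'   stacked.
#' @param op an [laplacian_operator()].
#' @return A non-negative scalar.
#' @export
network_quadratic <- function(beta, op) {
  G <- op$n_traits; p <- op$p
  if (length(beta) != G * p)
    stop("beta must have length G * p = ", G * p)
  B <- matrix(beta, nrow = p, ncol = G)
  sum(op$core * crossprod(B))
}

# Sparse (Ep x Gp) matrix sqrt(lambda2) * S^T used for the augmentation rows.
penalty_rows <- function(op, lambda2) {
  G <- op$n_traits; p <- op$p; E <- op$n_edges
  if (E == 0L || lambda2 == 0)
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(if (lambda2 == 0) 0L else E * p, G * p)))
  d <- op$degrees
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  for (e in seq_len(E)) {
    u <- op$edges[e, 1L]; v <- op$edges[e, 2L]
    rr <- (e - 1L) * p + seq_len(p)
    rows <- c(rows, rr, rr)
    cols <- c(cols, (u - 1L) * p + seq_len(p), (v - 1L) * p + seq_len(p))
    vals <- c(vals, rep(1 / sqrt(d[u]), p), rep(-1 / sqrt(d[v]), p))
  }
  Matrix::sparseMatrix(i = rows, j = cols, x = sqrt(lambda2) * vals,
                       dims = c(E * p, G * p))
}

#' Augment the dataset to absorb the network penalty
#'
#' Rewrites the network-penalized criterion as a pure group-lasso
#' problem on an artificial dataset: `Ep` pseudo-observation rows built
#' from the incidence factor `S` are appended below the data rows,
#'
#'   `X* = (1 + lambda2)^{-1/2} rbind(X, sqrt(lambda2) S^T)`,
#'   `Y* = c(Y, 0_{Ep})`,
#'
#' and the group penalty level becomes
#' `lambda* = lambda1 / sqrt(1 + lambda2)`.  The augmented solution maps
#' back via `beta = rescale * beta*` with `rescale = (1+lambda2)^{-1/2}`;
#' a final debias factor `1 + lambda2` (see [ngvs()]) counteracts the
#' double shrinkage, following the elastic-net convention.  Because the
#' row count grows from `Gn` to `Gn + Ep`, selection is no longer capped
#' at `Gn` variables.
#'
#' @param x design matrix (`Gn x Gp`, standardized, dense or sparse).
#' @param y stacked centered response vector (length `Gn`).
#' @param op an [laplacian_operator()] with matching `p`.
#' @param lambda1 group-lasso penalty level (>= 0).
#' @param lambda2 network penalty level (>= 0).
#' @return A list: `x_star` (sparse), `y_star`, `lambda_star`,
#'   `rescale`, `debias`.
#' @export
augment_dataset <- function(x, y, op, lambda1, lambda2) {
  stopifnot(lambda1 >= 0, lambda2 >= 0)
  x <- as(as(x, "CsparseMatrix"), "generalMatrix")
  if (lambda2 == 0) {
    return(list(x_star = x, y_star = as.numeric(y), lambda_star = lambda1,
                rescale = 1, debias = 1))
  }
  if (is.null(op))
    stop("lambda2 > 0 requires a penalty operator (network with all degrees > 0)")
  if (ncol(x) != op$n_traits * op$p)
    stop("design has ", ncol(x), " columns; operator expects ",
         op$n_traits * op$p)
  sc <- 1 / sqrt(1 + lambda2)
  x_star <- rbind(x, penalty_rows(op, lambda2)) * sc
  y_star <- c(as.numeric(y), rep(0, op$n_edges * op$p))
  list(x_star = x_star, y_star = y_star,
       lambda_star = lambda1 * sc, rescale = sc, debias = 1 + lambda2)
}
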