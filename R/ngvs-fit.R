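#' Fit the network-based group variable selection model
#'
#' Minimises the penalized criterion
#' `||Y - X beta||^2 + lambda1 sum_{g,j} w_j ||beta_{j,g}|| +
#'  lambda2 beta' L beta`
#' over all traits jointly: the group penalty selects whole marker sets
#' per trait, the Laplacian term shrinks degree-scaled coefficient
#' blocks of network-linked traits toward each other.  The problem is
#' reformulated as a group lasso on the augmented dataset (see
#' [augment_dataset()]) and solved by block co-ordinate gradient
#' descent; reported coefficients are rescaled by `1 + lambda2` to
#' counteract the double shrinkage (the raw minimiser is kept as
#' `coefficients_raw` and used for fitted values).
#'
#' @param genotypes a [genotype_matrix()] (or coercible matrix of
#'   `{-1,0,1}` codes).
#' @param expression numeric matrix, samples x traits.
#' @param lambda1 group penalty level (>= 0).
#' @param lambda2 network penalty level (>= 0; 10 is a robust default
#'   for selection-order work).
#' @param sets a [marker_partition()] (default singleton sets).
#' @param network a [trait_network()] (default fully connected).
#' @param coding `"two_effect"` (additive + dominant dummies, the
#'   recommended model) or `"additive"`.
#' @param problem alternatively, a prebuilt [ngvs_problem()] (for
#'   kernel, interaction or covariate models); overrides the data
#'   arguments.
#' @param tol,max_iter solver controls, see [group_lasso()].
#' @return An object of class `ngvs` with `coefficients` (debiased,
#'   `P x G`), `coefficients_raw`, `active` (list of active marker-set
#'   ids per trait), the solver fit, and the problem.
#' @examples
#' sim <- simulate_large_n(n = 60, snr = 5, seed = 1)
#' fit <- ngvs(sim$genotypes, sim$expression, lambda1 = 2,
#'             sets = sim$partition, network = sim$network)
#' fit
#' @export
ngvs <- function(genotypes, expression, lambda1, lambda2 = 10,
                 sets = NULL, network = NULL,
                 coding = c("two_effect", "additive"),
                 problem = NULL, tol = 1e-8, max_iter = 10000L) {
  cl <- match.call()
  if (is.null(problem)) {
    coding <- match.arg(coding)
    geno <- as_genotype_matrix(genotypes)
    sets <- default_partition(sets, ncol(geno))
    design <- if (coding == "two_effect") encode_two_effect(geno, sets)
              else encode_additive(geno, sets)
    problem <- ngvs_problem(design, expression, network,
                            lambda1 = lambda1, lambda2 = lambda2)
  } else {
    problem$lambda1 <- lambda1
    problem$lambda2 <- lambda2
  }
  aug <- augment_dataset(problem$x, problem$y, problem$op,
                         lambda1, lambda2)
  # solver convention is 0.5*RSS + lambda*penalty; the criterion uses RSS
  fit <- group_lasso(aug$x_star, aug$y_star, problem$groups,
                     lambda = aug$lambda_star / 2,
                     weights = problem$weights,
                     tol = tol, max_iter = max_iter)
  beta <- fit$coefficients * aug$rescale          # minimiser of the criterion
  beta_debiased <- beta * aug$debias
  P <- problem$P; G <- problem$G
  cf <- matrix(beta_debiased, P, G)
  rownames(cf) <- colnames(problem$design$values)
  active <- lapply(seq_len(G), function(g) {
    loc <- problem$group_local[intersect(fit$active,
                                         which(problem$group_trait == g))]
    sets_g <- problem$local_set[loc]
    sort(unique(sets_g[!is.na(sets_g)]))
  })
  structure(list(coefficients = cf,
                 coefficients_raw = matrix(beta, P, G,
                                           dimnames = dimnames(cf)),
                 active = active,
                 lambda1 = lambda1, lambda2 = lambda2,
                 problem = problem, solver = fit,
                 criterion = ngvs_criterion(beta, problem, lambda1, lambda2),
                 call = cl),
            class = "ngvs")
}

#' @export
print.ngvs <- function(x, ...) {
  cat("Network-based group variable selection fit\n")
  cat("  lambda1 =", signif(x$lambda1, 4), " lambda2 =",
      signif(x$lambda2, 4), "\n")
  cat("  ", x$problem$n, " samples, ", x$problem$G, " traits, ",
      x$problem$J, " groups/trait\n", sep = "")
  for (g in seq_len(x$problem$G))
    cat("  trait ", g, ": active marker sets ",
        if (length(x$active[[g]]) > 0) paste(x$active[[g]], collapse = ", ")
        else "(none)", "\n", sep = "")
  invisible(x)
}

#' @export
summary.ngvs <- function(object, ...) {
  P <- object$problem$P; G <- object$problem$G
  norms <- sapply(seq_len(G), function(g) {
    vapply(seq_len(object$problem$J), function(j) {
      cols <- which(object$problem$design$group == j)
      sqrt(sum(object$coefficients[cols, g]^2))
    }, numeric(1))
  })
  rownames(norms) <- paste0("group", seq_len(object$problem$J))
  colnames(norms) <- paste0("trait", seq_len(G))
  out <- list(fit = object, group_norms = norms,
              criterion = object$criterion,
              network_quadratic = network_quadratic(
                as.numeric(object$coefficients_raw), object$problem$op))
  class(out) <- "summary.ngvs"
  out
}

#' @export
print.summary.ngvs <- function(x, ...) {
  print(x$fit)
  cat("criterion value:", signif(x$criterion, 6),
      " network quadratic:", signif(x$network_quadratic, 6), "\n")
  cat("coefficient block norms (debiased):\n")
  print(round(x$group_norms, 4))
  invisible(x)
}

#' @export
coef.ngvs <- function(object, debias = TRUE, ...) {
  if (debias) object$coefficients else object$coefficients_raw
}

#' @export
fitted.ngvs <- function(object, ...) {
  pr <- object$problem
  yhat <- as.numeric(pr$x %*% as.numeric(object$coefficients_raw))
  m <- matrix(yhat, pr$n, pr$G)
  sweep(m, 2L, pr$response_center, "+")
}

#' @export
residuals.ngvs <- function(object, ...) {
  pr <- object$problem
  matrix(pr$y, pr$n, pr$G) +
    matrix(rep(pr$response_center, each = pr$n), pr$n, pr$G) -
    fitted(object)
}

#' Predict expression for new genotypes
#'
#' Only available for the linear codings (`additive`, `two_effect`);
#' kernel designs do not extend to new samples without the training
#' data.
#'
#' @param object an [ngvs()] fit.
#' @param newdata a [genotype_matrix()] with the same markers.
#' @param ... unused.
#' @return A matrix of predicted expression, samples x traits.
#' @export
predict.ngvs <- function(object, newdata, ...) {
  pr <- object$problem
  des <- pr$design
  if (!des$coding %in% c("additive", "two_effect"))
    stop("predict is only supported for the additive and two-effect codings")
  geno <- as_genotype_matrix(newdata)
  raw <- if (des$coding == "two_effect") encode_two_effect(geno)
         else encode_additive(geno)
  v <- raw$values
  if (ncol(v) != pr$P) stop("newdata has a different marker count")
  v <- sweep(v, 2L, des$center, "-")
  v <- sweep(v, 2L, des$scale, "/")
  yhat <- v %*% object$coefficients_raw
  sweep(yhat, 2L, pr$response_center, "+")
}

#' @export
plot.ngvs <- function(x, ...) {
  s <- summary(x)
  graphics::barplot(t(s$group_norms), beside = TRUE,
                    legend.text = colnames(s$group_norms),
                    xlab = "penalty group", ylab = "coefficient block norm",
                    main = "NGVS coefficient block norms", ...)
  invisible(x)
}
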