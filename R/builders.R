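# Model builders: interaction terms, covariate groups, the six model
# variants, and assembly of the joint multi-trait problem.

#' Append adjacent-marker interaction columns
#'
#' For every pair of adjacent markers within a marker set (genomic
#' order), one product column of their additive codes is appended to
#' that set's penalty group, enlarging the group (and its weight
#' `sqrt(group size)`).  Products use additive coding in both the
#' additive and the two-effect model: each two-locus interaction is a
#' single new variable.  Singleton sets are returned unchanged.
#'
#' @param design an unstandardized `ngvs_design` from
#'   [encode_additive()] or [encode_two_effect()].
#' @return The enlarged design.
#' @export
add_adjacent_interactions <- function(design) {
  if (design$standardized)
    stop("add interactions before standardization")
  codes <- additive_codes(design)
  sets <- sort(unique(design$set[!is.na(design$set)]))
  extra <- list(); emeta <- list()
  for (s in sets) {
    mk <- sort(unique(design$marker[which(design$set == s)]))
    if (length(mk) < 2L) next
    grp <- design$group[match(TRUE, design$set == s)]
    for (i in seq_len(length(mk) - 1L)) {
      a <- mk[i]; b <- mk[i + 1L]
      col <- codes[, a] * codes[, b]
      extra[[length(extra) + 1L]] <- col
      emeta[[length(emeta) + 1L]] <-
        list(name = paste0("I", a, "x", b), set = s, group = grp)
    }
  }
  if (length(extra) == 0L) return(design)
  add <- do.call(cbind, extra)
  colnames(add) <- vapply(emeta, function(m) m$name, character(1))
  out <- design
  out$values <- cbind(design$values, add)
  out$marker <- c(design$marker, rep(NA_integer_, length(extra)))
  out$set <- c(design$set, vapply(emeta, function(m) m$set, numeric(1)))
  out$group <- c(design$group,
                 vapply(emeta, function(m) m$group, numeric(1)))
  out
}

#' Append a covariate group
#'
#' Adds the covariate (e.g. sex) as one additional penalty group; with
#' `with_interactions = TRUE`, one further group per marker set holds
#' the covariate-by-marker product columns (additive codes), so
#' statements like "interaction of sex with marker k" can be read off
#' the selection order.
#'
#' @param design an unstandardized `ngvs_design`.
#' @param covariate numeric vector, one value per sample.
#' @param with_interactions append per-set interaction groups?
#' @param name label for the covariate column.
#' @return The enlarged design; the covariate group id is
#'   `max(design$group) + 1`.
#' @export
add_covariate_group <- function(design, covariate, with_interactions = FALSE,
                                name = "covariate") {
  if (design$standardized) stop("add covariates before standardization")
  covariate <- as.numeric(covariate)
  if (length(covariate) != nrow(design$values))
    stop("covariate length must equal the sample count")
  if (sd(covariate) == 0)
    stop("degenerate covariate: '", name, "' is constant")
  g0 <- max(design$group)
  vals <- cbind(design$values, covariate)
  colnames(vals)[ncol(vals)] <- name
  marker <- c(design$marker, NA_integer_)
  set <- c(design$set, NA_real_)
  group <- c(design$group, g0 + 1L)
  if (with_interactions) {
    codes <- additive_codes(design)
    sets <- sort(unique(design$set[!is.na(design$set)]))
    for (i in seq_along(sets)) {
      s <- sets[i]
      mk <- sort(unique(design$marker[which(design$set == s)]))
      block <- codes[, mk, drop = FALSE] * covariate
      colnames(block) <- paste0(name, "xM", mk)
      vals <- cbind(vals, block)
      marker <- c(marker, rep(NA_integer_, length(mk)))
      set <- c(set, rep(s, length(mk)))
      group <- c(group, rep(g0 + 1L + i, length(mk)))
    }
  }
  out <- design
  out$values <- vals; out$marker <- marker; out$set <- set
  out$group <- as.integer(group)
  out
}

#' Build one of the six model variants
#'
#' Wires genotype encoding, marker sets, optional interaction /
#' covariate / kernel terms, standardization and the trait network into
#' a ready multi-trait problem:
#' (1) additive linear model; (2) two-effect linear model;
#' (3) additive with adjacent-marker interactions; (4) two-effect with
#' adjacent-marker interactions; (5) two-effect with a covariate group
#' (e.g. sex); (6) additive kernel model (one of five kernels).
#'
#' @param geno a [genotype_matrix()].
#' @param expr expression matrix, samples x traits.
#' @param variant integer 1..6.
#' @param partition a [marker_partition()] (default singletons).
#' @param network a [trait_network()] (default fully connected).
#' @param lambda1,lambda2 penalty levels stored on the problem.
#' @param covariate per-sample covariate values (variant 5).
#' @param covariate_interactions also add covariate-by-set interaction
#'   groups (variant 5)?
#' @param kernel a [kernel_spec()] (variant 6).
#' @return An object of class `ngvs_problem`; see [ngvs_problem()].
#' @export
build_model <- function(geno, expr, variant, partition = NULL,
                        network = NULL, lambda1 = 0, lambda2 = 10,
                        covariate = NULL, covariate_interactions = FALSE,
                        kernel = NULL) {
  geno <- as_genotype_matrix(geno)
  partition <- default_partition(partition, ncol(geno))
  stopifnot(variant %in% 1:6)
  if (variant == 5L && is.null(covariate))
    stop("variant 5 needs a 'covariate' (e.g. sex)")
  if (variant == 6L && is.null(kernel))
    stop("variant 6 needs a 'kernel' specification")
  design <- switch(as.character(variant),
    "1" = encode_additive(geno, partition),
    "2" = encode_two_effect(geno, partition),
    "3" = add_adjacent_interactions(encode_additive(geno, partition)),
    "4" = add_adjacent_interactions(encode_two_effect(geno, partition)),
    "5" = add_covariate_group(encode_two_effect(geno, partition),
                              covariate, covariate_interactions, "sex"),
    "6" = kernelize_design(geno, partition, kernel))
  ngvs_problem(design, expr, network, lambda1 = lambda1, lambda2 = lambda2)
}

#' Assemble the joint multi-trait problem
#'
#' Standardizes the per-trait design, centers the responses, replicates
#' the design block-diagonally over the `G` traits (every trait shares
#' the same genotype regressors) and attaches the network penalty
#' operator.  Penalty group `(j, g)` holds marker set `j`'s columns for
#' trait `g`, weighted by `sqrt(group size)`.
#'
#' @param design an unstandardized per-trait `ngvs_design`.
#' @param expr expression matrix, samples x traits.
#' @param network a [trait_network()]; default fully connected.
#' @param lambda1,lambda2 penalty levels (both `>= 0`).
#' @return An object of class `ngvs_problem` with the sparse joint
#'   design `x` (`Gn x GP`), stacked centered response `y`, column
#'   groups, weights, the Laplacian operator `op`, and bookkeeping maps
#'   `group_trait` / `group_local` / `local_set`.
#' @export
ngvs_problem <- function(design, expr, network = NULL,
                         lambda1 = 0, lambda2 = 10) {
  expr <- as.matrix(expr)
  G <- ncol(expr)
  n <- nrow(expr)
  if (nrow(design$values) != n)
    stop("design and expression matrices disagree on the sample count")
  if (is.null(network)) {
    network <- if (G >= 2L) full_network(G)
               else trait_network(matrix(integer(0), 0L, 2L), 1L)
  }
  if (network$n_traits != G)
    stop("network has ", network$n_traits, " traits; expression has ", G)
  std <- standardize(design, expr)
  sd1 <- std$design
  P <- ncol(sd1$values)
  Jg <- max(sd1$group)
  xs <- as_sparse(sd1$values)
  x <- Matrix::bdiag(rep(list(xs), G))
  y <- as.numeric(std$responses)

  local_groups <- group_index(sd1$group)          # within-trait
  w1 <- group_weights(sd1$group)
  groups <- vector("list", G * Jg)
  for (g in seq_len(G)) {
    off <- (g - 1L) * P
    for (j in seq_len(Jg)) groups[[(g - 1L) * Jg + j]] <- local_groups[[j]] + off
  }
  weights <- rep(w1, times = G)
  group_trait <- rep(seq_len(G), each = Jg)
  group_local <- rep(seq_len(Jg), times = G)
  # marker set id of each within-trait group (NA for covariate groups)
  local_set <- vapply(seq_len(Jg), function(j) {
    s <- unique(sd1$set[local_groups[[j]]])
    if (length(s) == 1L && !is.na(s)) as.numeric(s) else NA_real_
  }, numeric(1))

  # a degree-0 trait leaves the smoothness penalty undefined: keep the
  # problem usable for lambda2 = 0 and defer the error to penalized use
  op <- if (all(network$degrees > 0L) && network$n_edges > 0L)
    laplacian_operator(network, P) else NULL
  structure(list(x = x, y = y, groups = groups, weights = weights,
                 group_trait = group_trait, group_local = group_local,
                 local_set = local_set, design = sd1,
                 response_center = std$response_center,
                 network = network, op = op,
                 lambda1 = lambda1, lambda2 = lambda2,
                 n = n, G = G, P = P, J = Jg),
            class = "ngvs_problem")
}

#' @export
print.ngvs_problem <- function(x, ...) {
  cat("NGVS problem: ", x$n, " samples, ", x$G, " traits, ", x$P,
      " columns/trait in ", x$J, " groups; network with ",
      x$network$n_edges, " edges; lambda1 = ", signif(x$lambda1, 4),
      ", lambda2 = ", signif(x$lambda2, 4), "\n", sep = "")
  invisible(x)
}

#' Evaluate the penalized selection criterion
#'
#' Returns
#' `||Y - X beta||^2 + lambda1 sum_{g,j} w_j ||beta_{j,g}|| +
#'  lambda2 beta' L beta`:
#' squared error, group penalty over marker sets within every trait,
#' and the network smoothness term.
#'
#' @param beta coefficient vector of length `G * P`.
#' @param problem an [ngvs_problem()].
#' @param lambda1,lambda2 optional overrides of the problem's levels.
#' @return A scalar.
#' @export
ngvs_criterion <- function(beta, problem, lambda1 = problem$lambda1,
                           lambda2 = problem$lambda2) {
  if (length(beta) != problem$G * problem$P)
    stop("beta must have length G * P = ", problem$G * problem$P)
  resid <- problem$y - as.numeric(problem$x %*% beta)
  pen <- sum(problem$weights *
               vapply(problem$groups,
                      function(i) sqrt(sum(beta[i]^2)), numeric(1)))
  net <- if (lambda2 > 0) {
    if (is.null(problem$op))
      stop("lambda2 > 0 requires a network in which every trait is linked")
    lambda2 * network_quadratic(beta, problem$op)
  } else 0
  sum(resid^2) + lambda1 * pen + net
}
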