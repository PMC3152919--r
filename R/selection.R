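# The three-stage QTL selection-order procedure: big-scale marker-set
# order (networked multi-trait fit), small-scale within-set order
# (single-trait group lasso), single-QTL p-values, and their
# combination; plus consensus sets and the post-hoc epistasis scan.

#' Big-scale marker-set selection order
#'
#' Runs the augmented group-lasso path on the joint multi-trait problem
#' and ranks, for every trait, the marker sets by the penalty level at
#' which their coefficient block first becomes nonzero (earliest entry
#' first).  The big-scale order is stable over a wide range of the
#' network penalty, so a fixed `lambda2` (default 10) is used and only
#' `lambda1` is varied, on a grid fine enough (with bisection
#' refinement) that marker sets enter one at a time.  Sets that never
#' enter are appended in order of their end-of-path gradient norm.
#'
#' @param problem an [ngvs_problem()].
#' @param lambda2 network penalty level for the path (default 10).
#' @param ... passed to [entry_path()] (grid controls, tolerances).
#' @return A list with `orders` (per trait, marker-set ids in selection
#'   order), `entry` (per-trait named vector of entry levels) and the
#'   underlying `path`.
#' @export
big_scale_order <- function(problem, lambda2 = 10, ...) {
  if (lambda2 > 0 && is.null(problem$op))
    stop("the problem has no usable network (a trait has degree 0); ",
         "lower the correlation cutoff or supply a larger network")
  if (lambda2 > 0) {
    E <- problem$network$n_edges; G <- problem$G
    P <- problem$P; n <- problem$n
    if (!(E > G * (P - n) / P))
      warning("network too small for saturation lifting: E <= G(P-n)/P; ",
              "the path can select at most Gn variables")
  }
  aug <- augment_dataset(problem$x, problem$y, problem$op,
                         lambda1 = 1, lambda2 = lambda2)
  path <- entry_path(aug$x_star, aug$y_star, problem$groups,
                     weights = problem$weights,
                     refine_classes = problem$group_trait, ...)
  orders <- vector("list", problem$G)
  entries <- vector("list", problem$G)
  for (g in seq_len(problem$G)) {
    gsel <- which(problem$group_trait == g & !is.na(problem$local_set))
    fe <- path$first_entry[gsel]
    tb <- path$tie_break[gsel]
    ge <- path$grad_end[gsel]
    sets <- problem$local_set[problem$group_local[gsel]]
    entered <- which(!is.na(fe))
    never <- which(is.na(fe))
    ord <- c(entered[order(-fe[entered], -tb[entered])],
             never[order(-ge[never])])
    orders[[g]] <- sets[ord]
    ent <- fe; names(ent) <- sets
    entries[[g]] <- ent
  }
  list(orders = orders, entry = entries, path = path)
}

#' Small-scale locus order within a marker set
#'
#' Single-trait group-lasso entry order over the loci of one marker
#' set, ignoring the loci grouping and the co-expression network: with
#' the two-effect coding each locus's additive and dominant dummies
#' form one group, so a locus enters as a unit.
#'
#' @param y_g response vector of one trait.
#' @param geno genotype codes of the set's loci (samples x loci).
#' @param loci original locus indices of the columns (default
#'   `1..ncol`).
#' @param coding `"two_effect"` or `"additive"`.
#' @param ... passed to [entry_path()].
#' @return A list with `order` (locus indices, strongest first) and
#'   `entry` (entry level per locus, `NA` if never entered).
#' @export
small_scale_order <- function(y_g, geno, loci = NULL,
                              coding = c("two_effect", "additive"), ...) {
  coding <- match.arg(coding)
  geno <- as.matrix(geno)
  if (is.null(loci)) loci <- seq_len(ncol(geno))
  if (ncol(geno) == 1L)
    return(list(order = loci, entry = stats::setNames(NA_real_, loci)))
  gm <- genotype_matrix(geno)
  design <- if (coding == "two_effect") encode_two_effect(gm)
            else encode_additive(gm)
  std <- standardize(design, matrix(y_g, ncol = 1L))
  if (ncol(geno) == 2L) {
    # exact: with two groups the first entrant is the larger marginal
    # gradient norm ||X_l' y|| / w_l (its own lambda_max), so the order
    # needs no path
    gl <- group_index(std$design$group)
    w <- group_weights(std$design$group)
    norms <- vapply(seq_along(gl), function(j)
      sqrt(sum(crossprod(std$design$values[, gl[[j]], drop = FALSE],
                         std$responses[, 1L])^2)) / w[j], numeric(1))
    o <- order(-norms)
    return(list(order = loci[o],
                entry = stats::setNames(norms, loci)))
  }
  path <- entry_path(std$design$values, std$responses[, 1L],
                     groups = std$design$group, ...)
  ord <- loci[path$full_order]
  ent <- path$first_entry
  names(ent) <- loci
  list(order = ord, entry = ent)
}

#' Single-QTL likelihood-ratio p-values
#'
#' Simple linear regression of one trait on each locus's additive code;
#' the slope is tested by the likelihood-ratio statistic
#' `n log(RSS0 / RSS1)` against a chi-squared distribution with one
#' degree of freedom.  Ranking by ascending p-value gives the
#' single-QTL selection order.
#'
#' @param y_g response vector of one trait (n >= 3).
#' @param geno a [genotype_matrix()] (or code matrix).
#' @return A numeric vector of p-values, one per locus; zero-variance
#'   loci get p = 1 with a warning.
#' @export
single_qtl_pvalues <- function(y_g, geno) {
  geno <- as.matrix(geno)
  n <- length(y_g)
  if (n < 3L) stop("need at least 3 samples")
  x <- matrix(as.numeric(geno), n)
  xc <- sweep(x, 2L, colMeans(x), "-")
  yc <- y_g - mean(y_g)
  sxx <- colSums(xc^2)
  syy <- sum(yc^2)
  sxy <- as.numeric(crossprod(xc, yc))
  degen <- sxx < 1e-12
  r2 <- ifelse(degen, 0, sxy^2 / (sxx * syy))
  stat <- -n * log(pmax(1 - r2, .Machine$double.xmin))
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  p[degen] <- 1
  if (any(degen))
    warning("zero-variance locus/loci: ", paste(which(degen), collapse = ", "),
            "; p-value set to 1")
  p
}

#' Combine the two selection scales into a final locus order
#'
#' Builds the final per-trait order as the unique ranking satisfying
#' the three criteria: (1) the leading (most significant) locus of each
#' marker set appears in big-scale set order; (2) loci within a marker
#' set appear in their small-scale order; (3) whenever several loci are
#' permitted by the first two criteria, the one with the smallest
#' single-QTL p-value goes first.  Operationally this is a greedy merge
#' of the per-set locus streams: at every step, among the loci whose
#' within-set predecessors (and, for set leaders, all higher-ranked
#' sets' leaders) are already placed, the smallest p-value wins.
#'
#' @param big marker-set ids in big-scale order.
#' @param small named list, one entry per marker set (names = set ids),
#'   each a vector of locus indices in small-scale order.
#' @param pvalues numeric vector of single-QTL p-values indexed by
#'   locus.
#' @param top_k optional truncation of the returned order.
#' @return Integer vector of locus indices, most significant first.
#' @examples
#' combine_orders(big = c(2, 1),
#'                small = list(`1` = c(1, 2), `2` = c(3, 4)),
#'                pvalues = c(0.01, 0.5, 0.02, 0.9))
#' @export
combine_orders <- function(big, small, pvalues, top_k = NULL) {
  big <- as.character(big)
  if (!setequal(big, names(small)))
    stop("big-scale order and small-scale orders cover different sets")
  loci <- unlist(small, use.names = FALSE)
  if (anyDuplicated(loci)) stop("a locus appears in more than one set")
  missing_p <- loci[is.na(pvalues[loci])]
  if (length(loci) > max(seq_along(pvalues)) || length(missing_p) > 0L)
    stop("missing p-values for loci: ",
         paste(if (length(missing_p)) missing_p else "out of range",
               collapse = ", "))
  streams <- lapply(small[big], as.integer)  # per set, big-scale rank order
  nsets <- length(streams)
  len <- lengths(streams)
  pos <- rep(1L, nsets)                 # next within-set slot per set
  leaders_placed <- 0L
  total <- length(loci)
  out <- integer(total)
  for (t in seq_len(total)) {
    # available: followers of sets whose leader is placed, plus the one
    # leader that is next in big-scale order
    cand <- which(pos <= len &
                    (pos > 1L | seq_len(nsets) == leaders_placed + 1L))
    cl <- vapply(cand, function(s) streams[[s]][pos[s]], integer(1))
    pick <- cand[order(pvalues[cl], cand)[1L]]
    out[t] <- streams[[pick]][pos[pick]]
    if (pos[pick] == 1L) leaders_placed <- leaders_placed + 1L
    pos[pick] <- pos[pick] + 1L
  }
  if (!is.null(top_k)) out <- head(out, top_k)
  out
}

#' Three-stage QTL selection orders
#'
#' The full procedure: (stage 1) big-scale marker-set order from the
#' networked multi-trait fit; (stage 2) small-scale locus order within
#' every marker set from single-trait group lasso; (stage 3) the final
#' per-trait locus order combining both scales with single-QTL p-values
#' as the adhesive.
#'
#' @inheritParams ngvs
#' @param lambda2 network penalty level for the big-scale path
#'   (default 10); `lambda2 = 0` gives single-trait selection (the
#'   network is ignored and traits decouple).
#' @param n_lambda,lambda_min_ratio,tol,max_iter path controls (see
#'   [entry_path()]).
#' @param big_lambda_min_ratio grid depth for the big-scale path only;
#'   on large problems the consumed part of the set order resolves high
#'   on the path, so a larger value (e.g. 0.2) saves the expensive
#'   weakly-penalized fits (sets that never enter are still ranked by
#'   gradient norm).
#' @param big_stop_per_trait stop the big-scale path once every trait
#'   has this many entered sets (see [entry_path()]).
#' @return An object of class `ngvs_order` with `big` (per trait),
#'   `small` (per trait, per set), `pvalues` (loci x traits), `final`
#'   (per trait) and the partition.
#' @examples
#' sim <- simulate_large_n(n = 60, snr = 5, seed = 1)
#' ord <- ngvs_order(sim$genotypes, sim$expression, sets = sim$partition,
#'                   network = sim$network)
#' ord$final[[1]]
#' @export
ngvs_order <- function(genotypes, expression, sets = NULL, network = NULL,
                       lambda2 = 10, coding = c("two_effect", "additive"),
                       n_lambda = 100L, lambda_min_ratio = 0.001,
                       big_lambda_min_ratio = lambda_min_ratio,
                       big_stop_per_trait = Inf,
                       tol = 1e-6, max_iter = 10000L) {
  coding <- match.arg(coding)
  geno <- as_genotype_matrix(genotypes)
  expression <- as.matrix(expression)
  sets <- default_partition(sets, ncol(geno))
  G <- ncol(expression)
  design <- if (coding == "two_effect") encode_two_effect(geno, sets)
            else encode_additive(geno, sets)
  problem <- ngvs_problem(design, expression, network,
                          lambda1 = 0, lambda2 = lambda2)
  big <- big_scale_order(problem, lambda2 = lambda2, n_lambda = n_lambda,
                         lambda_min_ratio = big_lambda_min_ratio,
                         stop_per_class = big_stop_per_trait,
                         tol = tol, max_iter = max_iter)
  J <- sets$n_sets
  pvals <- sapply(seq_len(G), function(g)
    single_qtl_pvalues(expression[, g], geno))
  small <- vector("list", G)
  final <- vector("list", G)
  for (g in seq_len(G)) {
    sg <- vector("list", J)
    names(sg) <- as.character(seq_len(J))
    for (j in seq_len(J)) {
      loci <- which(sets$set_of == j)
      sg[[j]] <- small_scale_order(expression[, g],
                                   geno[, loci, drop = FALSE],
                                   loci = loci, coding = coding,
                                   n_lambda = n_lambda,
                                   lambda_min_ratio = lambda_min_ratio,
                                   tol = tol, max_iter = max_iter)$order
    }
    small[[g]] <- sg
    final[[g]] <- combine_orders(big$orders[[g]], sg, pvals[, g])
  }
  structure(list(big = big$orders, small = small, pvalues = pvals,
                 final = final, partition = sets, lambda2 = lambda2,
                 coding = coding, big_entry = big$entry),
            class = "ngvs_order")
}

#' @export
print.ngvs_order <- function(x, ...) {
  G <- length(x$final)
  cat("Three-stage QTL selection orders for", G, "trait(s)\n")
  for (g in seq_len(G)) {
    cat("  trait ", g, ": sets [", paste(head(x$big[[g]], 5L), collapse = ", "),
        if (length(x$big[[g]]) > 5L) ", ..." else "",
        "]  loci [", paste(head(x$final[[g]], 5L), collapse = ", "),
        if (length(x$final[[g]]) > 5L) ", ..." else "", "]\n", sep = "")
  }
  invisible(x)
}

#' Marker sets significant across most traits
#'
#' Picks, from the per-trait big-scale orders, the marker sets that
#' appear among the top `m` of at least `ceiling(threshold * G)`
#' traits; used when the interest is in general (consensus) findings
#' for a class of traits rather than a single one.
#'
#' @param big_orders list of per-trait big-scale set orders (e.g.
#'   `x$big` of an [ngvs_order()]).
#' @param m how deep to look in each trait's order (default 3).
#' @param threshold required fraction of supporting traits
#'   (default 0.5).
#' @return Integer vector of set ids (most supported first) with a
#'   `support` attribute counting supporting traits.
#' @export
consensus_sets <- function(big_orders, m = 3L, threshold = 0.5) {
  G <- length(big_orders)
  tops <- lapply(big_orders, function(o) head(o, m))
  counts <- table(unlist(tops))
  need <- ceiling(threshold * G)
  keep <- counts[counts >= need]
  if (length(keep) == 0L)
    return(structure(integer(0), support = integer(0)))
  ord <- order(-as.numeric(keep))
  structure(as.integer(names(keep))[ord],
            support = as.integer(keep)[ord])
}

#' Post-hoc scan for epistatic (two-locus) interactions
#'
#' Restricted to the loci of the consensus marker sets, each trait gets
#' a group-lasso entry order over per-locus two-effect groups plus one
#' singleton group per adjacent-locus interaction (product of additive
#' codes).  Interactions appearing among a trait's first `top_k` groups
#' are collected with the number of supporting traits.
#'
#' @param expression expression matrix, samples x traits.
#' @param geno a [genotype_matrix()].
#' @param partition the [marker_partition()] defining the sets.
#' @param sets_to_scan consensus set ids (see [consensus_sets()]).
#' @param top_k how deep in each trait's entry order to look
#'   (default 3).
#' @param ... passed to [entry_path()].
#' @return A data.frame with columns `locus_a`, `locus_b`, `support`,
#'   sorted by support.
#' @export
epistasis_scan <- function(expression, geno, partition, sets_to_scan,
                           top_k = 3L, ...) {
  geno <- as_genotype_matrix(geno)
  expression <- as.matrix(expression)
  partition <- default_partition(partition, ncol(geno))
  loci <- which(partition$set_of %in% sets_to_scan)
  if (length(loci) < 1L) stop("no loci in the sets to scan")
  sub <- genotype_matrix(geno[, loci, drop = FALSE])
  design <- encode_two_effect(sub)   # per-locus groups (singleton sets)
  codes <- matrix(as.numeric(sub), nrow(sub))
  pairs <- list()
  for (s in sets_to_scan) {
    mk <- which(partition$set_of == s)
    if (length(mk) < 2L) next
    for (i in seq_len(length(mk) - 1L))
      pairs[[length(pairs) + 1L]] <- c(mk[i], mk[i + 1L])
  }
  n_loc <- length(loci)
  if (length(pairs) > 0L) {
    inter <- sapply(pairs, function(pr) {
      ia <- match(pr[1L], loci); ib <- match(pr[2L], loci)
      codes[, ia] * codes[, ib]
    })
    colnames(inter) <- vapply(pairs, function(pr)
      paste0("I", pr[1L], "x", pr[2L]), character(1))
    vals <- cbind(design$values, inter)
    groups <- c(design$group, n_loc + seq_along(pairs))
  } else {
    vals <- design$values
    groups <- design$group
  }
  G <- ncol(expression)
  support <- integer(length(pairs))
  for (g in seq_len(G)) {
    d2 <- new_design(vals, marker = NA, set = NA, group = groups,
                     coding = "two_effect")
    std <- standardize(d2, expression[, g, drop = FALSE])
    path <- entry_path(std$design$values, std$responses[, 1L],
                       groups = std$design$group, ...)
    top <- head(path$full_order, top_k)
    hits <- top[top > n_loc] - n_loc
    support[hits] <- support[hits] + 1L
  }
  out <- data.frame(
    locus_a = vapply(pairs, `[`, 1L, FUN.VALUE = numeric(1)),
    locus_b = vapply(pairs, `[`, 2L, FUN.VALUE = numeric(1)),
    support = support)
  out[order(-out$support), , drop = FALSE]
}
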