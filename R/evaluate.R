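# Scoring and benchmark drivers: sensitivity/specificity of a selected
# locus list, TP/FP at a cut-off, ROC area, and the simulation
# comparisons of NGVS against single-trait selection, per-locus group
# lasso, the additive lasso and single-QTL regression.

#' Sensitivity and specificity of a selected locus list
#'
#' @param selected integer vector of selected locus indices.
#' @param truth causal locus indices (nonempty).
#' @param n_loci total number of loci.
#' @return `c(sensitivity, specificity)`.
#' @export
sensitivity_specificity <- function(selected, truth, n_loci) {
  if (length(truth) == 0L) stop("truth must be nonempty")
  if (length(selected) > 0L && any(!selected %in% seq_len(n_loci)))
    stop("selected loci out of range")
  tp <- length(intersect(selected, truth))
  fp <- length(selected) - tp
  neg <- n_loci - length(truth)
  c(sensitivity = tp / length(truth),
    specificity = if (neg == 0L) 1 else (neg - fp) / neg)
}

#' True and false positives among the first k of an order
#'
#' @param order locus indices, most significant first.
#' @param truth causal locus indices.
#' @param k cut-off (`k <= length(order)`).
#' @return `c(TP, FP)` with `TP + FP = k`.
#' @export
tp_fp_at_k <- function(order, truth, k) {
  if (k > length(order)) stop("k exceeds the order length")
  sel <- order[seq_len(k)]
  tp <- length(intersect(sel, truth))
  c(TP = tp, FP = k - tp)
}

#' ROC curve and area for a complete selection order
#'
#' Sweeps the cut-off `k = 0..p` over an order covering all loci and
#' integrates sensitivity against the false-positive rate by the
#' trapezoidal rule.  Causal loci ranked first give area 1, ranked last
#' give area 0.
#'
#' @param order complete locus order.
#' @param truth causal locus indices.
#' @return A list with `fpr`, `tpr` and `auc`.
#' @export
roc_auc <- function(order, truth) {
  p <- length(order)
  if (!setequal(order, seq_len(p)))
    stop("order must cover all loci exactly once")
  hits <- cumsum(order %in% truth)
  tpr <- c(0, hits / length(truth))
  fpr <- c(0, (seq_len(p) - hits) / (p - length(truth)))
  auc <- sum(diff(fpr) * (head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

# -- per-trait comparison orders ---------------------------------------

#' Single-trait baseline selection orders
#'
#' `glasso_entry_order` ranks loci for one trait by the group-lasso
#' entry order over per-locus two-effect groups (no marker sets beyond
#' the locus, no network); `lasso_entry_order` does the same with the
#' additive coding and singleton groups (the classical lasso);
#' `single_qtl_order` ranks loci by ascending likelihood-ratio p-value.
#'
#' @param y_g response vector of one trait.
#' @param geno a [genotype_matrix()] (or code matrix).
#' @param ... passed to [entry_path()].
#' @return Integer vector of locus indices, strongest first.
#' @export
glasso_entry_order <- function(y_g, geno, ...) {
  design <- encode_two_effect(as_genotype_matrix(geno))
  std <- standardize(design, matrix(y_g, ncol = 1L))
  path <- entry_path(std$design$values, std$responses[, 1L],
                     groups = std$design$group, ...)
  path$full_order
}

#' @rdname glasso_entry_order
#' @export
lasso_entry_order <- function(y_g, geno, ...) {
  design <- encode_additive(as_genotype_matrix(geno))
  std <- standardize(design, matrix(y_g, ncol = 1L))
  path <- entry_path(std$design$values, std$responses[, 1L],
                     groups = std$design$group, ...)
  path$full_order
}

#' @rdname glasso_entry_order
#' @export
single_qtl_order <- function(y_g, geno) {
  order(single_qtl_pvalues(y_g, geno))
}

# -- benchmark drivers -------------------------------------------------

#' Benchmark NGVS against baseline selectors on simulated data
#'
#' `design = "large_n"`: for each of the four reference settings
#' (proper/tangled marker sets x SNR 1/5) and each replicate, computes
#' the per-trait sensitivity and specificity of declaring the first
#' `top` loci of each method's final order significant.  Methods:
#' `"ngvs"` (three-stage, network), `"glasso"` (per-locus two-effect
#' groups, no network), `"lasso"` (additive coding).
#'
#' `design = "large_p"`: for each replicate (60 x 200 x 5 at SNR 5) and
#' each fixed-window size `r`, computes total true/false positives over
#' all traits when the first `k` loci are declared significant.
#' Methods: `"ngvs"` and `"single_trait"` (expanded over `r_values`),
#' `"single_qtl"`, `"lasso"`.
#'
#' @param design `"large_n"` or `"large_p"`.
#' @param methods subset of the methods above.
#' @param reps number of independent datasets (reference scale: 50 for
#'   `large_n`, 20 for `large_p`).
#' @param seed base seed; replicate `i` of setting `m` uses
#'   `seed + 1000 * m + i`.
#' @param models which large-n settings to run (subset of 1:4).
#' @param top how many loci are declared significant (large_n,
#'   default 3).
#' @param r_values fixed-window sizes (large_p).
#' @param k_values cut-offs for TP/FP (large_p).
#' @param n sample count for large_n datasets.
#' @param tol solver tolerance used along the paths; defaults to
#'   `1e-6` (`large_n`) or `1e-5` (`large_p`, where entry orders are
#'   insensitive to the last digits of the fits).
#' @param n_lambda path grid size; defaults to 100 (`large_n`) or 40
#'   (`large_p`, where bisection keeps entries separated).
#' @return A data.frame with columns `method, model, trait, metric,
#'   k_or_top, mean, sd, reps, seed`.  For `large_p`, `mean` holds the
#'   summed counts over traits and replicates.
#' @export
run_benchmark <- function(design = c("large_n", "large_p"),
                          methods = NULL, reps = NULL, seed = 1L,
                          models = 1:4, top = 3L,
                          r_values = c(1L, 2L, 5L, 10L),
                          k_values = 2:5, n = 60L,
                          tol = NULL, n_lambda = NULL) {
  design <- match.arg(design)
  if (is.null(tol)) tol <- if (design == "large_n") 1e-6 else 1e-5
  if (is.null(n_lambda)) n_lambda <- if (design == "large_n") 100L else 40L
  if (design == "large_n") {
    if (is.null(methods)) methods <- c("ngvs", "glasso", "lasso")
    if (is.null(reps)) reps <- 50L
    bad <- setdiff(methods, c("ngvs", "glasso", "lasso"))
    if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))
    benchmark_large_n(methods, reps, seed, models, top, n, tol, n_lambda)
  } else {
    if (is.null(methods)) methods <- c("ngvs", "single_trait",
                                       "single_qtl", "lasso")
    if (is.null(reps)) reps <- 20L
    bad <- setdiff(methods, c("ngvs", "single_trait", "single_qtl", "lasso"))
    if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))
    benchmark_large_p(methods, reps, seed, r_values, k_values, tol, n_lambda)
  }
}

large_n_setting <- function(model) {
  # model 1: proper sets, SNR 1; 2: proper, SNR 5; 3: tangled, SNR 1;
  # model 4: tangled, SNR 5
  list(sets = if (model %in% c(1L, 2L)) "proper" else "tangled",
       snr = if (model %in% c(1L, 3L)) 1 else 5)
}

benchmark_large_n <- function(methods, reps, seed, models, top, n,
                              tol, n_lambda) {
  rows <- list()
  for (m in models) {
    cfg <- large_n_setting(m)
    G <- 2L
    acc <- array(NA_real_, dim = c(length(methods), G, 2L, reps),
                 dimnames = list(methods, NULL, c("sensitivity",
                                                  "specificity"), NULL))
    for (i in seq_len(reps)) {
      sim <- simulate_large_n(n = n, snr = cfg$snr, sets = cfg$sets,
                              seed = seed + 1000L * m + i)
      p <- ncol(sim$genotypes)
      truth <- sim$truth$causal_loci
      for (meth in methods) {
        for (g in seq_len(G)) {
          sel <- switch(meth,
            ngvs = NULL,  # filled below from the joint fit
            glasso = head(glasso_entry_order(sim$expression[, g],
                                             sim$genotypes, tol = tol,
                                             n_lambda = n_lambda), top),
            lasso = head(lasso_entry_order(sim$expression[, g],
                                           sim$genotypes, tol = tol,
                                           n_lambda = n_lambda), top))
          if (!is.null(sel))
            acc[meth, g, , i] <- sensitivity_specificity(sel, truth, p)
        }
        if (meth == "ngvs") {
          ord <- ngvs_order(sim$genotypes, sim$expression,
                            sets = sim$partition, network = sim$network,
                            lambda2 = 10, tol = tol, n_lambda = n_lambda)
          for (g in seq_len(G))
            acc["ngvs", g, , i] <- sensitivity_specificity(
              head(ord$final[[g]], top), truth, p)
        }
      }
    }
    for (meth in methods) for (g in seq_len(G))
      for (met in c("sensitivity", "specificity"))
        rows[[length(rows) + 1L]] <- data.frame(
          method = meth, model = m, trait = g, metric = met,
          k_or_top = top, mean = mean(acc[meth, g, met, ]),
          sd = if (reps > 1L) sd(acc[meth, g, met, ]) else 0,
          reps = reps, seed = seed)
  }
  do.call(rbind, rows)
}

benchmark_large_p <- function(methods, reps, seed, r_values, k_values,
                              tol, n_lambda) {
  labels <- c()
  for (meth in methods) {
    if (meth %in% c("ngvs", "single_trait"))
      labels <- c(labels, paste0(meth, "_r", r_values))
    else labels <- c(labels, meth)
  }
  tp <- matrix(0L, length(labels), length(k_values),
               dimnames = list(labels, k_values))
  fp <- tp
  for (i in seq_len(reps)) {
    sim <- simulate_large_p(seed = seed + 1000L + i)
    geno <- sim$genotypes
    truth <- sim$truth$causal_loci
    G <- ncol(sim$expression)
    orders <- list()
    for (meth in methods) {
      if (meth %in% c("ngvs", "single_trait")) {
        for (r in r_values) {
          partition <- form_marker_sets(geno, "fixed_size", r = r)
          ord <- ngvs_order(geno, sim$expression, sets = partition,
                            network = if (meth == "ngvs") sim$network
                                      else NULL,
                            lambda2 = if (meth == "ngvs") 10 else 0,
                            tol = tol, n_lambda = n_lambda,
                            big_lambda_min_ratio = 0.2,
                            big_stop_per_trait = 8L)
          orders[[paste0(meth, "_r", r)]] <- ord$final
        }
      } else if (meth == "single_qtl") {
        orders[["single_qtl"]] <- lapply(seq_len(G), function(g)
          single_qtl_order(sim$expression[, g], geno))
      } else if (meth == "lasso") {
        orders[["lasso"]] <- lapply(seq_len(G), function(g)
          lasso_entry_order(sim$expression[, g], geno, tol = tol,
                            n_lambda = n_lambda))
      }
    }
    for (lab in labels) for (ki in seq_along(k_values)) {
      for (g in seq_len(G)) {
        cnt <- tp_fp_at_k(orders[[lab]][[g]], truth, k_values[ki])
        tp[lab, ki] <- tp[lab, ki] + cnt["TP"]
        fp[lab, ki] <- fp[lab, ki] + cnt["FP"]
      }
    }
  }
  rows <- list()
  for (lab in labels) for (ki in seq_along(k_values)) {
    rows[[length(rows) + 1L]] <- data.frame(
      method = lab, model = "large_p", trait = NA_integer_,
      metric = "TP", k_or_top = k_values[ki], mean = tp[lab, ki],
      sd = NA_real_, reps = reps, seed = seed)
    rows[[length(rows) + 1L]] <- data.frame(
      method = lab, model = "large_p", trait = NA_integer_,
      metric = "FP", k_or_top = k_values[ki], mean = fp[lab, ki],
      sd = NA_real_, reps = reps, seed = seed)
  }
  do.call(rbind, rows)
}
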