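# Synthetic F2-cross generators with known truth.  Latent multivariate
# Gaussians are trichotomized at the outer quartiles into genotype
# codes; traits are driven by additive + dominant effects of a few
# causal loci with per-dataset effect perturbation, plus correlated
# Gaussian noise scaled to a target signal-to-noise ratio.

trichotomize <- function(z) {
  lo <- qnorm(0.25); hi <- qnorm(0.75)
  out <- matrix(0L, nrow(z), ncol(z))
  out[z < lo] <- -1L
  out[z > hi] <- 1L
  out
}

mvn_draw <- function(n, sigma_chol) {
  matrix(rnorm(n * ncol(sigma_chol)), n) %*% sigma_chol
}

# additive + dominant signal of the causal loci; effects perturbed per
# (locus, dummy, trait) by U(0.9, 1.1), constant across samples
two_effect_signal <- function(codes, causal, n_traits, effects) {
  n <- nrow(codes)
  signal <- matrix(0, n, n_traits)
  pert <- array(runif(length(causal) * 2L * n_traits, 0.9, 1.1),
                dim = c(length(causal), 2L, n_traits))
  for (g in seq_len(n_traits)) {
    for (i in seq_along(causal)) {
      l <- causal[i]
      signal[, g] <- signal[, g] +
        effects$additive * pert[i, 1L, g] * (codes[, l] == 1L) +
        effects$dominant * pert[i, 2L, g] * (codes[, l] == 0L)
    }
  }
  list(signal = signal, perturbation = pert)
}

#' Noise covariance matching a target signal-to-noise ratio
#'
#' The SNR is the mean square of a trait's genetic signal over its
#' noise variance, so `sigma_g^2 = mean-square(signal_g) / snr`;
#' off-diagonal noise covariances are `rho * sigma_u * sigma_v`
#' (default correlation 0.5).  The mean square is taken of the centered
#' signal: the dummy coding gives the raw signal a large constant mean
#' that the model removes by centering the responses, so only the
#' varying part counts as signal.
#'
#' @param signal matrix of noiseless trait values, samples x traits.
#' @param snr target signal-to-noise ratio (> 0).
#' @param rho noise correlation between traits.
#' @return The noise covariance matrix.
#' @export
scale_noise_to_snr <- function(signal, snr, rho = 0.5) {
  if (snr <= 0) stop("snr must be positive")
  signal <- as.matrix(signal)
  signal <- sweep(signal, 2L, colMeans(signal), "-")
  ms <- colMeans(signal^2)
  if (any(ms == 0)) stop("a trait has zero signal; cannot set the SNR")
  s <- sqrt(ms / snr)
  sigma <- rho * tcrossprod(s)
  diag(sigma) <- s^2
  sigma
}

#' Simulate the low-dimensional ("large n small p") design
#'
#' Seven latent genotype variables with `Cov(Z1, Z2) = 0.8` and
#' `Cov(Zi, Zj) = 0.4^|i-j|` otherwise are trichotomized at the
#' standard-normal quartiles into codes `-1, 0, 1` (so marginally
#' `P(aa) = P(AA) = 1/4`, `P(Aa) = 1/2`).  Two linked expression traits
#' are driven by the additive and dominant effects (AA and Aa dummies)
#' of loci 1-3, each effect perturbed per dataset by a `U(0.9, 1.1)`
#' factor, plus correlated Gaussian noise scaled to the target SNR.
#'
#' Two marker-set layouts are available: `"proper"` groups the highly
#' correlated pair `{Z1, Z2}` and leaves the rest singletons;
#' `"tangled"` is a deliberately bad division `{Z1, Z2, Z4}, {Z3, Z5},
#' {Z6, Z7}` in which every causal locus shares a set with a null one.
#'
#' @param n sample count (default 60, matching the linkage study the
#'   simulations emulate).
#' @param snr target signal-to-noise ratio (the reference settings use
#'   1 and 5).
#' @param sets `"proper"` or `"tangled"`.
#' @param effects list with `additive` and `dominant` coefficients
#'   applied to every causal locus and trait (default 1 and 1).
#' @param n_traits number of traits (default 2, on a single-edge
#'   network).
#' @param seed optional seed.
#' @return A list of class `ngvs_sim`: `genotypes`, `expression`,
#'   `partition`, `network`, `truth` (`causal_loci`, `causal_sets`),
#'   and the generator internals `latent`, `signal`, `sigma`,
#'   `perturbation`.
#' @export
simulate_large_n <- function(n = 60L, snr = 1,
                             sets = c("proper", "tangled"),
                             effects = list(additive = 1, dominant = 1),
                             n_traits = 2L, seed = NULL) {
  sets <- match.arg(sets)
  if (!is.null(seed)) set.seed(seed)
  p <- 7L
  sigma_z <- 0.4^abs(outer(seq_len(p), seq_len(p), "-"))
  sigma_z[1L, 2L] <- sigma_z[2L, 1L] <- 0.8
  z <- mvn_draw(n, chol(sigma_z))
  codes <- trichotomize(z)
  causal <- 1:3
  sig <- two_effect_signal(codes, causal, n_traits, effects)
  sigma_e <- scale_noise_to_snr(sig$signal, snr, rho = 0.5)
  expr <- sig$signal + mvn_draw(n, chol(sigma_e))
  colnames(expr) <- paste0("trait", seq_len(n_traits))
  set_of <- if (sets == "proper") c(1L, 1L, 2L, 3L, 4L, 5L, 6L)
            else c(1L, 1L, 2L, 1L, 2L, 3L, 3L)
  partition <- marker_partition(set_of)
  network <- if (n_traits >= 2L) full_network(n_traits)
             else trait_network(matrix(integer(0), 0L, 2L), 1L)
  structure(list(genotypes = genotype_matrix(codes),
                 expression = expr,
                 partition = partition,
                 network = network,
                 truth = list(causal_loci = causal,
                              causal_sets = unique(set_of[causal])),
                 latent = z, signal = sig$signal, sigma = sigma_e,
                 perturbation = sig$perturbation,
                 snr = snr, sets = sets, seed = seed, design = "large_n"),
            class = "ngvs_sim")
}

#' Simulate the high-dimensional ("large p small n") design
#'
#' 200 latent genotype variables with covariance `0.4^|i-j|`, truncated
#' to zero when markers are more than 10 apart (eigenvalue-clipped to
#' the nearest positive-definite matrix if the truncation breaks
#' definiteness), are trichotomized into codes for 60 samples.  Five
#' traits on a fully connected co-expression network are driven by the
#' additive + dominant effects of causal loci 3, 4, 13 and 27 (three
#' different marker sets under the `r = 10` fixed-window partition),
#' with `U(0.9, 1.1)` effect perturbation and correlated noise at
#' SNR 5.
#'
#' @param n,p,n_traits dimensions (defaults 60 x 200 x 5).
#' @param snr target signal-to-noise ratio (default 5).
#' @param causal causal locus indices (default `c(3, 4, 13, 27)`).
#' @param effects list with `additive` and `dominant` coefficients.
#' @param max_lag covariance truncation distance (default 10).
#' @param seed optional seed.
#' @return A list of class `ngvs_sim`, as [simulate_large_n()]; the
#'   `network` is the full graph on the traits.
#' @export
simulate_large_p <- function(n = 60L, p = 200L, n_traits = 5L, snr = 5,
                             causal = c(3L, 4L, 13L, 27L),
                             effects = list(additive = 1, dominant = 1),
                             max_lag = 10L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lag <- abs(outer(seq_len(p), seq_len(p), "-"))
  sigma_z <- 0.4^lag
  sigma_z[lag > max_lag] <- 0
  ev <- eigen(sigma_z, symmetric = TRUE)
  if (min(ev$values) < 1e-8) {
    warning("truncated covariance not positive definite; ",
            "clipping eigenvalues at 1e-8")
    sigma_z <- ev$vectors %*% (pmax(ev$values, 1e-8) * t(ev$vectors))
  }
  z <- mvn_draw(n, chol(sigma_z))
  codes <- trichotomize(z)
  sig <- two_effect_signal(codes, causal, n_traits, effects)
  sigma_e <- scale_noise_to_snr(sig$signal, snr, rho = 0.5)
  expr <- sig$signal + mvn_draw(n, chol(sigma_e))
  colnames(expr) <- paste0("trait", seq_len(n_traits))
  structure(list(genotypes = genotype_matrix(codes),
                 expression = expr,
                 partition = NULL,   # choose with form_marker_sets()
                 network = full_network(n_traits),
                 truth = list(causal_loci = causal, causal_sets = NULL),
                 latent = z, signal = sig$signal, sigma = sigma_e,
                 perturbation = sig$perturbation,
                 snr = snr, seed = seed, design = "large_p"),
            class = "ngvs_sim")
}

#' @export
print.ngvs_sim <- function(x, ...) {
  cat("Simulated eQTL dataset (", x$design, "): ",
      nrow(x$genotypes), " samples, ", ncol(x$genotypes), " markers, ",
      ncol(x$expression), " traits, SNR ", x$snr,
      "; causal loci ", paste(x$truth$causal_loci, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Marker sets containing the causal loci
#'
#' @param truth a `truth` element of an `ngvs_sim` (or a vector of
#'   causal loci).
#' @param partition a [marker_partition()].
#' @return Sorted unique set indices.
#' @export
truth_sets <- function(truth, partition) {
  loci <- if (is.list(truth)) truth$causal_loci else truth
  sort(unique(partition$set_of[loci]))
}
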