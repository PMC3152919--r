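#' SNP-set kernel specification
#'
#' @param kind one of `"linear"`, `"polynomial"`, `"gaussian"`,
#'   `"ibs"`, `"wibs"`.
#' @param q polynomial order (default 2).
#' @param d Gaussian bandwidth (default 1); the squared distance is
#'   scaled by `d * p_j` so bandwidths are comparable across set sizes.
#' @param maf per-marker minor allele frequencies, required for
#'   `"wibs"`; rare alleles get weight `1/sqrt(maf)`.
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(kind = c("linear", "polynomial", "gaussian",
                                 "ibs", "wibs"),
                        q = 2L, d = 1, maf = NULL) {
  kind <- match.arg(kind)
  if (q < 1L || q != round(q)) stop("q must be a positive integer")
  if (d <= 0) stop("d must be positive")
  if (!is.null(maf) && any(maf <= 0 | maf > 0.5))
    stop("maf entries must lie in (0, 0.5]")
  structure(list(kind = kind, q = as.integer(q), d = d, maf = maf),
            class = "kernel_spec")
}

#' Minor allele frequencies of a marker block
#'
#' Genotype codes are converted to allele counts (`aa, Aa, AA` ->
#' `0, 1, 2`); with `f` the mean allele count over `2`, the MAF is
#' `min(f, 1 - f)`.
#'
#' @param xj genotype codes (`{-1, 0, 1}`), samples x markers.
#' @return Frequencies in `[0, 0.5]`, one per marker.
#' @export
minor_allele_freq <- function(xj) {
  xj <- as.matrix(xj)
  counts <- xj + 1
  f <- colMeans(counts) / 2
  pmin(f, 1 - f)
}

#' Kernel matrix of one marker set
#'
#' Computes the `n x n` similarity matrix of a marker set under the
#' chosen kernel.  With `X_j` the raw code matrix (`{-1,0,1}`) and `g`
#' the allele counts (`{0,1,2}`):
#' linear `K = X_j X_j'`; polynomial `K = (1 + X_j X_j')^q`
#' (elementwise); Gaussian
#' `K(i, i') = exp(-||x_i - x_{i'}||^2 / (d p_j))`; IBS
#' `K(i, i') = sum_k (2 - |g_ik - g_{i'k}|) / (2 p_j)`; weighted IBS
#' replaces the uniform average by weights `w_k = 1/sqrt(q_jk)`
#' normalized by `2 sum_k w_k`, up-weighting rare alleles.
#'
#' @param xj genotype codes of one marker set, samples x `p_j` markers.
#' @param spec a [kernel_spec()].  For `"wibs"`, `spec$maf` may be
#'   omitted, in which case frequencies are estimated from `xj`
#'   (monomorphic markers are an error: their weight is infinite).
#' @return A symmetric `n x n` matrix; IBS-type kernels have unit
#'   diagonal and values in `[0, 1]`.
#' @examples
#' g <- rbind(c(-1, 0), c(1, 0), c(0, 1))
#' kernel_matrix(g, kernel_spec("ibs"))
#' @export
kernel_matrix <- function(xj, spec) {
  xj <- as.matrix(xj)
  if (!all(xj %in% c(-1, 0, 1))) stop("invalid genotype code in marker set")
  pj <- ncol(xj)
  switch(spec$kind,
    linear = tcrossprod(xj),
    polynomial = (1 + tcrossprod(xj))^spec$q,
    gaussian = {
      sq <- as.matrix(stats::dist(xj))^2
      exp(-sq / (spec$d * pj))
    },
    ibs = {
      counts <- xj + 1
      ibs_sum(counts, rep(1, pj)) / (2 * pj)
    },
    wibs = {
      maf <- spec$maf
      if (is.null(maf)) maf <- minor_allele_freq(xj)
      if (length(maf) != pj) stop("maf length must match the marker count")
      if (any(maf <= 0))
        stop("monomorphic marker (MAF 0) under the weighted IBS kernel")
      w <- 1 / sqrt(maf)
      ibs_sum(xj + 1, w) / (2 * sum(w))
    })
}

# sum_k w_k * (2 - |g_ik - g_i'k|) without an explicit n^2 p loop
ibs_sum <- function(counts, w) {
  n <- nrow(counts)
  out <- matrix(2 * sum(w), n, n)
  for (k in seq_len(ncol(counts))) {
    out <- out - w[k] * abs(outer(counts[, k], counts[, k], "-"))
  }
  out
}

#' Kernel representation of the design
#'
#' Replaces each marker set's columns by the `n` columns of its kernel
#' matrix, following the representer expansion of the set's epistatic
#' relationship function: the `J` kernels act as `J x n` correlated new
#' variables, all `n` columns of set `j` sharing penalty group `j`, so
#' the big-scale selection order is computed exactly as for the linear
#' design.
#'
#' @param geno a [genotype_matrix()].
#' @param partition a [marker_partition()].
#' @param spec a [kernel_spec()].
#' @return An unstandardized `ngvs_design` with `J * n` columns.
#' @export
kernelize_design <- function(geno, partition, spec) {
  geno <- as_genotype_matrix(geno)
  partition <- default_partition(partition, ncol(geno))
  n <- nrow(geno)
  J <- partition$n_sets
  blocks <- vector("list", J)
  for (j in seq_len(J)) {
    xj <- geno[, partition$set_of == j, drop = FALSE]
    K <- kernel_matrix(matrix(as.numeric(xj), n), spec)
    colnames(K) <- paste0("set", j, ":k", seq_len(n))
    blocks[[j]] <- K
  }
  values <- do.call(cbind, blocks)
  new_design(values,
             marker = rep(NA_integer_, J * n),
             set = rep(seq_len(J), each = n),
             group = rep(seq_len(J), each = n),
             coding = paste0("kernel_", spec$kind))
}
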