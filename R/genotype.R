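#' Genotype matrix for an F2 cross
#'
#' Wraps an `n x p` matrix of trichotomous genotype codes: `-1` (aa),
#' `0` (Aa) and `1` (AA).  Missing values and any other codes are
#' rejected; imputation is out of scope.
#'
#' @param values integer (or numeric) matrix, samples in rows, markers in
#'   columns, entries in `{-1, 0, 1}`.
#' @param marker_names optional character vector of marker names
#'   (defaults to the column names, or `M1..Mp`).
#' @param chrom optional chromosome label per marker, used by
#'   [form_marker_sets()] with `method = "by_chromosome"`.
#' @return An object of class `ngvs_geno`: the validated code matrix with
#'   attributes `marker_names` and `chrom`.
#' @examples
#' g <- genotype_matrix(rbind(c(-1, 0), c(1, 1), c(0, -1)))
#' dim(g)
#' @export
genotype_matrix <- function(values, marker_names = NULL, chrom = NULL) {
  values <- as.matrix(values)
  if (anyNA(values))
    stop("genotype matrix contains missing values; imputation is not supported")
  if (!all(values %in% c(-1, 0, 1)))
    stop("invalid genotype code: entries must be -1 (aa), 0 (Aa) or 1 (AA)")
  if (nrow(values) < 2L) stop("need at least 2 samples")
  if (ncol(values) < 1L) stop("need at least 1 marker")
  storage.mode(values) <- "integer"
  if (is.null(marker_names)) marker_names <- colnames(values)
  if (is.null(marker_names)) marker_names <- paste0("M", seq_len(ncol(values)))
  if (length(marker_names) != ncol(values))
    stop("marker_names length does not match the number of markers")
  if (!is.null(chrom) && length(chrom) != ncol(values))
    stop("chrom length does not match the number of markers")
  colnames(values) <- marker_names
  structure(values,
            marker_names = marker_names,
            chrom = chrom,
            class = c("ngvs_geno", "matrix", "array"))
}

as_genotype_matrix <- function(x) {
  if (inherits(x, "ngvs_geno")) x else genotype_matrix(x)
}

#' @export
print.ngvs_geno <- function(x, ...) {
  cat("Genotype matrix:", nrow(x), "samples x", ncol(x), "markers",
      if (!is.null(attr(x, "chrom"))) "(with chromosome labels)" else "", "\n")
  invisible(x)
}

#' Read genotype codes from CSV
#'
#' Expects a header row of marker names and the sample identifier in the
#' first column.  An optional marker-info CSV (columns `marker`,
#' `chromosome`, and optionally `position`) supplies chromosome labels.
#'
#' @param file path to the genotype CSV.
#' @param marker_info optional path to a marker-info CSV.
#' @return An [genotype_matrix()] object.
#' @export
read_genotypes <- function(file, marker_info = NULL) {
  d <- read.csv(file, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- as.character(d[[1]])
  chrom <- NULL
  if (!is.null(marker_info)) {
    info <- read.csv(marker_info, check.names = FALSE)
    chrom <- as.character(info$chromosome[match(colnames(m), info$marker)])
    if (anyNA(chrom))
      stop("marker_info is missing chromosome labels for some markers")
  }
  genotype_matrix(m, chrom = chrom)
}

#' Read an expression matrix from CSV
#'
#' First column is the sample identifier; the header names the traits.
#'
#' @param file path to the expression CSV.
#' @return A numeric matrix, samples in rows, traits in columns.
#' @export
read_expression <- function(file) {
  d <- read.csv(file, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- as.character(d[[1]])
  storage.mode(m) <- "double"
  m
}

#' Additive (single-dummy) genotype encoding
#'
#' Each marker contributes one regressor carrying its raw code in
#' `{-1, 0, 1}`, so a unit coefficient is half the aa-to-AA contrast.
#' This is the coding used by the classical lasso comparison model.
#'
#' @param geno a [genotype_matrix()].
#' @param partition optional [marker_partition()]; defaults to singleton
#'   sets.  Columns inherit their marker's set as the penalty group.
#' @return An unstandardized `ngvs_design` (see [standardize()]).
#' @export
encode_additive <- function(geno, partition = NULL) {
  geno <- as_genotype_matrix(geno)
  p <- ncol(geno)
  partition <- default_partition(partition, p)
  values <- matrix(as.numeric(geno), nrow(geno), p)
  colnames(values) <- colnames(geno)
  new_design(values,
             marker = seq_len(p),
             set = partition$set_of,
             group = partition$set_of,
             coding = "additive")
}

#' Two-effect (additive + dominant) genotype encoding
#'
#' Each marker contributes two dummy regressors against the aa baseline:
#' an AA indicator and an Aa indicator.  The pair captures additive and
#' dominant effects and is always penalized within the same group, so a
#' locus enters or leaves the model as a unit.
#'
#' @inheritParams encode_additive
#' @return An unstandardized `ngvs_design` with `2p` columns.
#' @examples
#' g <- genotype_matrix(rbind(c(1, 0), c(-1, 1), c(0, -1)))
#' d <- encode_two_effect(g)
#' d$values
#' @export
encode_two_effect <- function(geno, partition = NULL) {
  geno <- as_genotype_matrix(geno)
  n <- nrow(geno); p <- ncol(geno)
  partition <- default_partition(partition, p)
  values <- matrix(0, n, 2L * p)
  values[, seq(1L, 2L * p, by = 2L)] <- as.numeric(geno == 1L)   # AA
  values[, seq(2L, 2L * p, by = 2L)] <- as.numeric(geno == 0L)   # Aa
  nm <- colnames(geno)
  colnames(values) <- as.vector(rbind(paste0(nm, ":AA"), paste0(nm, ":Aa")))
  marker <- rep(seq_len(p), each = 2L)
  new_design(values,
             marker = marker,
             set = partition$set_of[marker],
             group = partition$set_of[marker],
             coding = "two_effect")
}

# Reconstruct additive codes from a design (used by interaction builders).
additive_codes <- function(design, geno = NULL) {
  if (!is.null(geno)) return(matrix(as.numeric(as_genotype_matrix(geno)),
                                    nrow(geno)))
  v <- design$values
  p <- max(design$marker, na.rm = TRUE)
  out <- matrix(NA_real_, nrow(v), p)
  if (identical(design$coding, "additive")) {
    for (k in seq_len(p)) out[, k] <- v[, match(k, design$marker)]
  } else {
    for (k in seq_len(p)) {
      cols <- which(design$marker == k)
      aa <- v[, cols[1L]]; het <- v[, cols[2L]]
      out[, k] <- 2 * aa + het - 1   # AA -> 1, Aa -> 0, aa -> -1
    }
  }
  out
}
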