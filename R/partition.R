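#' Marker partition
#'
#' An ordered assignment of the `p` markers to `J` disjoint,
#' exhaustive marker sets.
#'
#' @param set_of integer vector, length `p`: the set index of each
#'   marker.  Set labels are renumbered to `1..J` in order of first
#'   appearance.
#' @return An object of class `ngvs_partition` with fields `set_of`,
#'   `sizes` and `n_sets`.
#' @export
marker_partition <- function(set_of) {
  set_of <- as.integer(factor(set_of, levels = unique(set_of)))
  sizes <- as.integer(table(factor(set_of, levels = seq_len(max(set_of)))))
  if (any(sizes < 1L)) stop("every marker set must contain at least one marker")
  structure(list(set_of = set_of, sizes = sizes, n_sets = max(set_of)),
            class = "ngvs_partition")
}

default_partition <- function(partition, p) {
  if (is.null(partition)) return(marker_partition(seq_len(p)))
  if (!inherits(partition, "ngvs_partition")) partition <- marker_partition(partition)
  if (length(partition$set_of) != p)
    stop("partition covers ", length(partition$set_of),
         " markers but the genotype matrix has ", p)
  partition
}

#' @export
print.ngvs_partition <- function(x, ...) {
  cat("Marker partition:", length(x$set_of), "markers in", x$n_sets,
      "sets (sizes", paste(range(x$sizes), collapse = "-"), ")\n")
  invisible(x)
}

#' Form marker sets
#'
#' Groups markers into disjoint sets by one of three rules:
#' `fixed_size` windows of `r` consecutive markers (a trailing smaller
#' set keeps the remainder when `r` does not divide `p`; `r = 1` gives
#' singleton sets, i.e. no grouping), `by_chromosome` (requires
#' chromosome labels on the genotype matrix), or `correlation_boundary`,
#' which cuts between adjacent markers wherever the absolute Pearson
#' correlation of their additive codes drops below `threshold`.
#'
#' @param geno a [genotype_matrix()].
#' @param method one of `"fixed_size"`, `"by_chromosome"`,
#'   `"correlation_boundary"`.
#' @param r window size for `fixed_size`.
#' @param threshold correlation cut for `correlation_boundary`.
#' @return A [marker_partition()].
#' @export
form_marker_sets <- function(geno,
                             method = c("fixed_size", "by_chromosome",
                                        "correlation_boundary"),
                             r = 1L, threshold = 0.5) {
  geno <- as_genotype_matrix(geno)
  method <- match.arg(method)
  p <- ncol(geno)
  set_of <- switch(method,
    fixed_size = {
      if (r < 1L) stop("r must be a positive integer")
      rep(seq_len(ceiling(p / r)), each = r)[seq_len(p)]
    },
    by_chromosome = {
      chrom <- attr(geno, "chrom")
      if (is.null(chrom))
        stop("method 'by_chromosome' requires chromosome labels on the genotype matrix")
      as.integer(factor(chrom, levels = unique(chrom)))
    },
    correlation_boundary = {
      if (p == 1L) 1L else {
        codes <- matrix(as.numeric(geno), nrow(geno))
        adj <- vapply(seq_len(p - 1L), function(k) {
          suppressWarnings(abs(cor(codes[, k], codes[, k + 1L])))
        }, numeric(1))
        adj[is.na(adj)] <- 0
        cumsum(c(1L, as.integer(adj < threshold)))
      }
    })
  marker_partition(set_of)
}

#' Read / write a marker partition as CSV
#'
#' Two columns: `marker`, `set_id`.  Markers are matched by name against
#' the genotype matrix order when `marker_names` is supplied.
#'
#' @param file path to the partition CSV.
#' @param marker_names optional character vector giving the marker order.
#' @return A [marker_partition()].
#' @export
read_partition <- function(file, marker_names = NULL) {
  d <- read.csv(file, check.names = FALSE)
  if (!is.null(marker_names)) {
    idx <- match(marker_names, d$marker)
    if (anyNA(idx)) stop("partition file is missing some markers")
    d <- d[idx, , drop = FALSE]
  }
  marker_partition(d$set_id)
}

#' @rdname read_partition
#' @param partition a [marker_partition()] to write.
#' @export
write_partition <- function(partition, file, marker_names = NULL) {
  p <- length(partition$set_of)
  if (is.null(marker_names)) marker_names <- paste0("M", seq_len(p))
  write.csv(data.frame(marker = marker_names, set_id = partition$set_of),
            file, row.names = FALSE)
  invisible(file)
}
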