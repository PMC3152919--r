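# Internal design-matrix container.
#
# A design is a plain list: `values` (numeric matrix), and per-column
# metadata vectors `marker` (marker index or NA for covariate/kernel
# columns), `set` (marker-set id or NA), `group` (penalty group id,
# 1..J).  After standardize() every column has mean zero and unit
# Euclidean norm, with the centering/scaling constants retained so
# coefficients and predictions can be mapped back to the original scale.

new_design <- function(values, marker, set, group, coding,
                       standardized = FALSE, center = NULL, scale = NULL) {
  stopifnot(ncol(values) == length(group))
  structure(list(values = values,
                 marker = marker,
                 set = set,
                 group = as.integer(group),
                 coding = coding,
                 standardized = standardized,
                 center = center,
                 scale = scale),
            class = "ngvs_design")
}

#' @export
print.ngvs_design <- function(x, ...) {
  cat("Design matrix:", nrow(x$values), "samples x", ncol(x$values),
      "columns in", length(unique(x$group)), "groups;",
      if (x$standardized) "standardized" else "unstandardized", "\n")
  invisible(x)
}

#' Standardize a design and center responses
#'
#' Columns are centered and then scaled to unit Euclidean norm (not unit
#' variance), which makes the group penalty scale-free; responses are
#' centered per trait so no intercept is needed.
#'
#' @param design an `ngvs_design` from an encoding or model-builder
#'   function.
#' @param responses optional numeric matrix (samples x traits) to center
#'   alongside the design.
#' @return A list with elements `design` (standardized, with `center`
#'   and `scale` stored), `responses` (centered, or `NULL`) and
#'   `response_center`.
#' @examples
#' g <- genotype_matrix(rbind(c(1, 0), c(-1, 1), c(0, -1), c(1, 1)))
#' s <- standardize(encode_additive(g))
#' colSums(s$design$values)            # ~0
#' colSums(s$design$values^2)          # ~1
#' @export
standardize <- function(design, responses = NULL) {
  v <- design$values
  ctr <- colMeans(v)
  v <- sweep(v, 2L, ctr, "-")
  nrm <- sqrt(colSums(v^2))
  bad <- which(nrm < 1e-10)
  if (length(bad) > 0L) {
    lbl <- colnames(design$values)[bad]
    if (is.null(lbl)) lbl <- bad
    stop("zero-variance (degenerate) column(s): ", paste(lbl, collapse = ", "))
  }
  v <- sweep(v, 2L, nrm, "/")
  out <- design
  out$values <- v
  out$standardized <- TRUE
  out$center <- ctr
  out$scale <- nrm
  rc <- NULL
  if (!is.null(responses)) {
    responses <- as.matrix(responses)
    rc <- colMeans(responses)
    responses <- sweep(responses, 2L, rc, "-")
  }
  list(design = out, responses = responses, response_center = rc)
}

# Column indices per group, as a list ordered by group id.
group_index <- function(group) {
  split(seq_along(group), group)
}

# Yuan-Lin weights: sqrt(number of columns in the group).
group_weights <- function(group) {
  sz <- table(factor(group, levels = sort(unique(group))))
  sqrt(as.numeric(sz))
}
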