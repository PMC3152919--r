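#' Trait co-expression network
#'
#' An undirected graph on `G` traits, used to build the Laplacian
#' smoothness penalty.  Self-loops and duplicate edges are rejected.
#' Traits of degree zero are allowed in the container (and flagged) but
#' are an error when the penalty operator is built: the smoothness term
#' requires every trait to have at least one neighbour.
#'
#' @param edges two-column matrix (or data.frame) of trait index pairs.
#' @param n_traits number of traits `G`.
#' @param trait_names optional trait labels.
#' @return An object of class `ngvs_network` with fields `edges`
#'   (each row `u < v`), `n_traits`, `degrees` and `n_edges`.
#' @export
trait_network <- function(edges, n_traits, trait_names = NULL) {
  edges <- as.matrix(edges)
  if (length(edges) == 0L) edges <- matrix(integer(0), 0L, 2L)
  storage.mode(edges) <- "integer"
  if (ncol(edges) != 2L) stop("edges must have two columns")
  if (any(edges < 1L | edges > n_traits)) stop("edge endpoint out of range")
  if (nrow(edges) > 0L) {
    if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
    edges <- cbind(pmin(edges[, 1L], edges[, 2L]),
                   pmax(edges[, 1L], edges[, 2L]))
    if (anyDuplicated(paste(edges[, 1L], edges[, 2L])))
      stop("duplicate edges")
  }
  degrees <- tabulate(edges, nbins = n_traits)
  structure(list(edges = edges, n_traits = as.integer(n_traits),
                 degrees = degrees, n_edges = nrow(edges),
                 trait_names = trait_names),
            class = "ngvs_network")
}

#' @export
print.ngvs_network <- function(x, ...) {
  cat("Trait network:", x$n_traits, "traits,", x$n_edges, "edges")
  z <- which(x$degrees == 0L)
  if (length(z) > 0L) cat("; degree-0 traits:", paste(z, collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Fully connected trait network
#'
#' @param n_traits number of traits.
#' @return A [trait_network()] with all `G(G-1)/2` edges.
#' @export
full_network <- function(n_traits) {
  e <- t(utils::combn(n_traits, 2L))
  trait_network(e, n_traits)
}

#' Build a co-expression network from trait correlations
#'
#' Links traits `u ~ v` whenever the absolute Pearson correlation of
#' their expression vectors is at least `cutoff`.  When the marker count
#' `p` is supplied, the saturation-lifting feasibility condition
#' `E > G(p - n)/p` is evaluated: with at least that many edges the
#' augmented problem has more rows than coefficients, so selection is
#' not capped at `G n` variables.  Degree-zero traits are reported via
#' the `zero_degree` attribute; lower the cutoff (or enlarge the
#' network) before fitting if any are present.
#'
#' @param expr numeric matrix, samples x traits.
#' @param cutoff correlation threshold in `(0, 1]`.
#' @param p optional marker count used for the feasibility check.
#' @return A [trait_network()] with attributes `feasible` (logical or
#'   `NA` when `p` is missing) and `zero_degree` (trait indices).
#' @examples
#' set.seed(1)
#' z <- rnorm(30)
#' expr <- cbind(z + rnorm(30, sd = .1), z + rnorm(30, sd = .1), rnorm(30))
#' net <- build_network(expr, cutoff = 0.8)
#' attr(net, "zero_degree")
#' @export
build_network <- function(expr, cutoff, p = NULL) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 2L) stop("need at least 2 traits")
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff > 1)
    stop("cutoff must lie in (0, 1]")
  cm <- abs(cor(expr))
  G <- ncol(expr)
  idx <- which(upper.tri(cm) & cm >= cutoff, arr.ind = TRUE)
  net <- trait_network(idx, G, trait_names = colnames(expr))
  feasible <- NA
  if (!is.null(p)) {
    n <- nrow(expr)
    feasible <- net$n_edges > G * (p - n) / p
  }
  attr(net, "feasible") <- feasible
  attr(net, "zero_degree") <- which(net$degrees == 0L)
  net
}

#' Read / write a trait network edge list as CSV
#'
#' Columns `trait_u`, `trait_v` (indices or names resolved against
#' `trait_names`).
#'
#' @param file path to the edge-list CSV.
#' @param n_traits number of traits.
#' @param trait_names optional trait labels for name resolution.
#' @return A [trait_network()].
#' @export
read_network <- function(file, n_traits, trait_names = NULL) {
  d <- read.csv(file, check.names = FALSE)
  u <- d[[1L]]; v <- d[[2L]]
  if (!is.null(trait_names) && !is.numeric(u)) {
    u <- match(u, trait_names); v <- match(v, trait_names)
    if (anyNA(u) || anyNA(v)) stop("unknown trait name in the edge list")
  }
  trait_network(cbind(u, v), n_traits, trait_names)
}

#' @rdname read_network
#' @param net a [trait_network()] to write.
#' @export
write_network <- function(net, file) {
  write.csv(data.frame(trait_u = net$edges[, 1L], trait_v = net$edges[, 2L]),
            file, row.names = FALSE)
  invisible(file)
}
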