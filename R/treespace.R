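## Dissimilarities and summary statistics on registered trees.  Because all
## registered trees share one reference topology, they occupy a single
## orthant of tree space and ordinary Euclidean geometry applies.

#' Squared-difference dissimilarity between registered vectors
#'
#' `tree_dissimilarity()` is the squared Euclidean form
#' `(z_i - z_j)' (z_i - z_j)`; `tree_distance()` is its square root, the
#' Euclidean distance used by Ward clustering and classical MDS (which
#' re-squares it when double-centering).
#'
#' @param zi,zj equal-length numeric vectors (or `registered_tree` objects).
#' @return a single non-negative number.
#' @export
tree_dissimilarity <- function(zi, zj) {
  zi <- as_z(zi); zj <- as_z(zj)
  if (length(zi) != length(zj))
    stop("registered vectors differ in length (", length(zi), " vs ",
         length(zj), "); register them against one shared reference")
  sum((zi - zj)^2)
}

#' @rdname tree_dissimilarity
#' @export
tree_distance <- function(zi, zj) sqrt(tree_dissimilarity(zi, zj))

as_z <- function(z) {
  if (inherits(z, "registered_tree")) z$z else as.numeric(z)
}

#' Pairwise Euclidean distance matrix of a registered cohort
#'
#' @param x a `registered_set` (from [register_set()]) or a numeric matrix
#'   of registered row vectors.
#' @return a symmetric n x n matrix with zero diagonal and row/column
#'   labels; attribute `metric` is `"euclidean"`.
#' @export
distance_matrix <- function(x) {
  Z <- get_Z(x)
  if (nrow(Z) < 2) stop("need at least two trees for a distance matrix")
  D <- as.matrix(stats::dist(Z, method = "euclidean"))
  attr(D, "metric") <- "euclidean"
  D
}

#' Mean registered tree
#'
#' Coordinate-wise average of the registered vectors; rendered against the
#' reference edge indexing it is the average edge-length profile of a
#' cluster.  The mean of normalized vectors still sums to one.
#'
#' @param x a `registered_set` or numeric matrix of registered vectors.
#' @return a numeric vector of length `m`.
#' @export
tree_mean <- function(x) {
  Z <- get_Z(x)
  if (!nrow(Z)) stop("empty tree set")
  colMeans(Z)
}

#' Tree variance of a registered cohort
#'
#' Population variance `1/n * sum_i (z_i - mu)'(z_i - mu)` about the mean
#' registered vector, i.e. the average squared-difference dissimilarity to
#' the tree mean.
#'
#' @inheritParams tree_mean
#' @return a single non-negative number.
#' @export
tree_variance <- function(x) {
  Z <- get_Z(x)
  if (!nrow(Z)) stop("empty tree set")
  mu <- colMeans(Z)
  mean(rowSums(sweep(Z, 2, mu)^2))
}

#' Export a distance matrix as labeled square TSV
#'
#' @param D a square distance matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(D, path) {
  df <- data.frame(tree = rownames(D), D, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
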