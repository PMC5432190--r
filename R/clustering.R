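## Hierarchical clustering of registered trees with automatic selection of
## the number of clusters by the gap statistic.

#' Ward clustering of a distance matrix
#'
#' Ward linkage on Euclidean distances (`ward.D2`, i.e. squared-distance
#' updates), cut to `K` groups.  Deterministic for fixed input.
#'
#' @param S a symmetric distance matrix (e.g. from [distance_matrix()]) or
#'   a [stats::dist] object.
#' @param K number of clusters, `1 <= K <= n`.
#' @return integer cluster labels `1..K`, named by tree.
#' @export
ward_cluster <- function(S, K) {
  d <- if (inherits(S, "dist")) S else stats::as.dist(S)
  n <- attr(d, "Size")
  if (!is.numeric(K) || length(K) != 1 || K < 1 || K > n || K != round(K))
    stop("K must be an integer in 1..", n)
  stats::cutree(stats::hclust(d, method = "ward.D2"), k = as.integer(K))
}

#' Choose the number of clusters with the gap statistic
#'
#' Compares the observed within-cluster dispersion `W_k` (under Ward
#' clustering) with its expectation under `n_boot` reference datasets drawn
#' uniformly over the per-coordinate range of the data, and returns the
#' smallest `k` whose gap is within one simulation standard error of the
#' next gap (the 1-SE rule).  Implemented on top of [cluster::clusGap()]
#' with `spaceH0 = "original"` and `d.power = 2`.
#'
#' @param x a `registered_set` or numeric matrix of registered vectors.
#' @param k_max largest candidate `K`; default `min(n - 1, 10)`.
#' @param n_boot number of reference datasets (at least 10).
#' @param seed optional integer seed for the reference draws.
#' @return a list with `K` (chosen number of clusters) and `gap_trace`, a
#'   tibble with one row per candidate `k` (`logW`, `E_logW`, `gap`, `SE`).
#' @export
gap_select_k <- function(x, k_max = NULL, n_boot = 100, seed = NULL) {
  Z <- get_Z(x)
  n <- nrow(Z)
  if (is.null(k_max)) k_max <- min(n - 1L, 10L)
  if (k_max < 2 || k_max >= n)
    stop("k_max must satisfy 2 <= k_max < n")
  if (n_boot < 10) stop("n_boot must be at least 10")
  if (all(apply(Z, 2, function(col) diff(range(col)) == 0))) {
    warning("all registered vectors are identical; returning K = 1")
    return(list(K = 1L, gap_trace = NULL))
  }
  fc <- function(x, k) list(cluster = ward_cluster(stats::dist(x), k))
  run <- function() cluster::clusGap(Z, FUNcluster = fc, K.max = k_max,
                                     B = n_boot, d.power = 2,
                                     spaceH0 = "original", verbose = FALSE)
  g <- if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
  tab <- g$Tab
  K <- cluster::maxSE(tab[, "gap"], tab[, "SE.sim"], method = "Tibs2001SEmax")
  trace <- tibble::tibble(k = seq_len(nrow(tab)),
                          logW = tab[, "logW"], E_logW = tab[, "E.logW"],
                          gap = tab[, "gap"], SE = tab[, "SE.sim"])
  list(K = as.integer(K), gap_trace = trace)
}

#' Cluster a registered cohort of trees
#'
#' Runs Ward clustering on the pairwise Euclidean distances of the
#' registered vectors; when `K` is not given it is selected automatically
#' with [gap_select_k()].
#'
#' @param x a `registered_set` (from [register_set()]) or numeric matrix.
#' @param K optional fixed number of clusters.
#' @param k_max,n_boot,seed passed to [gap_select_k()] when `K` is absent.
#' @return an object of class `clone_clusters`: fields `labels` (named
#'   integer vector), `K`, `hclust` (the merge history), `gap_trace`
#'   (tibble or `NULL`), `seed`.
#' @export
cluster_trees <- function(x, K = NULL, k_max = NULL, n_boot = 100,
                          seed = NULL) {
  Z <- get_Z(x)
  D <- distance_matrix(Z)
  gap <- NULL
  if (is.null(K)) {
    sel <- gap_select_k(Z, k_max = k_max, n_boot = n_boot, seed = seed)
    K <- sel$K
    gap <- sel$gap_trace
  }
  hc <- stats::hclust(stats::as.dist(D), method = "ward.D2")
  labels <- stats::cutree(hc, k = K)
  names(labels) <- rownames(Z)
  structure(list(labels = labels, K = as.integer(K), hclust = hc,
                 gap_trace = gap, seed = seed, n = nrow(Z)),
            class = "clone_clusters")
}

#' @export
print.clone_clusters <- function(x, ...) {
  cat("<clone_clusters> ", x$n, " trees in ", x$K, " clusters",
      if (!is.null(x$gap_trace)) " (gap-selected)" else " (K fixed)",
      "\n", sep = "")
  print(table(cluster = x$labels))
  invisible(x)
}

#' Tidiers for cloneclust result objects
#'
#' `tidy()` returns per-observation rows (cluster assignments, registered
#' vectors, MDS coordinates); `glance()` returns a one-row model summary.
#'
#' @param x a result object.
#' @param ... unused.
#' @name tidy-cloneclust
NULL

#' @rdname tidy-cloneclust
#' @export
tidy.clone_clusters <- function(x, ...) {
  tibble::tibble(tree = names(x$labels), cluster = unname(x$labels))
}

#' @rdname tidy-cloneclust
#' @export
glance.clone_clusters <- function(x, ...) {
  tibble::tibble(n = x$n, K = x$K,
                 gap_selected = !is.null(x$gap_trace),
                 gap = if (!is.null(x$gap_trace))
                   x$gap_trace$gap[x$K] else NA_real_)
}

#' Serialize a Ward dendrogram as Newick with merge heights
#'
#' @param x a `clone_clusters` object.
#' @return a Newick string.
#' @export
dendrogram_newick <- function(x) {
  stopifnot(inherits(x, "clone_clusters"))
  ape::write.tree(ape::as.phylo(x$hclust))
}

#' Write cluster assignments as two-column TSV
#'
#' @param x a `clone_clusters` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clusters_tsv <- function(x, path) {
  utils::write.table(tidy.clone_clusters(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
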