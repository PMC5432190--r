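## Cluster interpretation: classical MDS embedding of the tree distances
## and sub-clonal diversity (lineage-through-time style) curves.

#' Classical MDS embedding of a tree distance matrix
#'
#' Double-centers the element-wise squared distance matrix
#' (`B = -1/2 H S^2 H`), eigendecomposes, and scales the top eigenvectors
#' by the square roots of their eigenvalues.  Negative eigenvalues are
#' clamped to zero and their axes dropped; if fewer than `dim` positive
#' eigenvalues exist the coordinates are zero-padded with a warning.  For
#' registered trees the distances are exactly Euclidean, so with enough
#' dimensions the embedding reproduces them to machine precision.
#'
#' @param S symmetric distance matrix with zero diagonal (from
#'   [distance_matrix()]), or a `registered_set`.
#' @param dim embedding dimension (default 2, for visualization).
#' @return an object of class `clone_mds`: `coordinates` (tibble with
#'   `tree`, `dim1`, ..), `eigenvalues` (descending), `goodness` (fraction
#'   of positive-eigenvalue mass captured), `dim`.
#' @export
cmds_embed <- function(S, dim = 2) {
  if (inherits(S, "registered_set")) S <- distance_matrix(S)
  if (!isSymmetric(unname(S)) || any(abs(diag(S)) > 1e-12))
    stop("S must be a symmetric distance matrix with zero diagonal")
  n <- nrow(S)
  if (dim > n - 1) stop("dim must be at most n - 1")
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(S), k = dim,
                                          eig = TRUE))
  eig <- sort(fit$eig, decreasing = TRUE)
  # axes whose eigenvalue is zero up to numerical noise carry no signal
  tol <- max(eig, 0) * 1e-9
  n_pos <- sum(eig > tol)
  pts <- matrix(0, n, dim)
  keep <- seq_len(min(dim, n_pos, ncol(fit$points)))
  pts[, keep] <- fit$points[, keep, drop = FALSE]
  if (n_pos < dim)
    warning("only ", n_pos, " positive eigenvalue(s); padding the ",
            "remaining coordinate(s) with zeros")
  colnames(pts) <- paste0("dim", seq_len(dim))
  labs <- rownames(S)
  if (is.null(labs)) labs <- paste0("tree", seq_len(n))
  goodness <- sum(pmax(eig[seq_len(min(dim, length(eig)))], 0)) /
    sum(pmax(eig, 0))
  structure(list(
    coordinates = tibble::add_column(tibble::as_tibble(pts), tree = labs,
                                     .before = 1),
    eigenvalues = eig, goodness = goodness, dim = dim),
    class = "clone_mds")
}

#' @export
print.clone_mds <- function(x, ...) {
  cat("<clone_mds> ", nrow(x$coordinates), " trees in ", x$dim,
      " dimensions; goodness of fit ", sprintf("%.3f", x$goodness),
      "\n", sep = "")
  invisible(x)
}

#' @rdname tidy-cloneclust
#' @export
tidy.clone_mds <- function(x, ...) x$coordinates

#' @rdname tidy-cloneclust
#' @export
glance.clone_mds <- function(x, ...) {
  tibble::tibble(n = nrow(x$coordinates), dim = x$dim,
                 goodness = x$goodness,
                 n_positive_eig = sum(x$eigenvalues > 1e-12))
}

#' Plot an MDS embedding
#'
#' @param object a `clone_mds` object.
#' @param clusters optional cluster labels (or a `clone_clusters` object)
#'   used to color points.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.clone_mds <- function(object, clusters = NULL, ...) {
  df <- object$coordinates
  if (inherits(clusters, "clone_clusters")) clusters <- clusters$labels
  p <- if (is.null(clusters)) {
    ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2))
  } else {
    df$cluster <- factor(clusters)
    ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2,
                                     colour = .data$cluster))
  }
  p + ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "MDS 1", y = "MDS 2") +
    ggplot2::theme_minimal()
}

## ---- sub-clonal diversity curves ------------------------------------------

#' Sub-clonal diversity curve
#'
#' A lineage-through-time style step function of the number of extant
#' clones (`y`, counting the normal cell) against the fraction of
#' accumulated SSNVs (`x`).  A clone is born once the SSNVs on its whole
#' root path have accumulated, so each non-root node contributes a step at
#' its normalized root distance: `y(x) = 1 + #\{nodes with distance <= x\}`.
#' At `x = 0` only the normal cell exists (`y = 1`); the founder appears at
#' the trunk fraction.  Zero-length spine nodes inserted by binarization
#' are encoding artifacts and are not counted.
#'
#' @param x a [clone_tree()] with normalized edge lengths (unnormalized
#'   trees are normalized internally with a warning) or a normalized
#'   `registered_tree`.
#' @param ... unused.
#' @return a tibble of breakpoints (class `diversity_curve`) with columns
#'   `x` and `y`, starting at `(0, 1)`; attributes `trunk_fraction` and
#'   `n_clones`.
#' @export
diversity_curve <- function(x, ...) UseMethod("diversity_curve")

#' @rdname diversity_curve
#' @export
diversity_curve.clone_tree <- function(x, ...) {
  tot <- sum(x$edge_length, na.rm = TRUE)
  if (abs(tot - 1) > 1e-8) {
    warning("edge lengths do not sum to 1; normalizing internally")
    x$edge_length <- x$edge_length / tot
  }
  dists <- ct_root_distances(x)
  keep <- !is.na(x$parent) & !x$inserted
  founder <- which(x$parent == ct_root(x))
  new_diversity_curve(dists[keep], trunk_fraction = dists[founder[1]],
                      label = x$label)
}

#' @rdname diversity_curve
#' @export
diversity_curve.registered_tree <- function(x, ...) {
  if (!x$normalized) {
    warning("registered tree is not normalized; normalizing internally")
    x <- normalize_lengths(x)
  }
  m <- length(x$z)
  dist_edge <- rep(NA_real_, m)
  for (k in x$mapped) {  # mapped is sorted, parents precede children
    p <- ref_parent_edge(k)
    dist_edge[k] <- x$z[k] + if (p == 0L) 0 else dist_edge[p]
  }
  birth <- dist_edge[x$mapped][!x$inserted]
  new_diversity_curve(birth, trunk_fraction = dist_edge[1],
                      label = x$label)
}

new_diversity_curve <- function(birth_times, trunk_fraction, label = "") {
  birth_times <- round(birth_times, 12)  # merge float ties into one step
  steps <- sort(unique(birth_times))
  counts <- as.integer(table(factor(birth_times, levels = steps)))
  out <- tibble::tibble(x = c(0, steps), y = c(1L, 1L + cumsum(counts)))
  class(out) <- c("diversity_curve", class(out))
  attr(out, "trunk_fraction") <- trunk_fraction
  attr(out, "n_clones") <- length(birth_times)
  attr(out, "label") <- label
  out
}

#' Evaluate a diversity curve at given SSNV fractions
#'
#' Right-continuous step evaluation: a clone whose root path completes
#' exactly at `x` is counted at `x`.
#'
#' @param curve a [diversity_curve()].
#' @param x numeric vector of accumulated-SSNV fractions in `[0, 1]`.
#' @return integer vector of clone counts.
#' @export
diversity_at <- function(curve, x) {
  stopifnot(inherits(curve, "diversity_curve"))
  vapply(x, function(xi) {
    if (xi < 0) stop("fractions must be non-negative")
    max(curve$y[curve$x <= xi + 1e-12])
  }, numeric(1))
}

#' Per-cluster diversity summary
#'
#' Groups per-tree diversity curves by cluster and reports each cluster's
#' size and first-expansion statistic: the median, across member trees, of
#' the trunk fraction (the `x` at which the curve first jumps from 1 to 2,
#' i.e. where the founder cell is established).
#'
#' @param curves a list of [diversity_curve()] objects, one per tree.
#' @param labels cluster labels aligned with `curves` (or a
#'   `clone_clusters` object).
#' @return a tibble with columns `cluster`, `n_trees`, `first_expansion`;
#'   per-tree trunk fractions are attached as attribute `trees` (a tibble
#'   `tree`, `cluster`, `trunk_fraction`).
#' @export
cluster_diversity_summary <- function(curves, labels) {
  if (inherits(labels, "clone_clusters")) labels <- labels$labels
  if (length(curves) != length(labels))
    stop("curves and labels lengths differ (", length(curves), " vs ",
         length(labels), ")")
  tf <- vapply(curves, function(cv) attr(cv, "trunk_fraction"), numeric(1))
  labs <- vapply(seq_along(curves), function(i) {
    l <- attr(curves[[i]], "label")
    if (is.null(l) || !nzchar(l)) paste0("tree", i) else l
  }, character(1))
  per_tree <- tibble::tibble(tree = labs, cluster = labels,
                             trunk_fraction = tf)
  out <- dplyr::summarise(dplyr::group_by(per_tree, .data$cluster),
                          n_trees = dplyr::n(),
                          first_expansion = stats::median(.data$trunk_fraction),
                          .groups = "drop")
  attr(out, "trees") <- per_tree
  out
}

#' Step plot of diversity curves
#'
#' @param curves a list of [diversity_curve()] objects (or a single one).
#' @param labels optional cluster labels (or `clone_clusters`) to color
#'   curves by cluster.
#' @return a ggplot.
#' @export
plot_diversity_curves <- function(curves, labels = NULL) {
  if (inherits(curves, "diversity_curve")) curves <- list(curves)
  if (inherits(labels, "clone_clusters")) labels <- labels$labels
  dfs <- lapply(seq_along(curves), function(i) {
    cv <- curves[[i]]
    # extend each curve to x = 1 so steps render fully
    lab <- attr(cv, "label")
    data.frame(tree = if (is.null(lab) || !nzchar(lab)) paste0("tree", i)
               else lab,
               x = c(cv$x, 1), y = c(cv$y, max(cv$y)),
               cluster = if (is.null(labels)) NA else labels[i],
               row.names = NULL)
  })
  df <- do.call(rbind, dfs)
  aes <- if (is.null(labels)) {
    ggplot2::aes(.data$x, .data$y, group = .data$tree)
  } else {
    df$cluster <- factor(df$cluster)
    ggplot2::aes(.data$x, .data$y, group = .data$tree,
                 colour = .data$cluster)
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_step(alpha = 0.8) +
    ggplot2::labs(x = "fraction of accumulated SSNVs",
                  y = "number of clones") +
    ggplot2::theme_minimal()
}

#' @rdname plot_diversity_curves
#' @param object a `diversity_curve`.
#' @param ... unused.
#' @export
autoplot.diversity_curve <- function(object, ...) {
  plot_diversity_curves(list(object))
}
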