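## Registration: mapping observed trees onto a common complete bifurcated
## reference tree and representing each tree as a fixed-length edge vector.

#' Build the reference tree
#'
#' The reference is the complete bifurcated tree of depth `d_max`, deep
#' enough to hold every (binarized) tree in the cohort.  Its
#' `m = 2 * (2^d_max - 1)` edges are numbered in level order: edges 1 and 2
#' leave the root, and edge `k` has child edges `2k + 1` and `2k + 2`.
#'
#' @param d_max positive integer depth.
#' @return an object of class `reference_tree` with fields `depth` and `m`.
#' @export
build_reference <- function(d_max) {
  if (!is.numeric(d_max) || length(d_max) != 1 || d_max < 1 ||
      d_max != round(d_max))
    stop("d_max must be a positive integer")
  d_max <- as.integer(d_max)
  structure(list(depth = d_max, m = 2L * (2L^d_max - 1L)),
            class = "reference_tree")
}

#' @export
print.reference_tree <- function(x, ...) {
  cat("<reference_tree> depth ", x$depth, ", ", x$m, " edges\n", sep = "")
  invisible(x)
}

# parent edge index under level-order numbering; 0 for the two root edges
ref_parent_edge <- function(k) (k - 1L) %/% 2L

## ---- canonical child ordering ---------------------------------------------

# Per-node sort keys, computed bottom-up:
#   1. subtree depth (edges below the node), descending
#   2. connecting edge length, descending
#   3. subtree total edge length (including the connecting edge), descending
#   4. canonical subtree string, descending (total-order tie break)
canonical_order_keys <- function(x) {
  n <- ct_n_nodes(x)
  ch <- ct_children(x)
  len <- x$edge_length
  len[is.na(len)] <- 0
  depth_below <- integer(n)
  total_len <- numeric(n)
  canon <- character(n)
  ord <- order(ct_node_depths(x), decreasing = TRUE)  # children first
  for (v in ord) {
    kids <- ch[[v]]
    el <- x$edge_length[v]
    if (is.na(el)) el <- 0
    if (!length(kids)) {
      depth_below[v] <- 0L
      total_len[v] <- el
      canon[v] <- sprintf("%.12g", el)
    } else {
      depth_below[v] <- 1L + max(depth_below[kids])
      total_len[v] <- el + sum(total_len[kids])
      ki <- kids[canonical_order_idx(depth_below[kids], len[kids],
                                     total_len[kids], canon[kids])]
      canon[v] <- paste0("(", paste(canon[ki], collapse = ","), ")",
                         sprintf("%.12g", el))
    }
  }
  list(depth_below = depth_below, len = len, total_len = total_len,
       canon = canon)
}

canonical_order_idx <- function(depth, len, total, canon) {
  order(depth, len, total, canon, method = "radix",
        decreasing = c(TRUE, TRUE, TRUE, TRUE))
}

# permutation of `kids` (node indices) into canonical order
canonical_order <- function(keys, kids) {
  if (length(kids) < 2) return(seq_along(kids))
  canonical_order_idx(keys$depth_below[kids], keys$len[kids],
                      keys$total_len[kids], keys$canon[kids])
}

#' Canonical ordering of a node's children
#'
#' Children are ranked by subtree depth (deepest first), then by the length
#' of the connecting edge (longest first), then by subtree total edge
#' length, then by a canonical subtree string; ties beyond that keep input
#' order (the sort is stable).  The first two keys follow the mapping rule
#' of the registration: sub-trees are mapped beginning with the largest
#' depths and, at equal depth, the largest edge lengths.  The extra keys
#' only make the order total, so registration is a deterministic function
#' of the tree.
#'
#' @param x a [clone_tree()].
#' @param node node index whose children are ordered.
#' @return integer vector of child node indices, canonically ordered.
#' @export
canonical_child_order <- function(x, node) {
  keys <- canonical_order_keys(x)
  kids <- ct_children(x)[[node]]
  kids[canonical_order(keys, kids)]
}

## ---- registration ----------------------------------------------------------

#' Register a binarized tree onto a reference tree
#'
#' The trunk maps to reference edge 1 (the sibling root slot stays
#' degenerate); below each mapped edge, the canonically first child takes
#' the lower-index reference child slot.  Unvisited reference edges receive
#' length zero ("degenerated" edges).
#'
#' @param x a binary [clone_tree()] (see [binarize_multifurcations()]).
#' @param ref a [build_reference()] object at least as deep as `x`.
#' @return an object of class `registered_tree`: fields `z` (length-`m`
#'   edge-length vector), `mapped` (reference indices of mapped edges),
#'   `inserted` (logical along `mapped`, marking binarization spine edges),
#'   `depth`, `label`, `normalized`.
#' @export
register <- function(x, ref) {
  stopifnot(inherits(ref, "reference_tree"))
  if (!is_binary_tree(x))
    stop("tree must be binarized first; see binarize_multifurcations()")
  keys <- canonical_order_keys(x)
  ch <- ct_children(x)
  m <- ref$m
  z <- numeric(m)
  mapped <- integer(0)
  ins <- logical(0)
  assign_edge <- function(v, k) {
    if (k > m)
      stop("tree '", x$label, "' is deeper than the reference (depth ",
           ref$depth, "); rebuild the reference with a larger d_max")
    z[k] <<- x$edge_length[v]
    mapped[length(mapped) + 1L] <<- k
    ins[length(ins) + 1L] <<- x$inserted[v]
    kids <- ch[[v]]
    kids <- kids[canonical_order(keys, kids)]
    for (i in seq_along(kids)) assign_edge(kids[i], 2L * k + i)
  }
  founder <- ch[[ct_root(x)]][1]
  assign_edge(founder, 1L)
  o <- order(mapped)
  structure(list(z = z, mapped = mapped[o], inserted = ins[o],
                 depth = ref$depth, label = x$label, normalized = FALSE),
            class = "registered_tree")
}

#' @export
print.registered_tree <- function(x, ...) {
  cat("<registered_tree> ", if (nzchar(x$label)) x$label else "(unlabeled)",
      ": ", length(x$mapped), "/", length(x$z), " edges mapped, ",
      if (x$normalized) "normalized" else "raw SSNV counts", "\n", sep = "")
  invisible(x)
}

#' Normalize registered edge lengths
#'
#' Divides every edge length by the tree's total SSNV count so that the
#' vector sums to one; this removes between-patient differences in the
#' number of detected SSNVs.  Degenerate edges stay zero.  Idempotent.
#'
#' @param rt a `registered_tree`.
#' @return the normalized `registered_tree`.
#' @export
normalize_lengths <- function(rt) {
  stopifnot(inherits(rt, "registered_tree"))
  tot <- sum(rt$z)
  if (tot <= 0) stop("cannot normalize: total edge length is zero")
  rt$z <- rt$z / tot
  rt$normalized <- TRUE
  rt
}

#' Register a cohort of trees into a shared matrix
#'
#' Binarizes every tree, computes the cohort maximum depth (after
#' binarization), builds one shared reference, registers every tree onto
#' it, and normalizes.  Rows keep the input order.
#'
#' @param trees a [clone_tree()] or list thereof (e.g. from
#'   [read_clone_trees()] or [generate_design()]).
#' @param labels optional row labels (defaults to tree labels).
#' @return an object of class `registered_set`: fields `Z` (n x m matrix,
#'   rows summing to 1), `depth`, `reference`, `trees` (the per-tree
#'   `registered_tree` objects), `labels`.
#' @export
register_set <- function(trees, labels = NULL) {
  trees <- as_tree_list(trees)
  labs <- if (is.null(labels)) tree_labels(trees) else as.character(labels)
  if (length(labs) != length(trees))
    stop("labels length does not match the number of trees")
  btrees <- vector("list", length(trees))
  for (i in seq_along(trees)) {
    btrees[[i]] <- tryCatch(binarize_multifurcations(trees[[i]]),
      error = function(e) stop("tree '", labs[i], "': ",
                               conditionMessage(e), call. = FALSE))
    btrees[[i]]$label <- labs[i]
  }
  d_max <- max(vapply(btrees, function(t) max(as.integer(tip_depths(t))),
                      integer(1)))
  ref <- build_reference(d_max)
  rts <- vector("list", length(btrees))
  for (i in seq_along(btrees)) {
    rts[[i]] <- tryCatch(normalize_lengths(register(btrees[[i]], ref)),
      error = function(e) stop("tree '", labs[i], "': ",
                               conditionMessage(e), call. = FALSE))
  }
  Z <- do.call(rbind, lapply(rts, function(r) r$z))
  rownames(Z) <- labs
  colnames(Z) <- paste0("e", seq_len(ref$m))
  structure(list(Z = Z, depth = d_max, reference = ref, trees = rts,
                 labels = labs),
            class = "registered_set")
}

#' @export
print.registered_set <- function(x, ...) {
  cat("<registered_set> ", nrow(x$Z), " trees x ", ncol(x$Z),
      " reference edges (depth ", x$depth, ")\n", sep = "")
  invisible(x)
}

#' @rdname tidy-cloneclust
#' @export
tidy.registered_set <- function(x, ...) {
  out <- tibble::as_tibble(x$Z)
  tibble::add_column(out, tree = x$labels, .before = 1)
}

get_Z <- function(x) {
  if (inherits(x, "registered_set")) return(x$Z)
  if (is.matrix(x) && is.numeric(x)) return(x)
  stop("expected a registered_set or a numeric matrix of registered vectors")
}

#' Export a registered matrix as TSV
#'
#' Writes the trees-by-edges matrix with a `tree` label column, plus a
#' sidecar `<path>.meta` key-value file recording the reference depth and
#' edge count.
#'
#' @param x a `registered_set`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_registered_tsv <- function(x, path) {
  stopifnot(inherits(x, "registered_set"))
  df <- data.frame(tree = x$labels, x$Z, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- c(paste0("reference_depth\t", x$depth),
            paste0("reference_edges\t", x$reference$m),
            paste0("n_trees\t", nrow(x$Z)))
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}
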