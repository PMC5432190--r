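#' Rooted cancer evolutionary trees
#'
#' A `clone_tree` is a rooted tree in which the root represents the normal
#' cell, the root's single child represents the founder clone, every further
#' node is a sub-clone, and each edge length counts the somatic single
#' nucleotide variants (SSNVs) newly acquired by the child clone.  The edge
#' from the normal cell to the founder is the *trunk*.
#'
#' Internally a tree is stored as parallel vectors over nodes `1..n`:
#' `parent` (integer, `NA` at the root), `edge_length` (non-negative double,
#' `NA` at the root), `name` (node names), and `inserted` (logical; `TRUE`
#' only for zero-length spine nodes introduced by
#' [binarize_multifurcations()]).
#'
#' @param parent integer vector of parent node indices, `NA` for the root.
#' @param edge_length numeric vector of SSNV counts on the edge from each
#'   node's parent, `NA` for the root.  Non-negative; fractional values are
#'   accepted (normalization produces fractions anyway).
#' @param name character vector of node names.
#' @param label free-text sample label for the whole tree.
#' @param inserted logical vector marking binarization artifacts.
#'
#' @return An object of class `clone_tree`.
#' @seealso [parse_newick()], [binarize_multifurcations()], [register_set()]
#' @export
clone_tree <- function(parent, edge_length, name = NULL, label = "",
                       inserted = NULL) {
  n <- length(parent)
  if (is.null(name)) name <- paste0("n", seq_len(n))
  if (is.null(inserted)) inserted <- rep(FALSE, n)
  x <- structure(
    list(parent = as.integer(parent),
         edge_length = as.numeric(edge_length),
         name = as.character(name),
         label = as.character(label)[1],
         inserted = as.logical(inserted)),
    class = "clone_tree")
  validate_clone_tree(x)
}

#' Validate a clone tree
#'
#' Checks the structural invariants: a unique root with exactly one child
#' (the founder; the trunk convention), connectedness and acyclicity,
#' non-negative edge lengths with a positive total, and at least two nodes.
#'
#' @param x a [clone_tree()].
#' @return `x`, invisibly-checked (returned unchanged).
#' @export
validate_clone_tree <- function(x) {
  n <- length(x$parent)
  if (n < 2) stop("a clone tree needs at least a root and a founder node")
  root <- which(is.na(x$parent))
  if (length(root) != 1)
    stop("tree must have exactly one root, found ", length(root))
  if (sum(x$parent == root, na.rm = TRUE) != 1)
    stop("the root (normal cell) must have exactly one child (the founder); ",
         "got ", sum(x$parent == root, na.rm = TRUE))
  bad <- which(!is.na(x$parent) & (x$parent < 1 | x$parent > n))
  if (length(bad)) stop("parent index out of range for node ", bad[1])
  # connectivity + acyclicity: every node must reach the root
  for (v in seq_len(n)) {
    seen <- 0L
    u <- v
    while (!is.na(x$parent[u])) {
      u <- x$parent[u]
      seen <- seen + 1L
      if (seen > n) stop("cycle detected involving node ", v)
    }
    if (u != root) stop("node ", v, " is disconnected from the root")
  }
  len <- x$edge_length[-root]
  if (anyNA(len)) stop("non-root nodes must carry an edge length")
  if (any(len < 0)) stop("negative edge length on node ",
                         setdiff(which(x$edge_length < 0), root)[1])
  if (sum(len) <= 0) stop("total edge length must be positive")
  x
}

ct_root <- function(x) which(is.na(x$parent))

ct_n_nodes <- function(x) length(x$parent)

# children of every node, as a list indexed by node
ct_children <- function(x) {
  n <- ct_n_nodes(x)
  ch <- vector("list", n)
  for (v in seq_len(n)) ch[[v]] <- integer(0)
  for (v in seq_len(n)) {
    p <- x$parent[v]
    if (!is.na(p)) ch[[p]] <- c(ch[[p]], v)
  }
  ch
}

ct_leaves <- function(x) {
  setdiff(seq_len(ct_n_nodes(x)), unique(stats::na.omit(x$parent)))
}

# number of edges on the path root -> node, for every node
ct_node_depths <- function(x) {
  n <- ct_n_nodes(x)
  d <- integer(n)
  for (v in seq_len(n)) {
    u <- v
    while (!is.na(x$parent[u])) {
      u <- x$parent[u]
      d[v] <- d[v] + 1L
    }
  }
  d
}

# cumulative edge length on the path root -> node
ct_root_distances <- function(x) {
  n <- ct_n_nodes(x)
  d <- numeric(n)
  ord <- order(ct_node_depths(x))  # parents before children
  for (v in ord) {
    p <- x$parent[v]
    if (!is.na(p)) d[v] <- d[p] + x$edge_length[v]
  }
  d
}

#' @export
print.clone_tree <- function(x, ...) {
  cat("<clone_tree> ", if (nzchar(x$label)) x$label else "(unlabeled)",
      ": ", ct_n_nodes(x), " nodes, total length ",
      format(sum(x$edge_length, na.rm = TRUE)), ", max depth ",
      max(ct_node_depths(x)), "\n", sep = "")
  invisible(x)
}

#' Tip depths of a clone tree
#'
#' Depth of a terminal node is the number of edges on its path from the
#' root.  The trunk alone has depth 1.
#'
#' @param x a [clone_tree()].
#' @return named integer vector of depths, one per terminal node.
#' @export
tip_depths <- function(x) {
  lv <- ct_leaves(x)
  d <- ct_node_depths(x)[lv]
  names(d) <- x$name[lv]
  d
}

#' Depth profile of a set of trees
#'
#' Summarises per-tree terminal depths and the cohort-wide maximum depth,
#' which fixes the depth of the shared reference tree.
#'
#' @param trees a list of [clone_tree()] objects (or a single tree).
#' @return a tibble with columns `tree`, `n_tips`, `max_depth`; the global
#'   maximum is attached as attribute `d_max`.
#' @export
depth_profile <- function(trees) {
  trees <- as_tree_list(trees)
  if (!length(trees)) stop("depth_profile() needs at least one tree")
  labs <- tree_labels(trees)
  per <- lapply(trees, tip_depths)
  out <- tibble::tibble(
    tree = labs,
    n_tips = vapply(per, length, integer(1)),
    max_depth = vapply(per, function(d) max(as.integer(d)), integer(1)))
  attr(out, "d_max") <- max(out$max_depth)
  out
}

as_tree_list <- function(trees) {
  if (inherits(trees, "clone_tree")) trees <- list(trees)
  if (!is.list(trees) || !all(vapply(trees, inherits, logical(1), "clone_tree")))
    stop("expected a clone_tree or a list of clone_tree objects")
  trees
}

tree_labels <- function(trees) {
  labs <- vapply(trees, function(t) t$label, character(1))
  if (!is.null(names(trees)) && all(nzchar(names(trees)))) labs <- names(trees)
  blank <- !nzchar(labs)
  labs[blank] <- paste0("tree", which(blank))
  make.unique(labs, sep = "_")
}

## ---- Newick I/O (via ape) --------------------------------------------------

# report common syntax defects with a character offset before handing to ape
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("malformed Newick: unmatched ')' at character ", i)
    }
  }
  if (depth > 0L)
    stop("malformed Newick: ", depth, " unclosed '(' by character ",
         length(chars))
  if (!grepl(";", text, fixed = TRUE))
    stop("malformed Newick: missing terminating ';' (string ends at character ",
         length(chars), ")")
  invisible(TRUE)
}

#' Parse a Newick string into a clone tree
#'
#' The outermost pair of parentheses encloses the founder's subtree, so
#' `"(F:10);"` is a trunk-only tree and `"((A:1,B:2)F:3);"` has founder `F`
#' with two sub-clones.  Branch lengths default to 0 when absent; a branch
#' length on the root itself is dropped with a warning (the normal cell
#' acquires no SSNVs).  Unbranched (singleton) chains of nodes — ubiquitous
#' in clone trees — are parsed faithfully, which is why the package carries
#' its own recursive-descent parser; parse errors name the character offset.
#'
#' @param text a single Newick string.
#' @return a [clone_tree()].
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  check_newick_syntax(text)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n_ch <- length(chars)
  pos <- 1L
  peek <- function() if (pos <= n_ch) chars[pos] else ""
  skip_ws <- function() {
    while (pos <= n_ch && chars[pos] %in% c(" ", "\t", "\r", "\n"))
      pos <<- pos + 1L
  }
  parent <- integer(0); len <- numeric(0); nm <- character(0)
  new_node <- function(p) {
    parent[length(parent) + 1L] <<- p
    len[length(len) + 1L] <<- NA_real_
    nm[length(nm) + 1L] <<- ""
    length(parent)
  }
  read_token <- function() {
    start <- pos
    while (pos <= n_ch && !chars[pos] %in% c("(", ")", ",", ":", ";"))
      pos <<- pos + 1L
    if (pos > start) trimws(paste(chars[start:(pos - 1L)], collapse = ""))
    else ""
  }
  parse_subtree <- function(p) {
    skip_ws()
    v <- new_node(p)
    if (peek() == "(") {
      pos <<- pos + 1L
      repeat {
        parse_subtree(v)
        skip_ws()
        if (peek() == ",") { pos <<- pos + 1L; next }
        if (peek() == ")") { pos <<- pos + 1L; break }
        stop("malformed Newick: expected ',' or ')' at character ", pos)
      }
    }
    nm[v] <<- read_token()
    skip_ws()
    if (peek() == ":") {
      pos <<- pos + 1L
      at <- pos
      s <- read_token()
      val <- suppressWarnings(as.numeric(s))
      if (is.na(val))
        stop("malformed Newick: invalid branch length '", s,
             "' at character ", at)
      if (val < 0)
        stop("negative branch length (", s, ") at character ", at)
      len[v] <<- val
    }
    v
  }
  skip_ws()
  root <- parse_subtree(NA_integer_)
  skip_ws()
  if (peek() != ";")
    stop("malformed Newick: expected ';' at character ", pos)
  if (!is.na(len[root])) {
    warning("branch length on the root is not meaningful and was dropped")
  }
  len[root] <- NA_real_
  len[is.na(len) & !is.na(parent)] <- 0
  clone_tree(parent, len, nm, label = nm[root])
}

#' Convert an ape phylo object to a clone tree
#'
#' @param phy an [ape::read.tree()] style `phylo` object; single-child
#'   (unbranched) nodes are preserved.
#' @param label sample label.
#' @return a [clone_tree()].
#' @export
as_clone_tree <- function(phy, label = "") {
  stopifnot(inherits(phy, "phylo"))
  n_tip <- length(phy$tip.label)
  n <- n_tip + phy$Nnode
  parent <- rep(NA_integer_, n)
  len <- rep(NA_real_, n)
  el <- phy$edge.length
  if (is.null(el)) el <- rep(0, nrow(phy$edge))
  el[is.na(el)] <- 0
  if (any(el < 0))
    stop("negative branch length in Newick input (",
         format(min(el)), ")")
  for (i in seq_len(nrow(phy$edge))) {
    parent[phy$edge[i, 2]] <- phy$edge[i, 1]
    len[phy$edge[i, 2]] <- el[i]
  }
  nm <- character(n)
  nm[seq_len(n_tip)] <- phy$tip.label
  if (!is.null(phy$node.label)) {
    lab <- phy$node.label
    lab[is.na(lab)] <- ""
    nm[n_tip + seq_len(phy$Nnode)] <- lab
  }
  blank <- !nzchar(nm)
  nm[blank] <- paste0("n", which(blank))
  clone_tree(parent, len, nm, label = label)
}

# clone_tree -> phylo (tips keep input order; internal nodes in preorder)
as_phylo_clone_tree <- function(x) {
  n <- ct_n_nodes(x)
  ch <- ct_children(x)
  tips <- ct_leaves(x)
  n_tip <- length(tips)
  new_id <- integer(n)
  new_id[tips] <- seq_len(n_tip)
  # internal nodes: root first, then preorder
  internal <- setdiff(seq_len(n), tips)
  ord <- integer(0)
  stack <- ct_root(x)
  while (length(stack)) {
    v <- stack[1]; stack <- stack[-1]
    if (!(v %in% tips)) {
      ord <- c(ord, v)
      stack <- c(ch[[v]], stack)
    }
  }
  new_id[ord] <- n_tip + seq_along(ord)
  edge <- matrix(0L, n - 1L, 2L)
  elen <- numeric(n - 1L)
  k <- 0L
  emit <- function(v) {
    for (c in ch[[v]]) {
      k <<- k + 1L
      edge[k, ] <<- c(new_id[v], new_id[c])
      elen[k] <<- x$edge_length[c]
      emit(c)
    }
  }
  emit(ct_root(x))
  structure(list(edge = edge, edge.length = elen,
                 tip.label = x$name[tips],
                 node.label = x$name[ord],
                 Nnode = length(ord)),
            class = "phylo", order = "cladewise")
}

#' @importFrom ape as.phylo
#' @export
as.phylo.clone_tree <- function(x, ...) as_phylo_clone_tree(x)

#' Serialize a clone tree as Newick
#'
#' Round-trips with [parse_newick()]: the output re-parses to an isomorphic
#' tree with identical edge lengths.  Zero-length edges are written
#' explicitly as `:0`, never omitted; singleton chains are preserved.
#'
#' @param x a [clone_tree()].
#' @param digits significant digits for branch lengths (default 15, enough
#'   to round-trip doubles).
#' @return a single Newick string.
#' @export
write_newick <- function(x, digits = 15) {
  validate_clone_tree(x)
  ch <- ct_children(x)
  clean <- function(s) gsub("[(),:; \t]", "_", s)
  rec <- function(v) {
    kids <- ch[[v]]
    inner <- if (length(kids))
      paste0("(", paste(vapply(kids, rec, character(1)), collapse = ","), ")")
    else ""
    paste0(inner, clean(x$name[v]), ":",
           sprintf("%.*g", digits, x$edge_length[v]))
  }
  root <- ct_root(x)
  paste0("(", paste(vapply(ch[[root]], rec, character(1)), collapse = ","),
         ")", clean(x$name[root]), ";")
}

#' Read clone trees from Newick files
#'
#' Each file may hold one tree or several (one per line).
#'
#' @param paths character vector of file paths.
#' @return a named list of [clone_tree()] objects, labeled by file name
#'   (with `_i` suffixes for multi-tree files).
#' @export
read_clone_trees <- function(paths) {
  out <- list()
  for (p in paths) {
    if (!file.exists(p)) stop("file not found: ", p)
    lines <- trimws(readLines(p, warn = FALSE))
    lines <- lines[nzchar(lines)]
    if (!length(lines)) stop("no Newick strings in file: ", p)
    base <- sub("\\.[^.]*$", "", basename(p))
    for (i in seq_along(lines)) {
      tr <- parse_newick(lines[i])
      # a named root carries the sample label; fall back to the file name
      if (!nzchar(tr$label))
        tr$label <- if (length(lines) == 1) base else paste0(base, "_", i)
      out[[tr$label]] <- tr
    }
  }
  out
}

#' Write clone trees to a Newick file, one per line
#'
#' @param trees list of [clone_tree()] objects.
#' @param path output file.
#' @param digits significant digits for branch lengths.
#' @return `path`, invisibly.
#' @export
write_clone_trees <- function(trees, path, digits = 15) {
  trees <- as_tree_list(trees)
  writeLines(vapply(trees, function(t) {
    # stamp the sample label on the root so it survives the round trip
    root <- ct_root(t)
    if (nzchar(t$label) && !nzchar(t$name[root])) t$name[root] <- t$label
    write_newick(t, digits = digits)
  }, character(1)), path)
  invisible(path)
}

## ---- binarization ----------------------------------------------------------

#' Resolve multifurcations into a binary tree
#'
#' Registration requires every node to have at most two children.  A node
#' with more than two children keeps its canonically first child (see
#' [canonical_child_order()]) on the original edge; the remaining children
#' hang off a chain ("spine") of zero-length edges, recursively.  Total edge
#' length is conserved exactly and no terminal depth decreases.  Already
#' binary trees are returned structurally unchanged.  Spine nodes are marked
#' in the `inserted` field so that interpretation tools (e.g.
#' [diversity_curve()]) can ignore them: they are an encoding artifact, not
#' sub-clones.
#'
#' @param x a [clone_tree()].
#' @return a binary [clone_tree()] (class gains `"binary_clone_tree"`).
#' @export
binarize_multifurcations <- function(x) {
  validate_clone_tree(x)
  ch <- ct_children(x)
  ord_keys <- canonical_order_keys(x)

  parent <- integer(0); len <- numeric(0); nm <- character(0); ins <- logical(0)
  add_node <- function(p, l, name, inserted) {
    parent[length(parent) + 1L] <<- p
    len[length(len) + 1L] <<- l
    nm[length(nm) + 1L] <<- name
    ins[length(ins) + 1L] <<- inserted
    length(parent)
  }
  n_spine <- 0L
  copy <- function(v, p_new) {
    v_new <- add_node(p_new, x$edge_length[v], x$name[v], x$inserted[v])
    kids <- ch[[v]]
    if (length(kids)) attach_kids(kids[canonical_order(ord_keys, kids)], v_new)
    v_new
  }
  attach_kids <- function(kids, p_new) {
    if (length(kids) <= 2) {
      for (c in kids) copy(c, p_new)
    } else {
      copy(kids[1], p_new)
      n_spine <<- n_spine + 1L
      s <- add_node(p_new, 0, paste0(".spine", n_spine), TRUE)
      attach_kids(kids[-1], s)
    }
  }
  root <- ct_root(x)
  add_node(NA_integer_, NA_real_, x$name[root], FALSE)
  copy(ch[[root]][1], 1L)
  out <- clone_tree(parent, len, nm, label = x$label, inserted = ins)
  class(out) <- c("binary_clone_tree", class(out))
  out
}

is_binary_tree <- function(x) {
  all(vapply(ct_children(x), length, integer(1)) <= 2)
}

## ---- VAF binarization ------------------------------------------------------

#' Binarize a VAF table
#'
#' Multi-region variant allele frequency profiles are binarized prior to
#' phylogeny reconstruction: an entry becomes 1 when the VAF reaches the
#' threshold (default 0.05) and 0 otherwise.
#'
#' @param vaf a numeric matrix or data frame (variants x regions) with
#'   entries in `[0, 1]`.  A data frame may carry a leading character column
#'   of variant identifiers, which is preserved.
#' @param threshold detection threshold; entries `>= threshold` map to 1.
#' @return an object of the same shape with binary entries.
#' @export
binarize_vaf <- function(vaf, threshold = 0.05) {
  id_col <- NULL
  m <- vaf
  if (is.data.frame(m)) {
    if (ncol(m) && is.character(m[[1]])) {
      id_col <- m[[1]]
      m <- m[, -1, drop = FALSE]
    }
    m <- as.matrix(m)
  }
  if (!is.numeric(m)) stop("VAF table must be numeric")
  if (anyNA(m)) stop("VAF table contains missing values")
  if (any(m < 0 | m > 1))
    stop("VAF entries must lie in [0, 1]; offending value ",
         format(m[which(m < 0 | m > 1)[1]]))
  b <- (m >= threshold) * 1L
  if (is.null(id_col)) {
    if (is.data.frame(vaf)) as.data.frame(b) else b
  } else {
    out <- cbind(data.frame(variant = id_col, stringsAsFactors = FALSE),
                 as.data.frame(b))
    names(out)[1] <- names(vaf)[1]
    out
  }
}
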