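## Labeled synthetic cohorts of cancer evolutionary trees: topology classes,
## SSNV-accumulation classes, and the three benchmark designs.
##
## Generator constants (frozen; see the methods vignette for rationale):
##   * topology edits per tree ~ Poisson(lambda), lambda(i) = 0.05 * 3^(i-1)
##     for dispersion index i, so the lowest index yields mild perturbation
##     (most trees stay at their archetype) and the spread grows geometrically;
##   * trunk fraction ~ Beta(mu * phi, (1 - mu) * phi) with mu = 0.8 (TR),
##     0.5 (BL), 0.2 (BR) and concentration phi(v) = 400 / 2^(v-1) for
##     variance index v;
##   * non-trunk mass split by a symmetric Dirichlet with alpha(v) =
##     30 / 2^(v-1);
##   * integer SSNV counts conserve the tree total by largest-remainder
##     rounding.

.edit_lambda <- function(dispersion_index) 0.05 * 3^(dispersion_index - 1)

.trunk_mu <- c(TR = 0.8, BL = 0.5, BR = 0.2)

.beta_phi <- function(variance_index) 400 / 2^(variance_index - 1)

.dirichlet_alpha <- function(variance_index) 30 / 2^(variance_index - 1)

.archetype_newick <- c(
  MC = "(F:1);",
  PL = "((A:1,B:1)F:1);",
  PM = "(((C:1,D:1)A:1,B:1)F:1);",
  PH = "((((E:1,G:1)C:1,(H:1,I:1)D:1)A:1,B:1)F:1);",
  MT = "(((((A4:1,L4:1)A3:1,L3:1)A2:1,L2:1)A1:1,L1:1)F:1);")

#' Archetype tree topologies
#'
#' Frozen base topologies for the simulated classes: monoclonal (`MC`,
#' trunk only), polyclonal-low (`PL`, trunk plus two branches),
#' polyclonal-middle (`PM`, four branches over two levels),
#' polyclonal-high (`PH`, eight branches over three levels), and
#' mutator-phenotype (`MT`, a depth-5 caterpillar).  All archetype edges
#' have unit length; lengths are reassigned downstream.
#'
#' @param class_name one of `"MC"`, `"PL"`, `"PM"`, `"PH"`, `"MT"`.
#' @return a [clone_tree()].
#' @export
base_topology <- function(class_name) {
  if (!class_name %in% names(.archetype_newick))
    stop("unknown topology class '", class_name, "'; expected one of ",
         paste(names(.archetype_newick), collapse = ", "))
  tr <- parse_newick(.archetype_newick[[class_name]])
  tr$label <- class_name
  tr
}

#' Randomly perturb a tree topology
#'
#' Applies `E ~ Poisson(lambda)` random edit operations, where `lambda`
#' grows geometrically with the dispersion index.  Each edit is drawn
#' uniformly from the feasible subset of: leaf insertion (a new unit-length
#' leaf under a random non-root node), leaf deletion (keeping at least two
#' nodes), and leaf regrafting (moving a leaf under another non-root node).
#'
#' @param base a [clone_tree()].
#' @param dispersion_index integer `>= 1`; larger means more edits.
#' @param seed optional integer seed.
#' @return a perturbed [clone_tree()].
#' @export
perturb_topology <- function(base, dispersion_index = 1, seed = NULL) {
  stopifnot(dispersion_index >= 1)
  run <- function() {
    x <- base
    n_edits <- stats::rpois(1, .edit_lambda(dispersion_index))
    for (e in seq_len(n_edits)) x <- random_edit(x)
    x
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

random_edit <- function(x) {
  n <- ct_n_nodes(x)
  leaves <- ct_leaves(x)
  ops <- "insert"
  if (n > 2) ops <- c(ops, "delete")
  # regraft needs a leaf with at least one valid target
  if (n > 3) ops <- c(ops, "regraft")
  op <- sample(ops, 1)
  if (op == "insert") {
    at <- resample(setdiff(seq_len(n), ct_root(x)), 1)
    return(add_leaf(x, at))
  }
  if (op == "delete") {
    return(drop_leaf(x, resample(leaves, 1)))
  }
  # regraft
  u <- resample(leaves, 1)
  targets <- setdiff(seq_len(n), c(ct_root(x), u, x$parent[u]))
  if (!length(targets)) return(x)
  x$parent[u] <- resample(targets, 1)
  validate_clone_tree(x)
}

resample <- function(x, size) x[sample.int(length(x), size)]

add_leaf <- function(x, at, len = 1) {
  x$parent <- c(x$parent, as.integer(at))
  x$edge_length <- c(x$edge_length, len)
  x$name <- make.unique(c(x$name, "new"), sep = "")
  x$inserted <- c(x$inserted, FALSE)
  validate_clone_tree(x)
}

drop_leaf <- function(x, leaf) {
  keep <- setdiff(seq_len(ct_n_nodes(x)), leaf)
  remap <- match(x$parent[keep], keep)
  clone_tree(remap, x$edge_length[keep], x$name[keep], label = x$label,
             inserted = x$inserted[keep])
}

#' Assign SSNV counts to the edges of a tree
#'
#' Draws the trunk fraction from a Beta distribution centered at 0.8
#' (`TR`, trunk accumulation), 0.5 (`BL`, balanced) or 0.2 (`BR`, branch
#' accumulation), spreads the remaining mass over the non-trunk edges with
#' a symmetric Dirichlet, and rounds to integer counts that sum exactly to
#' `total_ssnvs` (largest-remainder rounding).  Concentrations decrease
#' with the variance index, widening the within-class spread.
#'
#' @param tree a [clone_tree()].
#' @param pattern one of `"TR"`, `"BL"`, `"BR"`.
#' @param variance_index integer `>= 1`; larger means more spread.
#' @param total_ssnvs total SSNV count to distribute (at least the number
#'   of edges).
#' @param seed optional integer seed.
#' @return the tree with integer edge lengths summing to `total_ssnvs`.
#' @export
assign_edge_lengths <- function(tree, pattern = c("TR", "BL", "BR"),
                                variance_index = 1, total_ssnvs,
                                seed = NULL) {
  pattern <- match.arg(pattern)
  stopifnot(variance_index >= 1)
  n_edges <- ct_n_nodes(tree) - 1L
  if (total_ssnvs < n_edges)
    stop("total_ssnvs (", total_ssnvs, ") is smaller than the number of ",
         "edges (", n_edges, ")")
  run <- function() {
    mu <- .trunk_mu[[pattern]]
    phi <- .beta_phi(variance_index)
    p <- stats::rbeta(1, mu * phi, (1 - mu) * phi)
    root <- ct_root(tree)
    founder <- which(tree$parent == root)
    others <- setdiff(which(!is.na(tree$parent)), founder)
    raw <- numeric(ct_n_nodes(tree))
    if (length(others)) {
      w <- stats::rgamma(length(others), shape =
                           .dirichlet_alpha(variance_index), rate = 1)
      w <- w / sum(w)
      raw[founder] <- p * total_ssnvs
      raw[others] <- (1 - p) * total_ssnvs * w
    } else {
      raw[founder] <- total_ssnvs
    }
    counts <- largest_remainder(raw[c(founder, others)], total_ssnvs)
    tree$edge_length[c(founder, others)] <- counts
    tree
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

# round `raw` to integers summing exactly to `total`
largest_remainder <- function(raw, total) {
  fl <- floor(raw)
  rem <- as.integer(round(total - sum(fl)))
  if (rem > 0) {
    idx <- order(raw - fl, decreasing = TRUE)[seq_len(rem)]
    fl[idx] <- fl[idx] + 1
  }
  fl
}

#' Generate a labeled simulated cohort
#'
#' Three benchmark designs:
#' * **I** — topology classes only (default `MC`, `PL`, `PH`, `MT`); every
#'   edge length is set to 1, so only tree shape separates the classes.
#' * **II** — one topology (`PM`, mildly perturbed), three
#'   SSNV-accumulation classes `TR`, `BL`, `BR`.
#' * **III** — nine classes: `{PL, PM, PH} x {TR, BL, BR}`, e.g. `PL-TR`.
#'
#' @param design `"I"`, `"II"` or `"III"`.
#' @param classes optional subset of the design's classes.
#' @param trees_per_class trees per class (default 10).
#' @param dispersion_index topology spread (designs I-III), `>= 1`.
#' @param variance_index edge-length spread (designs II-III), `>= 1`.
#' @param total_ssnv_range integer range the per-tree SSNV total is drawn
#'   from, uniformly.
#' @param seed optional integer seed; the whole cohort is reproducible
#'   from it.
#' @return an object of class `tree_cohort`: `trees` (list of
#'   [clone_tree()]), `truth` (character class labels), `design`, `config`.
#' @export
generate_design <- function(design = c("I", "II", "III"), classes = NULL,
                            trees_per_class = 10, dispersion_index = 1,
                            variance_index = 1,
                            total_ssnv_range = c(100, 1000), seed = NULL) {
  design <- match.arg(design)
  stopifnot(trees_per_class >= 1)
  defaults <- switch(design,
    I = c("MC", "PL", "PH", "MT"),
    II = c("TR", "BL", "BR"),
    III = as.vector(outer(c("PL", "PM", "PH"), c("TR", "BL", "BR"),
                          paste, sep = "-")))
  if (is.null(classes)) classes <- defaults
  if (!all(classes %in% defaults))
    stop("invalid class(es) for design ", design, ": ",
         paste(setdiff(classes, defaults), collapse = ", "))
  run <- function() {
    trees <- list()
    truth <- character(0)
    for (cl in classes) {
      for (i in seq_len(trees_per_class)) {
        if (design == "I") {
          tr <- perturb_topology(base_topology(cl), dispersion_index)
          tr$edge_length[!is.na(tr$parent)] <- 1
        } else {
          topo <- if (design == "II") "PM" else sub("-.*", "", cl)
          pat <- if (design == "II") cl else sub(".*-", "", cl)
          tr <- perturb_topology(base_topology(topo), dispersion_index)
          total <- sample(seq(total_ssnv_range[1], total_ssnv_range[2]), 1)
          total <- max(total, ct_n_nodes(tr) - 1L)
          tr <- assign_edge_lengths(tr, pat, variance_index, total)
        }
        tr$label <- sprintf("%s_%02d", cl, i)
        trees[[tr$label]] <- tr
        truth <- c(truth, cl)
      }
    }
    structure(list(trees = trees, truth = truth, design = design,
                   config = list(classes = classes,
                                 trees_per_class = trees_per_class,
                                 dispersion_index = dispersion_index,
                                 variance_index = variance_index,
                                 total_ssnv_range = total_ssnv_range,
                                 seed = seed)),
              class = "tree_cohort")
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

#' @export
print.tree_cohort <- function(x, ...) {
  cat("<tree_cohort> design ", x$design, ": ", length(x$trees),
      " trees, ", length(unique(x$truth)), " classes\n", sep = "")
  print(table(class = x$truth))
  invisible(x)
}

#' @rdname tidy-cloneclust
#' @export
tidy.tree_cohort <- function(x, ...) {
  tibble::tibble(
    tree = names(x$trees),
    class = x$truth,
    n_nodes = vapply(x$trees, ct_n_nodes, integer(1)),
    total_ssnvs = vapply(x$trees,
                         function(t) sum(t$edge_length, na.rm = TRUE),
                         numeric(1)),
    max_depth = vapply(x$trees, function(t) max(ct_node_depths(t)),
                       integer(1)))
}

#' Write a simulated cohort to disk
#'
#' Emits a multi-tree Newick file (one tree per line), a truth-label TSV,
#' and a key-value config echo.
#'
#' @param cohort a `tree_cohort`.
#' @param dir output directory (created if missing).
#' @param stem file stem, default `"cohort"`.
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir, stem = "cohort") {
  stopifnot(inherits(cohort, "tree_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_clone_trees(cohort$trees, file.path(dir, paste0(stem, ".nwk")))
  utils::write.table(
    data.frame(tree = names(cohort$trees), class = cohort$truth),
    file.path(dir, paste0(stem, "_truth.tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- cohort$config
  cfg$classes <- paste(cfg$classes, collapse = ",")
  cfg$total_ssnv_range <- paste(cfg$total_ssnv_range, collapse = "..")
  cfg$seed <- if (is.null(cfg$seed)) "none" else cfg$seed
  writeLines(paste0(names(cfg), "\t", unlist(cfg), collapse = "\n"),
             file.path(dir, paste0(stem, "_config.tsv")))
  invisible(dir)
}
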