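# Fixture builders and independent brute-force oracles used across tests.

# Random clone tree: root -> founder, then `extra` nodes attached uniformly
# at random below the founder, with positive random edge lengths.
rand_tree <- function(extra = 5, max_len = 10, label = "rand") {
  parent <- c(NA_integer_, 1L)
  len <- c(NA_real_, runif(1, 0.5, max_len))
  for (i in seq_len(extra)) {
    cand <- 2:length(parent)
    at <- cand[sample.int(length(cand), 1)]
    parent <- c(parent, at)
    len <- c(len, runif(1, 0, max_len))
  }
  clone_tree(parent, len, label = label)
}

# Independent canonical form for isomorphism checks: children strings are
# sorted lexicographically (a different rule than the package's mapping
# order, but equally a tree invariant).
iso_canon <- function(x) {
  ch <- lapply(seq_along(x$parent), function(v) which(x$parent == v))
  rec <- function(v) {
    l <- x$edge_length[v]
    tag <- if (is.na(l)) "R" else sprintf("%.9g", l)
    kids <- ch[[v]]
    if (!length(kids)) return(tag)
    paste0(tag, "[", paste(sort(vapply(kids, rec, character(1))),
                           collapse = "|"), "]")
  }
  rec(which(is.na(x$parent)))
}

# Brute-force external validation indices, computed straight from first
# principles (pair loops / entropy sums), independent of the package code.
bf_purity <- function(pred, true) {
  s <- 0
  for (k in unique(pred)) {
    s <- s + max(table(true[pred == k]))
  }
  s / length(pred)
}

bf_nmi <- function(pred, true) {
  n <- length(pred)
  ent <- function(lab) {
    p <- table(lab) / n
    -sum(p * log(p))
  }
  mi <- 0
  for (a in unique(pred)) for (b in unique(true)) {
    pab <- sum(pred == a & true == b) / n
    if (pab > 0) mi <- mi + pab * log(pab / (mean(pred == a) * mean(true == b)))
  }
  hp <- ent(pred); ht <- ent(true)
  if (hp + ht == 0) return(1)
  2 * mi / (hp + ht)
}

bf_rand <- function(pred, true) {
  n <- length(pred)
  agree <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    same_p <- pred[i] == pred[j]
    same_t <- true[i] == true[j]
    if (same_p == same_t) agree <- agree + 1
  }
  agree / choose(n, 2)
}

# Mean of a score over seeded design replicates with forced K (used for
# monotone-degradation checks).
mean_nmi_design <- function(design, index_arg, index_value, n_seeds,
                            trees_per_class = 10) {
  scores <- vapply(seq_len(n_seeds), function(s) {
    args <- list(design = design, trees_per_class = trees_per_class,
                 seed = 7000 + 97 * s)
    args[[index_arg]] <- index_value
    co <- do.call(generate_design, args)
    rs <- register_set(co$trees)
    k <- length(unique(co$truth))
    labs <- ward_cluster(distance_matrix(rs), k)
    nmi(labs, co$truth)
  }, numeric(1))
  mean(scores)
}
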