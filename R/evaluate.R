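## External clustering validation indices: purity, normalized mutual
## information, Rand index.

check_labels <- function(pred, true, min_n = 1) {
  if (length(pred) != length(true))
    stop("label vectors differ in length (", length(pred), " vs ",
         length(true), ")")
  if (length(pred) < min_n)
    stop("need at least ", min_n, " observations")
  invisible(TRUE)
}

#' Contingency table of two labelings
#'
#' @param pred,true equal-length label vectors.
#' @return a `pred x true` count table.
#' @export
label_contingency <- function(pred, true) {
  check_labels(pred, true)
  table(pred = as.character(pred), true = as.character(true))
}

#' Cluster purity
#'
#' `(1/n) * sum_k max_c n_kc`: each predicted cluster is credited with its
#' best-matching true class.  Purity is not symmetric in its arguments —
#' an all-singleton prediction scores 1.
#'
#' @param pred predicted cluster labels.
#' @param true ground-truth class labels.
#' @return a number in `[0, 1]`.
#' @export
purity <- function(pred, true) {
  check_labels(pred, true, min_n = 1)
  ct <- label_contingency(pred, true)
  sum(apply(ct, 1, max)) / length(pred)
}

#' Normalized mutual information
#'
#' `I(pred; true)` normalized by the arithmetic mean of the two partition
#' entropies (natural logs); `variant = "sqrt"` normalizes by the
#' geometric mean instead.  When both partitions are trivial (a single
#' cluster each) the index is defined as 1.
#'
#' @inheritParams purity
#' @param variant `"arithmetic"` (default) or `"sqrt"` normalization.
#' @return a number in `[0, 1]`.
#' @export
nmi <- function(pred, true, variant = c("arithmetic", "sqrt")) {
  variant <- match.arg(variant)
  check_labels(pred, true, min_n = 1)
  ct <- label_contingency(pred, true)
  n <- length(pred)
  p_joint <- ct / n
  p_pred <- rowSums(p_joint)
  p_true <- colSums(p_joint)
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  hp <- h(p_pred); ht <- h(p_true)
  outer_p <- outer(p_pred, p_true)
  nz <- p_joint > 0
  mi <- sum(p_joint[nz] * log(p_joint[nz] / outer_p[nz]))
  denom <- if (variant == "arithmetic") (hp + ht) / 2 else sqrt(hp * ht)
  if (denom == 0) return(if (hp == 0 && ht == 0) 1 else 0)
  min(max(mi / denom, 0), 1)
}

#' Rand index
#'
#' Fraction of object pairs on which the two partitions agree: the pair is
#' either co-clustered in both or separated in both.
#'
#' @inheritParams purity
#' @return a number in `[0, 1]`.
#' @export
rand_index <- function(pred, true) {
  check_labels(pred, true, min_n = 2)
  n <- length(pred)
  ct <- label_contingency(pred, true)
  sum_nij2 <- sum(choose(ct, 2))
  sum_a2 <- sum(choose(rowSums(ct), 2))
  sum_b2 <- sum(choose(colSums(ct), 2))
  total <- choose(n, 2)
  (total + 2 * sum_nij2 - sum_a2 - sum_b2) / total
}

#' All three validation indices at once
#'
#' @inheritParams purity
#' @return a one-row tibble with columns `purity`, `nmi`, `rand`.
#' @export
eval_scores <- function(pred, true) {
  tibble::tibble(purity = purity(pred, true),
                 nmi = nmi(pred, true),
                 rand = rand_index(pred, true))
}
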