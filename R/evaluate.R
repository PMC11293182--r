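#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected pair-counting agreement under the permutation model:
#' \deqn{ARI = \frac{\sum_{ij}\binom{n_{ij}}{2} - E}{\tfrac12(A + B) - E}}
#' with `A`, `B` the row/column pair sums of the contingency table and
#' `E = AB / \binom{n}{2}` the expected agreement. Equals 1 for identical
#' partitions, is 0 in expectation for independent ones, and is symmetric
#' and invariant to relabeling.
#'
#' @param a,b Label vectors of equal length (any atomic type).
#' @return ARI in `[-1, 1]`.
#' @examples
#' adjusted_rand_index(c(0, 0, 0, 1, 1), c(0, 0, 1, 1, 1))  # 1/6
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) abort("`a` and `b` must have equal length")
  n <- length(a)
  if (n < 2) abort("need at least 2 items")
  tab <- table(a, b)
  s <- sum(choose(tab, 2))
  ra <- sum(choose(rowSums(tab), 2))
  cb <- sum(choose(colSums(tab), 2))
  e <- ra * cb / choose(n, 2)
  denom <- (ra + cb) / 2 - e
  if (abs(denom) < .Machine$double.eps) return(1)  # two trivial partitions
  (s - e) / denom
}

#' Rare-cell detection accuracy
#'
#' Fraction of ground-truth rare cells that are correctly recognized. A
#' rare cell counts as recognized when the predicted cluster it sits in
#' is dominated by the rare type: the rare type's count in that cluster
#' strictly exceeds every other type's count (majority rule). With
#' `strict = TRUE` the cluster must instead consist exclusively of rare
#' cells. Rare cells absorbed into clusters dominated by an abundant type
#' score zero — the characteristic failure mode of fixed-k graphs.
#'
#' @param predicted Predicted cluster labels.
#' @param truth Ground-truth type labels, same length/order.
#' @param rare_type The truth label regarded as the rare type.
#' @param strict If `TRUE`, require pure rare clusters.
#' @return Fraction in `[0, 1]` of rare cells recognized.
#' @export
rare_accuracy <- function(predicted, truth, rare_type, strict = FALSE) {
  if (length(predicted) != length(truth))
    abort("`predicted` and `truth` must have equal length")
  truth <- as.character(truth)
  rare <- truth == rare_type
  if (!any(rare)) abort(paste0("no cells with rare type '", rare_type, "'"))
  ok_cluster <- vapply(unique(predicted[rare]), function(cl) {
    comp <- table(truth[predicted == cl])
    if (strict) return(length(comp) == 1 && names(comp) == rare_type)
    others <- comp[names(comp) != rare_type]
    n_rare <- if (rare_type %in% names(comp)) comp[[rare_type]] else 0L
    length(others) == 0 || n_rare > max(others)
  }, logical(1))
  recognized <- ok_cluster[match(predicted[rare], unique(predicted[rare]))]
  sum(recognized) / sum(rare)
}

#' Evaluate a clustering against ground truth
#'
#' Convenience wrapper computing the Adjusted Rand Index, the number of
#' communities and (when a rare type is given) the rare-cell detection
#' accuracy.
#'
#' @param clustering An `aknn_clustering` or a label vector.
#' @param truth Ground-truth type labels, same cell order.
#' @param rare_type Optional rare type label.
#' @param strict Passed to [rare_accuracy()].
#' @return One-row tibble with `ari`, `n_communities` and (optionally)
#'   `rare_accuracy`.
#' @export
evaluate_clustering <- function(clustering, truth, rare_type = NULL,
                                strict = FALSE) {
  labels <- if (is(clustering, "aknn_clustering")) clustering$labels
            else clustering
  out <- tibble(ari = adjusted_rand_index(labels, truth),
                n_communities = length(unique(labels)))
  if (!is.null(rare_type))
    out$rare_accuracy <- rare_accuracy(labels, truth, rare_type, strict)
  out
}
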