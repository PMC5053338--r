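## Method-comparison metrics: agreement of impact-direction calls and
## overlap of the top-a most impacted pathways between two scoring methods
## (e.g. decision coefficients vs mean impact values, or vs total effects).

#' Direction concordance rate
#'
#' Fraction of aligned positions carrying the same direction label.
#'
#' @param labels_a,labels_b equal-length direction vectors.
#' @return List with `rate`, `matches` and `total`.
#' @export
direction_concordance <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("direction vectors differ in length (", length(labels_a), " vs ",
         length(labels_b), ")")
  if (length(labels_a) == 0L)
    stop("direction concordance undefined for empty vectors")
  matches <- sum(labels_a == labels_b)
  list(rate = matches / length(labels_a),
       matches = matches, total = length(labels_a))
}

#' Top-a overlap of two score vectors
#'
#' Both vectors are ranked by absolute value (ties broken by name, so the
#' result is invariant under relabeling order) and the overlap of the two
#' top-`a` sets is reported as a fraction of `a`.
#'
#' @param scores_a,scores_b aligned named score vectors.
#' @param a number of top pathways to compare (1 <= a <= length).
#' @return List with `rate` and `overlap` (the shared ids).
#' @export
top_a_overlap <- function(scores_a, scores_b, a) {
  if (length(scores_a) != length(scores_b))
    stop("score vectors differ in length")
  if (is.null(names(scores_a)) || is.null(names(scores_b)))
    stop("score vectors must be named")
  if (!setequal(names(scores_a), names(scores_b)))
    stop("score vectors must cover the same pathways")
  if (a < 1 || a > length(scores_a))
    stop("a must lie in [1, ", length(scores_a), "]")
  top <- function(s) names(s)[order(-abs(s), names(s))][seq_len(a)]
  overlap <- intersect(top(scores_a), top(scores_b))
  list(rate = length(overlap) / a, overlap = sort(overlap))
}
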