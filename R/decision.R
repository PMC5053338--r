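## Decision coefficients and their significance machinery.
##
## The decision coefficient of child j is
##   DC_j = (b*_j)^2 + 2 sum_{t != j} b*_j r_jt b*_t,
## the direct determination factor plus the indirect determination
## contributed by every correlated sibling. Column j of the subdivision
## matrix lists those addends, so the matrix displays the pairwise
## regulation structure in numerical form. Summed over children,
## sum_j DC_j = 2 R^2 - sum_j (b*_j)^2, an algebraic identity used as a
## self-check throughout the test suite.

#' Decision coefficients and subdivision matrix
#'
#' @param model a [path_model()].
#' @return List with `dc`, the named vector of decision coefficients, and
#'   `subdivision`, the symmetric q x q matrix with `(b*_j)^2` on the
#'   diagonal and `2 b*_t r_tj b*_j` off it; column sums reproduce `dc`.
#' @export
decision_coefficients <- function(model) {
  stopifnot(inherits(model, "path_model"))
  b <- model$b_star
  s <- 2 * outer(b, b) * model$R_x
  diag(s) <- b^2
  dimnames(s) <- list(model$child_ids, model$child_ids)
  dc <- colSums(s)
  names(dc) <- model$child_ids
  list(dc = dc, subdivision = s)
}

#' Significance cutoff for decision coefficients
#'
#' The cutoff for child j at significance level `alpha` is
#' `2 t |r_jy - b*_j| sqrt(c_jj (1 - R^2) / (n - q - 1))` with `t` the
#' upper `alpha/2` quantile of the t distribution on `n - q - 1` degrees of
#' freedom and `c_jj` the j-th diagonal element of the inverse correlation
#' matrix. A decision coefficient is significant when its absolute value
#' reaches the cutoff.
#'
#' Two degenerate cases are resolved conservatively towards significance:
#' when `r_jy = b*_j` (no indirect effect) the cutoff is exactly zero, and
#' an `R^2` at or above 1 (possible only through rounding of inputs) clamps
#' `1 - R^2` at zero. In both cases any nonzero coefficient is flagged.
#'
#' @param model a [path_model()].
#' @param alpha significance level in (0, 1).
#' @return Named nonnegative vector of cutoffs.
#' @export
dc_cutoff <- function(model, alpha) {
  stopifnot(inherits(model, "path_model"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must be a single value in (0, 1)")
  df <- model$n - model$q - 1
  if (df < 1)
    stop("need n - q - 1 >= 1 degrees of freedom (n = ", model$n,
         ", q = ", model$q, ")")
  one_minus_r2 <- max(0, 1 - model$R2)
  tq <- qt(1 - alpha / 2, df)
  cutoff <- 2 * tq * abs(model$R_xy - model$b_star) *
    sqrt(model$c_diag * one_minus_r2 / df)
  names(cutoff) <- model$child_ids
  cutoff
}

#' Select significantly impacted pathways
#'
#' A child is selected when the absolute value of its decision coefficient
#' reaches its cutoff; `cutoff` may be the per-child vector from
#' [dc_cutoff()] or a single fixed threshold (the integrated-threshold
#' practice, default 0.4 in [decision_analysis()]). Ranking is by absolute
#' decision coefficient, ties broken by child id.
#'
#' @param dc named vector of decision coefficients.
#' @param cutoff nonnegative vector (recycled if length 1).
#' @return List with `significant` (named logical) and `ranking` (child ids
#'   in decreasing |dc| order).
#' @export
select_impacted <- function(dc, cutoff) {
  if (length(cutoff) == 1L) cutoff <- rep(cutoff, length(dc))
  if (length(cutoff) != length(dc))
    stop("cutoff must have length 1 or length(dc)")
  significant <- abs(dc) >= cutoff
  names(significant) <- names(dc)
  ord <- order(-abs(dc), names(dc))
  list(significant = significant, ranking = names(dc)[ord])
}

#' Impact direction from the decision-coefficient sign
#'
#' A positive decision coefficient marks a pathway as activated
#' (up-regulated), a negative one as inhibited (down-regulated), zero as
#' neutral.
#'
#' @param dc numeric vector of decision coefficients.
#' @return Character vector with values `"activated"`, `"inhibited"` or
#'   `"neutral"`.
#' @export
impact_direction <- function(dc) {
  out <- ifelse(dc > 0, "activated", ifelse(dc < 0, "inhibited", "neutral"))
  names(out) <- names(dc)
  out
}

#' Decision percentages
#'
#' Normalizes absolute decision coefficients over the siblings of one
#' parent: `dp_j = |DC_j| / sum_k |DC_k| * 100`. These are the edge labels
#' of the decision tree.
#'
#' @param dc numeric vector with at least one nonzero entry.
#' @return Named vector summing to 100.
#' @export
decision_percentages <- function(dc) {
  total <- sum(abs(dc))
  if (total == 0)
    stop("decision percentages undefined: all decision coefficients are 0")
  out <- abs(dc) / total * 100
  names(out) <- names(dc)
  out
}

#' Full decision analysis for one parent
#'
#' Convenience wrapper combining [decision_coefficients()], [dc_cutoff()]
#' at each requested level, [select_impacted()], [impact_direction()] and
#' [decision_percentages()] into one report.
#'
#' @param model a [path_model()].
#' @param alphas significance levels for the t-based cutoffs.
#' @param dc_threshold fixed threshold for the `most_impacted` flag
#'   (`|DC| >= dc_threshold`).
#' @return List with `report` (one data-frame row per child: parent_id,
#'   child_id, b_star, direct_factor, indirect_factor, dc, one cutoff column
#'   per level, significant_at, direction, decision_percentage,
#'   most_impacted), `subdivision` (matrix) and `ranking`.
#' @export
decision_analysis <- function(model, alphas = c(0.01, 0.05, 0.1),
                              dc_threshold = 0.4) {
  stopifnot(inherits(model, "path_model"))
  alphas <- sort(alphas)
  dcs <- decision_coefficients(model)
  dc <- dcs$dc
  direct <- model$b_star^2
  indirect <- dc - direct

  cutoffs <- vapply(alphas, function(a) dc_cutoff(model, a),
                    numeric(model$q))
  colnames(cutoffs) <- sprintf("cutoff_%.2f", alphas)
  sig <- abs(dc) >= cutoffs
  significant_at <- apply(sig, 1L, function(row) {
    hit <- alphas[row]
    if (length(hit) == 0L) "none" else paste(sprintf("%.2f", hit),
                                             collapse = ",")
  })

  report <- data.frame(
    parent_id = model$parent_id,
    child_id = model$child_ids,
    b_star = unname(model$b_star),
    direct_factor = unname(direct),
    indirect_factor = unname(indirect),
    dc = unname(dc),
    stringsAsFactors = FALSE)
  report <- cbind(report, as.data.frame(cutoffs, row.names = NULL))
  report$significant_at <- unname(significant_at)
  report$direction <- unname(impact_direction(dc))
  report$decision_percentage <- unname(decision_percentages(dc))
  report$most_impacted <- abs(unname(dc)) >= dc_threshold

  list(report = report,
       subdivision = dcs$subdivision,
       ranking = select_impacted(dc, dc_threshold)$ranking)
}
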