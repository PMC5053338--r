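## Gene-level impact scoring, so the pipeline can start from
## differential-expression tables instead of precomputed impact values.
## The impact of a pathway in one contrast is
##   (#DEG in pathway / #annotated genes) * mean(|log2FC| over DEG)
##                                        * mean(-log10 p over DEG)
## and the signed direction value is impact(up DEG) - impact(down DEG).
## Fold-change magnitudes enter as absolute values; signs act only through
## the up/down split, keeping the impact itself a nonnegative magnitude.

.degs_in_pathway <- function(degs, pathway_id) {
  hit <- vapply(degs$pathway_ids, function(p) pathway_id %in% p, logical(1L))
  degs[hit, , drop = FALSE]
}

.impact_from_records <- function(records, gene_universe) {
  if (any(records$pvalue <= 0)) stop("DEG p-values must be > 0")
  deg <- records[records$is_deg, , drop = FALSE]
  if (nrow(deg) == 0L) return(0)
  (nrow(deg) / gene_universe) *
    mean(abs(deg$log2fc)) *
    mean(-log10(deg$pvalue))
}

#' Pathway impact value from a DEG table
#'
#' @param degs data frame for a single contrast, as returned by
#'   [read_deg_table()] (columns `gene_id`, `log2fc`, `pvalue`, `is_deg`,
#'   list column `pathway_ids`).
#' @param pathway_id pathway to score.
#' @param gene_universe number of annotated genes in the pathway (>= 1).
#' @return Nonnegative impact value; 0 when the pathway has no DEG.
#' @export
pathway_impact <- function(degs, pathway_id, gene_universe) {
  if (gene_universe < 1) stop("gene_universe must be >= 1")
  .impact_from_records(.degs_in_pathway(degs, pathway_id), gene_universe)
}

#' Signed impact direction value
#'
#' Impact computed over up-regulated DEG minus impact over down-regulated
#' DEG; genes with `log2fc == 0` contribute to neither side.
#'
#' @inheritParams pathway_impact
#' @return Signed direction value.
#' @export
impact_direction_value <- function(degs, pathway_id, gene_universe) {
  if (gene_universe < 1) stop("gene_universe must be >= 1")
  records <- .degs_in_pathway(degs, pathway_id)
  up <- records[records$log2fc > 0, , drop = FALSE]
  down <- records[records$log2fc < 0, , drop = FALSE]
  .impact_from_records(up, gene_universe) -
    .impact_from_records(down, gene_universe)
}

#' Impact matrix from a multi-contrast DEG table
#'
#' Scores every pathway in every contrast and assembles the result in the
#' pathway x contrast layout the modelling functions consume. Contrast
#' column order follows first appearance in the table.
#'
#' @param degs data frame as returned by [read_deg_table()].
#' @param gene_universe named vector of annotated-gene counts per pathway;
#'   by default the number of distinct genes attached to the pathway
#'   anywhere in `degs`.
#' @param signed use [impact_direction_value()] instead of
#'   [pathway_impact()].
#' @return Numeric matrix (pathways x contrasts).
#' @export
impact_matrix_from_degs <- function(degs, gene_universe = NULL,
                                    signed = FALSE) {
  pathways <- sort(unique(unlist(degs$pathway_ids)))
  contrasts <- unique(degs$contrast)
  if (is.null(gene_universe)) {
    gene_universe <- vapply(pathways, function(p) {
      length(unique(.degs_in_pathway(degs, p)$gene_id))
    }, numeric(1L))
  }
  missing_size <- setdiff(pathways, names(gene_universe))
  if (length(missing_size) > 0L)
    stop("no gene_universe entry for pathway(s): ",
         paste(missing_size, collapse = ", "))
  score <- if (signed) impact_direction_value else pathway_impact
  out <- matrix(NA_real_, length(pathways), length(contrasts),
                dimnames = list(pathways, contrasts))
  for (ct in contrasts) {
    slice <- degs[degs$contrast == ct, , drop = FALSE]
    for (p in pathways)
      out[p, ct] <- score(slice, p, gene_universe[[p]])
  }
  out
}
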