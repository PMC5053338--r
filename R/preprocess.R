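## Missing-data handling before modelling. Pathways with too many missing
## contrasts are dropped; sparse gaps are filled with the mean of the
## pathway's observed values (a row mean, not a column mean, so each pathway
## is completed from its own time course).

#' Filter heavily missing pathways and impute the rest
#'
#' Rows whose missing-value count reaches `max_missing` are removed and
#' logged; remaining missing cells are replaced by the mean of the row's
#' observed values. Observed cells are never changed.
#'
#' @param m numeric impact matrix (pathways x contrasts), missing values
#'   as `NA`.
#' @param max_missing remove a row when it has at least this many missing
#'   values (default 3).
#' @return List with `matrix` (no missing values) and `log`, a data frame of
#'   removed pathways with columns `pathway_id` and `reason`.
#' @export
filter_and_impute <- function(m, max_missing = 3) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (ncol(m) == 0L) stop("impact matrix has no contrast columns")
  if (ncol(m) < 2L) stop("need at least 2 contrasts to impute")
  if (max_missing < 1) stop("max_missing must be >= 1")

  n_missing <- rowSums(is.na(m))
  drop <- n_missing >= max_missing
  all_missing_kept <- !drop & n_missing == ncol(m)
  if (any(all_missing_kept))
    stop("pathway(s) with all values missing cannot be imputed: ",
         paste(rownames(m)[all_missing_kept], collapse = ", "))

  log <- data.frame(
    pathway_id = rownames(m)[drop],
    reason = sprintf("missing_count=%d>=max_missing=%d",
                     n_missing[drop], as.integer(max_missing)),
    stringsAsFactors = FALSE)

  kept <- m[!drop, , drop = FALSE]
  for (i in which(rowSums(is.na(kept)) > 0L)) {
    row <- kept[i, ]
    row[is.na(row)] <- mean(row, na.rm = TRUE)
    kept[i, ] <- row
  }
  list(matrix = kept, log = log)
}

#' Drop zero-variance pathways
#'
#' Pearson correlation is undefined for a constant row, so rows whose values
#' are all identical (including rows that became constant through
#' imputation) are removed and logged.
#'
#' @param m numeric impact matrix without missing values.
#' @return List with `matrix` and `log` as in [filter_and_impute()].
#' @export
drop_degenerate <- function(m) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (anyNA(m)) stop("drop_degenerate() expects a complete matrix")
  constant <- apply(m, 1L, function(row) all(row == row[1L]))
  log <- data.frame(pathway_id = rownames(m)[constant],
                    reason = rep("zero_variance", sum(constant)),
                    stringsAsFactors = FALSE)
  list(matrix = m[!constant, , drop = FALSE], log = log)
}
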