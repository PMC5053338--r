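## Plain-text input/output for hierarchies, impact matrices, DEG tables and
## decision reports. Everything is UTF-8 TSV with a header row; "" and "NA"
## are accepted as missing tokens.

.hierarchy_levels <- c("category", "subcategory", "secondary")

#' Construct and validate a pathway hierarchy
#'
#' A pathway hierarchy is a three-level tree: categories at the top,
#' subcategories below them, secondary pathways at the bottom. Each
#' non-category node names exactly one parent one level above it; categories
#' have an empty `parent_id`. Deeper nesting and multi-parent structures
#' (GO-style DAGs) are rejected.
#'
#' @param nodes data frame with columns `level`, `id`, `name`, `parent_id`.
#' @return The validated data frame with class `pathway_hierarchy`.
#' @seealso [read_pathway_hierarchy()]
#' @export
pathway_hierarchy <- function(nodes) {
  required <- c("level", "id", "name", "parent_id")
  missing_cols <- setdiff(required, names(nodes))
  if (length(missing_cols) > 0L)
    stop("hierarchy is missing column(s): ", paste(missing_cols, collapse = ", "))
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)[required]
  for (col in required) nodes[[col]] <- as.character(nodes[[col]])
  nodes$parent_id[is.na(nodes$parent_id)] <- ""

  bad_level <- !nodes$level %in% .hierarchy_levels
  if (any(bad_level))
    stop("unknown hierarchy level(s): ",
         paste(unique(nodes$level[bad_level]), collapse = ", "))
  if (anyDuplicated(nodes$id))
    stop("duplicate pathway id(s): ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  if (any(!nzchar(nodes$id))) stop("empty pathway id")

  is_cat <- nodes$level == "category"
  if (any(is_cat & nzchar(nodes$parent_id)))
    stop("category nodes must not declare a parent")
  if (any(!is_cat & !nzchar(nodes$parent_id)))
    stop("non-category node without parent_id: ",
         paste(nodes$id[!is_cat & !nzchar(nodes$parent_id)], collapse = ", "))

  parent_level <- nodes$level[match(nodes$parent_id, nodes$id)]
  for (i in which(!is_cat)) {
    pl <- parent_level[i]
    if (is.na(pl))
      stop("node '", nodes$id[i], "' references missing parent '",
           nodes$parent_id[i], "'")
    expected <- .hierarchy_levels[match(nodes$level[i], .hierarchy_levels) - 1L]
    if (pl != expected)
      stop("node '", nodes$id[i], "' (", nodes$level[i],
           ") must have a ", expected, " parent, not a ", pl)
  }
  ## With the one-level-up rule verified, edges always point from a lower to
  ## a strictly higher level, so the structure is acyclic by construction.
  class(nodes) <- c("pathway_hierarchy", "data.frame")
  nodes
}

#' Read a pathway hierarchy from TSV
#'
#' Expects header columns `level`, `id`, `name`, `parent_id`; `level` is one
#' of `category`, `subcategory`, `secondary`.
#'
#' @param path file path.
#' @return A [pathway_hierarchy()] object.
#' @export
read_pathway_hierarchy <- function(path) {
  raw <- tryCatch(
    read.delim(path, colClasses = "character", na.strings = NULL,
               check.names = FALSE, fileEncoding = "UTF-8"),
    error = function(e) stop("cannot parse hierarchy file '", path, "': ",
                             conditionMessage(e)))
  n_fields <- utils::count.fields(path, sep = "\t", quote = "\"",
                                  blank.lines.skip = TRUE)
  bad <- which(n_fields != n_fields[1L])
  if (length(bad) > 0L)
    stop("malformed hierarchy row at line ", bad[1L], " of '", path,
         "': expected ", n_fields[1L], " fields, found ", n_fields[bad[1L]])
  pathway_hierarchy(raw)
}

#' Write a pathway hierarchy to TSV
#'
#' @param hierarchy a [pathway_hierarchy()] object.
#' @param path file path.
#' @return Invisibly, `path`.
#' @export
write_pathway_hierarchy <- function(hierarchy, path) {
  stopifnot(inherits(hierarchy, "pathway_hierarchy"))
  write.table(as.data.frame(hierarchy), path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Children of a hierarchy node
#'
#' @param hierarchy a [pathway_hierarchy()] object.
#' @param parent_id node identifier.
#' @return Character vector of child ids (possibly empty).
#' @export
hierarchy_children <- function(hierarchy, parent_id) {
  stopifnot(inherits(hierarchy, "pathway_hierarchy"))
  hierarchy$id[hierarchy$parent_id == parent_id]
}

#' Read a pathway-by-contrast impact matrix from TSV
#'
#' First column holds pathway identifiers, remaining columns hold numeric
#' impact values for each contrast (time point or treatment comparison) in
#' observation order. Empty cells and the token `NA` are read as missing,
#' never as zero; any other non-numeric cell is a parse error.
#'
#' @param path file path.
#' @return Numeric matrix, rows named by pathway id, columns by contrast
#'   label in file order.
#' @export
read_impact_matrix <- function(path) {
  raw <- read.delim(path, colClasses = "character", na.strings = NULL,
                    check.names = FALSE, fileEncoding = "UTF-8")
  if (ncol(raw) < 2L)
    stop("impact matrix '", path, "' needs an id column plus >= 1 contrast")
  ids <- raw[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate pathway id(s) in impact matrix: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  out <- matrix(NA_real_, nrow(vals), ncol(vals),
                dimnames = list(ids, colnames(raw)[-1L]))
  for (j in seq_len(ncol(vals))) {
    cell <- vals[, j]
    is_missing <- cell %in% c("", "NA")
    num <- suppressWarnings(as.numeric(cell))
    bad <- !is_missing & is.na(num)
    if (any(bad))
      stop("non-numeric cell '", cell[which(bad)[1L]], "' at line ",
           which(bad)[1L] + 1L, ", column '", colnames(out)[j],
           "' of '", path, "'")
    num[is_missing] <- NA_real_
    out[, j] <- num
  }
  out
}

#' Write an impact matrix to TSV
#'
#' Values are written with 12 significant digits so that a write/read
#' round trip is value-exact at that precision; missing cells are written
#' as `NA`.
#'
#' @param m numeric matrix with row and column names.
#' @param path file path.
#' @param id_column header for the identifier column.
#' @return Invisibly, `path`.
#' @export
write_impact_matrix <- function(m, path, id_column = "pathway_id") {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  txt <- matrix(sprintf("%.12g", m), nrow(m), ncol(m))
  txt[is.na(m)] <- "NA"
  df <- data.frame(rownames(m), txt, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c(id_column, colnames(m))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a differential-expression table from TSV
#'
#' Expected columns: `gene_id`, `contrast`, `log2fc`, `pvalue`, `is_deg`
#' (logical or 0/1), `pathway_ids` (semicolon-separated pathway
#' memberships). Every record must carry a p-value in (0, 1] and at least
#' one pathway.
#'
#' @param path file path.
#' @return Data frame; `pathway_ids` is a list column of character vectors.
#' @export
read_deg_table <- function(path) {
  raw <- read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  required <- c("gene_id", "contrast", "log2fc", "pvalue", "is_deg",
                "pathway_ids")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L)
    stop("DEG table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  raw$log2fc <- as.numeric(raw$log2fc)
  raw$pvalue <- as.numeric(raw$pvalue)
  raw$is_deg <- as.logical(raw$is_deg)
  if (any(!is.finite(raw$pvalue)) || any(raw$pvalue <= 0) ||
      any(raw$pvalue > 1))
    stop("DEG p-values must lie in (0, 1]")
  raw$pathway_ids <- strsplit(as.character(raw$pathway_ids), ";", fixed = TRUE)
  if (any(lengths(raw$pathway_ids) == 0L))
    stop("every DEG record must be attached to at least one pathway")
  raw
}

.report_numeric_cols <- function(alphas) {
  c("b_star", "direct_factor", "indirect_factor", "dc",
    sprintf("cutoff_%.2f", alphas), "decision_percentage")
}

#' Write a decision report to TSV
#'
#' One row per child pathway with the fitted path coefficient, the direct
#' and indirect determination factors, the decision coefficient, its
#' significance cutoffs, the levels at which it is significant, the impact
#' direction call and the decision percentage within its parent. Numeric
#' columns are written with 6 decimal places.
#'
#' @param report data frame as produced by [decision_analysis()] (or a
#'   row-bound collection of them); may have zero rows.
#' @param path file path.
#' @param alphas significance levels whose cutoff columns are present.
#' @return Invisibly, `path`.
#' @export
write_decision_report <- function(report, path,
                                  alphas = c(0.01, 0.05, 0.1)) {
  cols <- c("parent_id", "child_id", .report_numeric_cols(alphas))
  cols <- append(cols, c("significant_at", "direction"), after = length(cols) - 1L)
  missing_cols <- setdiff(cols, names(report))
  if (length(missing_cols) > 0L)
    stop("decision report is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  out <- report[, cols, drop = FALSE]
  for (col in .report_numeric_cols(alphas))
    out[[col]] <- sprintf("%.6f", out[[col]])
  if (nrow(report) == 0L) out <- out[0L, , drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a decision report written by [write_decision_report()]
#'
#' @param path file path.
#' @return Data frame with numeric score columns.
#' @export
read_decision_report <- function(path) {
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character", fileEncoding = "UTF-8")
  for (col in setdiff(names(raw),
                      c("parent_id", "child_id", "significant_at",
                        "direction")))
    raw[[col]] <- as.numeric(raw[[col]])
  raw
}

#' Write a removal log (pathway_id, reason) to TSV
#'
#' @param log data frame with columns `pathway_id` and `reason`.
#' @param path file path.
#' @return Invisibly, `path`.
#' @export
write_removal_log <- function(log, path) {
  stopifnot(all(c("pathway_id", "reason") %in% names(log)))
  write.table(log[, c("pathway_id", "reason")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a labelled subdivision matrix to TSV
#'
#' The diagonal holds the direct determination factors, off-diagonal cells
#' the pairwise indirect determination factors; column sums are the decision
#' coefficients.
#'
#' @param s square numeric matrix with matching row/column names.
#' @param path file path.
#' @return Invisibly, `path`.
#' @export
write_subdivision_matrix <- function(s, path) {
  stopifnot(is.matrix(s), nrow(s) == ncol(s),
            identical(rownames(s), colnames(s)))
  txt <- matrix(sprintf("%.6f", s), nrow(s), ncol(s))
  df <- data.frame(rownames(s), txt, stringsAsFactors = FALSE,
                   check.names = FALSE)
  names(df) <- c("pathway_id", colnames(s))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
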