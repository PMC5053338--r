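## Decision-tree assembly and export. Every edge of the hierarchy is
## annotated with the child's decision percentage within its parent; every
## scored node carries its decision coefficient and direction. Activated
## nodes render red, inhibited nodes blue, neutral grey; unscored nodes stay
## uncolored. Percentages are local to each parent, so sibling edge labels
## sum to 100 at every level independently.

#' Build an annotated decision tree
#'
#' @param hierarchy a [pathway_hierarchy()].
#' @param report decision report rows for one or more parents (the `report`
#'   element of [decision_analysis()], row-bound across parents), with
#'   columns `parent_id`, `child_id`, `dc`, `direction`,
#'   `decision_percentage`.
#' @return Object of class `decision_tree`: the hierarchy plus a node
#'   annotation table.
#' @export
build_decision_tree <- function(hierarchy, report) {
  stopifnot(inherits(hierarchy, "pathway_hierarchy"))
  needed <- c("parent_id", "child_id", "dc", "direction",
              "decision_percentage")
  missing_cols <- setdiff(needed, names(report))
  if (length(missing_cols) > 0L)
    stop("report is missing column(s): ",
         paste(missing_cols, collapse = ", "))

  unknown <- setdiff(c(report$parent_id, report$child_id), hierarchy$id)
  if (length(unknown) > 0L)
    stop("report references node(s) absent from the hierarchy: ",
         paste(unknown, collapse = ", "))
  declared <- hierarchy$parent_id[match(report$child_id, hierarchy$id)]
  bad <- declared != report$parent_id
  if (any(bad))
    stop("report parent mismatch for child(ren): ",
         paste(report$child_id[bad], collapse = ", "))
  if (anyDuplicated(report$child_id))
    stop("duplicate child annotation(s): ",
         paste(unique(report$child_id[duplicated(report$child_id)]),
               collapse = ", "))
  for (p in unique(report$parent_id)) {
    dp_sum <- sum(report$decision_percentage[report$parent_id == p])
    if (abs(dp_sum - 100) > 1e-8)
      stop("decision percentages under parent '", p, "' sum to ",
           format(dp_sum, digits = 10), ", not 100")
  }
  structure(list(hierarchy = hierarchy,
                 annotations = report[, needed, drop = FALSE]),
            class = "decision_tree")
}

.dot_quote <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')

.tree_node_json <- function(tree, id) {
  h <- tree$hierarchy
  ann <- tree$annotations
  i <- match(id, ann$child_id)
  node <- list(id = id, name = h$name[match(id, h$id)])
  if (!is.na(i)) {
    node$dc <- ann$dc[i]
    node$direction <- ann$direction[i]
    node$dp <- ann$decision_percentage[i]
  }
  kids <- hierarchy_children(h, id)
  node$children <- lapply(kids, function(k) .tree_node_json(tree, k))
  node
}

#' Export a decision tree as Graphviz DOT or JSON
#'
#' DOT output colors activated nodes red, inhibited nodes blue and neutral
#' nodes grey, and labels each annotated edge with the child's decision
#' percentage to one decimal. JSON output nests parents over their children
#' with keys `id`, `name`, `dc`, `direction`, `dp`, `children`; numeric
#' annotations survive a parse round trip losslessly.
#'
#' @param tree a [build_decision_tree()] result.
#' @param format `"dot"` or `"json"`.
#' @return A single character string.
#' @export
export_tree <- function(tree, format = c("dot", "json")) {
  stopifnot(inherits(tree, "decision_tree"))
  format <- match.arg(format)
  h <- tree$hierarchy
  ann <- tree$annotations

  if (format == "json") {
    roots <- lapply(h$id[h$level == "category"],
                    function(id) .tree_node_json(tree, id))
    return(as.character(jsonlite::toJSON(roots, auto_unbox = TRUE,
                                         digits = NA, null = "null")))
  }

  colors <- c(activated = "red", inhibited = "blue", neutral = "grey")
  lines <- c("digraph decision_tree {", "  node [shape=box];")
  for (i in seq_len(nrow(h))) {
    id <- h$id[i]
    j <- match(id, ann$child_id)
    attrs <- sprintf("label=%s", .dot_quote(h$name[i]))
    if (!is.na(j)) {
      attrs <- c(attrs,
                 sprintf("color=%s", colors[[ann$direction[j]]]),
                 sprintf("tooltip=\"DC=%.4f\"", ann$dc[j]))
    }
    lines <- c(lines, sprintf("  %s [%s];", .dot_quote(id),
                              paste(attrs, collapse = ", ")))
  }
  for (i in which(nzchar(h$parent_id))) {
    id <- h$id[i]
    j <- match(id, ann$child_id)
    label <- if (!is.na(j))
      sprintf(" [label=\"%.1f%%\"]", ann$decision_percentage[j]) else ""
    lines <- c(lines, sprintf("  %s -> %s%s;", .dot_quote(h$parent_id[i]),
                              .dot_quote(id), label))
  }
  paste(c(lines, "}"), collapse = "\n")
}
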