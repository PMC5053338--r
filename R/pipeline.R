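## End-to-end orchestration: preprocess -> per-parent path model ->
## decision analysis -> report, subdivision matrices and tree exports.
## Per-parent models are independent; parents are processed in hierarchy
## order purely for deterministic output files.

.analyzable_parents <- function(hierarchy, m, min_contrasts = 3L) {
  parents <- hierarchy$id[hierarchy$level %in% c("category", "subcategory")]
  keep <- character(0)
  for (p in parents) {
    kids <- hierarchy_children(hierarchy, p)
    kids_present <- intersect(kids, rownames(m))
    if (length(kids_present) == 0L || !(p %in% rownames(m))) next
    if (length(kids_present) < 2L) {
      warning("parent '", p, "' skipped: fewer than 2 children with ",
              "impact rows (correlation structure degenerate)")
      next
    }
    keep <- c(keep, p)
  }
  keep
}

#' Run the full decision-analysis pipeline
#'
#' Reads a hierarchy and an impact matrix, applies the missing-data rules,
#' fits a path model for every parent whose own impact row and at least two
#' children's rows survive preprocessing, and writes the combined decision
#' report, one subdivision matrix per parent, DOT and JSON tree exports, a
#' removal log and a reproducibility log (input digests, options, package
#' version) into `out_dir`. Output is byte-identical across reruns on the
#' same inputs and options.
#'
#' @param hierarchy_path TSV hierarchy file (see
#'   [read_pathway_hierarchy()]).
#' @param impact_path TSV impact matrix (see [read_impact_matrix()]).
#' @param out_dir output directory, created if needed.
#' @param alphas significance levels for t-based cutoffs.
#' @param dc_threshold fixed decision-coefficient threshold for the
#'   most-impacted flag.
#' @param max_missing row-removal threshold, see [filter_and_impute()].
#' @param strict error (instead of pseudo-inverse + warning) on a
#'   near-singular correlation matrix.
#' @param seed recorded in the run log; the analysis itself is
#'   deterministic.
#' @return Invisibly, a list with `report`, `models`, `skipped` and
#'   `files`.
#' @export
run_analyze <- function(hierarchy_path, impact_path, out_dir,
                        alphas = c(0.01, 0.05, 0.1), dc_threshold = 0.4,
                        max_missing = 3, strict = FALSE, seed = NULL) {
  hierarchy <- read_pathway_hierarchy(hierarchy_path)
  m_raw <- read_impact_matrix(impact_path)
  pre <- filter_and_impute(m_raw, max_missing = max_missing)
  deg <- drop_degenerate(pre$matrix)
  m <- deg$matrix
  removal_log <- rbind(pre$log, deg$log)

  parents <- .analyzable_parents(hierarchy, m)
  if (length(parents) == 0L)
    stop("no analyzable parent: every parent lacks an impact row or ",
         "has fewer than 2 children with impact rows")

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  models <- list()
  reports <- list()
  sub_files <- character(0)
  for (p in parents) {
    kids <- intersect(hierarchy_children(hierarchy, p), rownames(m))
    model <- tryCatch(
      fit_path_model(m[kids, , drop = FALSE], m[p, ], parent_id = p,
                     strict = strict),
      error = function(e) stop("parent '", p, "': ", conditionMessage(e)))
    da <- decision_analysis(model, alphas = alphas,
                            dc_threshold = dc_threshold)
    models[[p]] <- model
    reports[[p]] <- da$report
    sub_path <- file.path(out_dir, sprintf("subdivision_%s.tsv",
                                           gsub("[^A-Za-z0-9._-]", "_", p)))
    write_subdivision_matrix(da$subdivision, sub_path)
    sub_files <- c(sub_files, sub_path)
  }
  report <- do.call(rbind, c(reports, list(make.row.names = FALSE)))

  report_path <- file.path(out_dir, "decision_report.tsv")
  write_decision_report(report, report_path, alphas = sort(alphas))
  tree <- build_decision_tree(hierarchy, report)
  dot_path <- file.path(out_dir, "decision_tree.dot")
  json_path <- file.path(out_dir, "decision_tree.json")
  writeLines(export_tree(tree, "dot"), dot_path)
  writeLines(export_tree(tree, "json"), json_path)
  removal_path <- file.path(out_dir, "removal_log.tsv")
  write_removal_log(removal_log, removal_path)

  log_path <- file.path(out_dir, "run_log.tsv")
  digests <- tools::md5sum(c(hierarchy_path, impact_path))
  log <- data.frame(
    key = c("package_version", "hierarchy_md5", "impact_md5", "alphas",
            "dc_threshold", "max_missing", "strict", "seed", "parents"),
    value = c(as.character(packageVersion("pathdc")),
              unname(digests[1L]), unname(digests[2L]),
              paste(sort(alphas), collapse = ","),
              format(dc_threshold), format(max_missing),
              as.character(strict),
              if (is.null(seed)) "NA" else format(seed),
              paste(parents, collapse = ",")),
    stringsAsFactors = FALSE)
  write.table(log, log_path, sep = "\t", quote = FALSE, row.names = FALSE)

  invisible(list(report = report, models = models,
                 skipped = removal_log,
                 files = c(report = report_path, dot = dot_path,
                           json = json_path, removal = removal_path,
                           log = log_path, sub_files)))
}

#' Simulate an impact dataset to file
#'
#' @param out_path TSV destination for the simulated impact matrix
#'   (children rows plus parent row `y`).
#' @param q,n,noise_sd,seed passed to [simulation_config()].
#' @param rho exchangeable child-child correlation.
#' @return Invisibly, the simulated matrix.
#' @export
run_simulate <- function(out_path, q = 4, n = 50, noise_sd = NULL,
                         rho = 0.3, seed = 1) {
  config <- simulation_config(q = q,
                              R_x_target = exchangeable_correlation(q, rho),
                              n = n, noise_sd = noise_sd, seed = seed)
  m <- simulate_dataset(config)
  write_impact_matrix(m, out_path)
  invisible(m)
}

#' Compute an impact matrix from a DEG table file
#'
#' @param deg_path DEG TSV (see [read_deg_table()]).
#' @param out_path destination impact-matrix TSV.
#' @param sizes_path optional TSV with columns `pathway_id`, `n_genes`
#'   giving the annotated-gene universe per pathway; defaults to the genes
#'   observed in the DEG table.
#' @param signed write signed direction values instead of impact
#'   magnitudes.
#' @return Invisibly, the impact matrix.
#' @export
run_impact <- function(deg_path, out_path, sizes_path = NULL,
                       signed = FALSE) {
  degs <- read_deg_table(deg_path)
  universe <- NULL
  if (!is.null(sizes_path)) {
    sizes <- read.delim(sizes_path, stringsAsFactors = FALSE)
    stopifnot(all(c("pathway_id", "n_genes") %in% names(sizes)))
    universe <- setNames(as.numeric(sizes$n_genes), sizes$pathway_id)
  }
  m <- impact_matrix_from_degs(degs, gene_universe = universe,
                               signed = signed)
  write_impact_matrix(m, out_path)
  invisible(m)
}

#' Compare direction calls (and optionally rankings) from two methods
#'
#' Each input is a TSV with columns `pathway_id`, `direction` and
#' optionally `score`; rows are aligned by pathway id, which must coincide
#' between the files.
#'
#' @param path_a,path_b input files.
#' @param a optional top-a size for the most-impacted overlap (requires
#'   `score` columns in both files).
#' @return List with `direction` ([direction_concordance()] result) and,
#'   when `a` is given, `top_a` ([top_a_overlap()] result).
#' @export
run_compare <- function(path_a, path_b, a = NULL) {
  read_cmp <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("pathway_id", "direction") %in% names(df)))
    df
  }
  da <- read_cmp(path_a)
  db <- read_cmp(path_b)
  if (!setequal(da$pathway_id, db$pathway_id))
    stop("the two files must cover the same pathways")
  db <- db[match(da$pathway_id, db$pathway_id), , drop = FALSE]
  out <- list(direction = direction_concordance(da$direction, db$direction))
  if (!is.null(a)) {
    if (!all(c("score") %in% names(da)) || !all(c("score") %in% names(db)))
      stop("top-a comparison needs a 'score' column in both files")
    out$top_a <- top_a_overlap(setNames(da$score, da$pathway_id),
                               setNames(db$score, db$pathway_id), a)
  }
  out
}
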