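## Standardized path-analysis model for one parent node of the hierarchy.
##
## Observations are the contrasts (time points); variables are the child
## pathways x_1..x_q plus the parent response y. All statistics are computed
## from Pearson correlations, so standardization of the raw impact values is
## implicit: the path coefficients b* solve the normal equations
## R_x b* = R_xy and coincide with the coefficients of an ordinary
## least-squares fit on standardized data.

#' Correlation structure of a parent model
#'
#' Computes the Pearson correlation matrix of the child pathways and their
#' correlation vector with the parent response over the shared contrasts.
#'
#' @param x_block numeric matrix, one row per child pathway, columns =
#'   contrasts (at least 3).
#' @param y_row numeric vector of the parent's impact values, same length as
#'   `ncol(x_block)`.
#' @return List with `R_x` (q x q, unit diagonal, symmetric), `R_xy`
#'   (length q) and `n` (number of contrasts).
#' @export
correlation_structure <- function(x_block, y_row) {
  stopifnot(is.matrix(x_block), is.numeric(x_block))
  y_row <- as.numeric(y_row)
  n <- ncol(x_block)
  if (length(y_row) != n)
    stop("parent row length (", length(y_row),
         ") does not match contrast count (", n, ")")
  if (n < 3L) stop("need at least 3 contrasts to estimate correlations")
  if (anyNA(x_block) || anyNA(y_row))
    stop("missing values must be handled before correlation")
  sds <- apply(x_block, 1L, sd)
  if (any(sds == 0) || sd(y_row) == 0)
    stop("zero-variance row(s); run drop_degenerate() first: ",
         paste(rownames(x_block)[sds == 0], collapse = ", "))
  R_x <- cor(t(x_block))
  R_x <- (R_x + t(R_x)) / 2  # kill floating asymmetry
  diag(R_x) <- 1
  R_xy <- as.vector(cor(t(x_block), y_row))
  names(R_xy) <- rownames(x_block)
  list(R_x = R_x, R_xy = R_xy, n = n)
}

#' Solve the path-coefficient system
#'
#' Solves `R_x b* = R_xy` for the standardized path coefficients (direct
#' effects) and returns the diagonal of the inverse correlation matrix,
#' which enters the decision-coefficient cutoff. A reciprocal condition
#' number below `1/cond_tol` marks the system as near-singular: in
#' permissive mode the Moore-Penrose pseudo-inverse is used and a warning is
#' emitted, in strict mode an error is raised.
#'
#' @param R_x correlation matrix of the children.
#' @param R_xy correlation vector of children with the parent.
#' @param strict raise an error on a near-singular `R_x` instead of falling
#'   back to the pseudo-inverse.
#' @param cond_tol condition-number threshold (default `1e12`).
#' @return List with `b_star`, `c_diag` (diagonal of the (pseudo-)inverse)
#'   and `condition_flag`.
#' @export
solve_path_coefficients <- function(R_x, R_xy, strict = FALSE,
                                    cond_tol = 1e12) {
  stopifnot(is.matrix(R_x), nrow(R_x) == ncol(R_x),
            length(R_xy) == nrow(R_x))
  if (max(abs(R_x - t(R_x))) > 1e-8 || max(abs(diag(R_x) - 1)) > 1e-8)
    stop("R_x must be a symmetric unit-diagonal correlation matrix")
  rc <- rcond(R_x)
  flagged <- !is.finite(rc) || rc < 1 / cond_tol
  if (flagged) {
    if (strict)
      stop("correlation matrix is (near-)singular: reciprocal condition ",
           "number ", format(rc, digits = 3), "; reduce the number of ",
           "children or add contrasts")
    warning("near-singular correlation matrix (rcond = ",
            format(rc, digits = 3), "); using pseudo-inverse, ",
            "cutoffs may be unreliable")
    inv <- MASS::ginv(R_x)
    b_star <- as.vector(inv %*% R_xy)
  } else {
    inv <- solve(R_x)
    b_star <- as.vector(inv %*% R_xy)
  }
  names(b_star) <- names(R_xy)
  c_diag <- diag(inv)
  names(c_diag) <- names(R_xy)
  list(b_star = b_star, c_diag = c_diag, condition_flag = flagged)
}

#' Assemble a path model from components
#'
#' Low-level constructor; most callers should use [fit_path_model()]. The
#' coefficient of determination is taken as `sum(b_star * R_xy)`, the
#' standardized-regression identity.
#'
#' @param parent_id,child_ids identifiers.
#' @param n number of contrasts the correlations were estimated from.
#' @param R_x,R_xy,b_star,c_diag model components (see
#'   [solve_path_coefficients()]).
#' @param condition_flag `TRUE` when `R_x` was near-singular.
#' @param check verify the normal equations `R_x b* = R_xy`.
#' @param tol tolerance for the normal-equation check, scaled by q.
#' @return Object of class `path_model`.
#' @export
path_model <- function(parent_id, child_ids, n, R_x, R_xy, b_star, c_diag,
                       condition_flag = FALSE, check = TRUE, tol = 1e-8) {
  q <- length(child_ids)
  stopifnot(length(R_xy) == q, length(b_star) == q, length(c_diag) == q,
            nrow(R_x) == q)
  if (check && !condition_flag) {
    resid <- max(abs(R_x %*% b_star - R_xy))
    if (resid >= tol * q)
      stop("normal equations violated: max |R_x b* - R_xy| = ",
           format(resid, digits = 4))
  }
  R2 <- sum(b_star * R_xy)
  structure(
    list(parent_id = parent_id,
         child_ids = as.character(child_ids),
         n = as.integer(n), q = q,
         R_x = R_x, R_xy = R_xy, b_star = b_star,
         R2 = R2, c_diag = c_diag,
         condition_flag = isTRUE(condition_flag)),
    class = "path_model")
}

#' Fit the path model for one parent node
#'
#' @param x_block numeric matrix of child impact values (children x
#'   contrasts), rows named by child id.
#' @param y_row numeric vector of parent impact values.
#' @param parent_id parent identifier (for reporting).
#' @param strict,cond_tol passed to [solve_path_coefficients()].
#' @return Object of class `path_model`.
#' @examples
#' sim <- simulate_dataset(simulation_config(q = 3, n = 30, seed = 1))
#' fit_path_model(sim[1:3, ], sim["y", ], parent_id = "parent")
#' @export
fit_path_model <- function(x_block, y_row, parent_id = "parent",
                           strict = FALSE, cond_tol = 1e12) {
  cs <- correlation_structure(x_block, y_row)
  sol <- solve_path_coefficients(cs$R_x, cs$R_xy, strict = strict,
                                 cond_tol = cond_tol)
  child_ids <- rownames(x_block)
  if (is.null(child_ids)) child_ids <- paste0("x", seq_len(nrow(x_block)))
  path_model(parent_id, child_ids, cs$n, cs$R_x, cs$R_xy,
             sol$b_star, sol$c_diag, sol$condition_flag)
}

#' @export
print.path_model <- function(x, ...) {
  cat("Path model for parent '", x$parent_id, "': q = ", x$q,
      " children, n = ", x$n, " contrasts\n", sep = "")
  cat("  R2 =", format(x$R2, digits = 4),
      if (x$condition_flag) " (near-singular R_x, pseudo-inverse used)",
      "\n")
  print(data.frame(child = x$child_ids, b_star = x$b_star,
                   r_jy = x$R_xy, row.names = NULL), ...)
  invisible(x)
}

#' Decompose total effects into direct, indirect and retro parts
#'
#' For every child j, the total effect (its correlation `r_jy` with the
#' parent) splits as the direct effect `b*_j` plus the indirect effects
#' `r_jk b*_k` transmitted through each correlated sibling k. The
#' retro-regulation `sum_k r_kj b*_j` aggregates the influence child j
#' exerts back on its siblings; it is what distinguishes decision-coefficient
#' ranking from ranking by total effect alone.
#'
#' @param model a `path_model`.
#' @return List with `table`, a data frame (child_id, direct, indirect_sum,
#'   total, retro), and `components`, the q x q matrix whose (j, k) entry is
#'   `r_jk b*_k` (diagonal `NA`).
#' @export
effect_decomposition <- function(model) {
  stopifnot(inherits(model, "path_model"))
  b <- model$b_star
  comp <- model$R_x * rep(b, each = model$q)  # comp[j, k] = r_jk * b_k
  diag(comp) <- NA_real_
  dimnames(comp) <- list(model$child_ids, model$child_ids)
  indirect_sum <- rowSums(comp, na.rm = TRUE)
  retro <- b * (colSums(model$R_x) - 1)
  list(
    table = data.frame(
      child_id = model$child_ids,
      direct = unname(b),
      indirect_sum = unname(indirect_sum),
      total = unname(model$R_xy),
      retro = unname(retro),
      stringsAsFactors = FALSE),
    components = comp)
}

#' Decompose the coefficient of determination
#'
#' The model's R-squared splits into a direct part `sum_j (b*_j)^2` and an
#' indirect part `sum_{j<t} 2 b*_j r_jt b*_t`; their total equals both
#' `sum_j b*_j r_jy` and `1 - SS_res/SS_tot` of the standardized
#' regression. The reported ratios are direct/R2 and |indirect|/R2; when the
#' indirect part is negative they do not sum to one.
#'
#' @param model a `path_model`.
#' @return List with `direct_cd`, `indirect_cd`, `total_cd`, `direct_ratio`
#'   and `indirect_ratio`.
#' @export
coefficient_of_determination <- function(model) {
  stopifnot(inherits(model, "path_model"))
  b <- model$b_star
  direct <- sum(b^2)
  total <- as.numeric(t(b) %*% model$R_x %*% b)
  indirect <- total - direct
  list(direct_cd = direct,
       indirect_cd = indirect,
       total_cd = total,
       direct_ratio = direct / total,
       indirect_ratio = abs(indirect) / total)
}
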