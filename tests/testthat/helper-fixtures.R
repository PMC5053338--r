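# Fixtures are built in code at test time; no binary data ships with the
# package.

# random correlation matrix, strictly positive definite
random_spd_correlation <- function(q) {
  a <- matrix(rnorm(q * q), q)
  stats::cov2cor(crossprod(a) + 0.5 * diag(q))
}

# simulate one dataset and fit its parent model
fitted_sim_model <- function(q = 3, n = 50, seed = 1, rho = 0.3) {
  config <- simulation_config(q = q,
                              R_x_target = exchangeable_correlation(q, rho),
                              n = n, seed = seed)
  data <- simulate_dataset(config)
  fit_path_model(data[seq_len(q), , drop = FALSE], data["y", ])
}

# consistent model straight from components: R_xy implied by R_x and b
model_from_components <- function(R_x, b_star, n = 50,
                                  ids = paste0("x", seq_along(b_star))) {
  dimnames(R_x) <- list(ids, ids)
  names(b_star) <- ids
  path_model(parent_id = "parent", child_ids = ids, n = n, R_x = R_x,
             R_xy = as.vector(R_x %*% b_star), b_star = b_star,
             c_diag = diag(solve(R_x)))
}

write_tsv_text <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# minimal valid three-level chain
chain_hierarchy_lines <- c(
  "level\tid\tname\tparent_id",
  "category\tcat1\tMetabolism\t",
  "subcategory\tsub1\tLipid Metabolism\tcat1",
  "secondary\tsec1\tFatty acid metabolism\tsub1")

# toy DEG table: 4 annotated genes, 2 of them DEG, one pathway
toy_deg_lines <- c(
  "gene_id\tcontrast\tlog2fc\tpvalue\tis_deg\tpathway_ids",
  "g1\tt1\t1\t0.01\tTRUE\tpw1",
  "g2\tt1\t-3\t0.0001\tTRUE\tpw1",
  "g3\tt1\t0.1\t0.5\tFALSE\tpw1",
  "g4\tt1\t-0.2\t0.9\tFALSE\tpw1")
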