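test_that("correlation structure matches hand-computed Pearson values", {
  x <- rbind(a = c(1, 2, 3), b = c(3, 2, 1))
  cs <- correlation_structure(x, c(1, 2, 3))
  expect_equal(cs$R_x["a", "a"], 1)
  expect_equal(cs$R_x["a", "b"], -1)
  expect_equal(unname(cs$R_xy), c(1, -1))

  # hand Pearson oracle: rows (1,2,4) and (2,2,5) -> r = 0.9449
  cs2 <- correlation_structure(rbind(a = c(1, 2, 4), b = c(2, 2, 5)),
                               c(0, 1, 2))
  expect_equal(cs2$R_x["a", "b"], 0.9449, tolerance = 1e-4)
  expect_equal(cs2$R_x["a", "b"], 2.5 / (sqrt(7 / 3) * sqrt(3)),
               tolerance = 1e-12)
})

test_that("correlation structure rejects short, incomplete or flat input", {
  expect_error(correlation_structure(rbind(c(1, 2), c(2, 1)), c(1, 2)),
               "at least 3")
  expect_error(correlation_structure(rbind(c(1, NA, 2)), c(1, 2, 3)),
               "missing")
  expect_error(correlation_structure(rbind(flat = c(2, 2, 2)), c(1, 2, 3)),
               "zero-variance")
  expect_error(correlation_structure(rbind(c(1, 2, 3)), c(5, 5, 5)),
               "zero-variance")
})

test_that("orthogonal predictors return the correlations as coefficients", {
  sol <- solve_path_coefficients(diag(2), c(0.3, -0.2))
  expect_equal(sol$b_star, c(0.3, -0.2))
  expect_equal(sol$c_diag, c(1, 1))
  expect_false(sol$condition_flag)
})

test_that("path coefficients equal an OLS fit on standardized data", {
  set.seed(5)
  for (rep in 1:5) {
    config <- simulation_config(q = 3, R_x_target = random_spd_correlation(3),
                                n = 40, seed = 100 + rep)
    data <- simulate_dataset(config)
    x <- t(data[1:3, ]); y <- data["y", ]
    cs <- correlation_structure(data[1:3, ], y)
    sol <- solve_path_coefficients(cs$R_x, cs$R_xy)
    oracle <- unname(coef(lm(scale(y) ~ scale(x)))[-1])
    expect_equal(unname(sol$b_star), oracle, tolerance = 1e-6)
  }
})

test_that("near-singular systems error in strict mode, warn in permissive", {
  R_x <- matrix(c(1, 1, 1, 1), 2, 2)  # exactly singular
  expect_error(solve_path_coefficients(R_x, c(0.5, 0.5), strict = TRUE),
               "singular")
  expect_warning(sol <- solve_path_coefficients(R_x, c(0.5, 0.5)),
                 "pseudo-inverse")
  expect_true(sol$condition_flag)
  # pseudo-inverse solution still reproduces R_xy
  expect_equal(as.vector(R_x %*% sol$b_star), c(0.5, 0.5), tolerance = 1e-8)
})

test_that("the four-child fixture is internally consistent", {
  fx <- table2_fixture()
  # printed b* and reconstructed R_x reproduce the printed r_jy closely;
  # the system is too ill-conditioned for the reverse direction (solving
  # for b* from 3-decimal r_jy) to be meaningful
  expect_lt(max(abs(fx$model$R_x %*% fx$model$b_star - fx$expected$r_jy)),
            2e-3)
  expect_equal(unname(eigen(fx$model$R_x, only.values = TRUE)$values > 0),
               rep(TRUE, 4))
  expect_true(all(fx$model$c_diag >= 1))
})

test_that("effect decomposition reproduces the fixture's printed columns", {
  fx <- table2_fixture()
  ed <- effect_decomposition(fx$model)
  x2 <- ed$table[ed$table$child_id == "x2", ]
  expect_equal(x2$direct, -1.097)
  expect_equal(x2$indirect_sum, 0.243, tolerance = 0.005)
  expect_equal(x2$total, -0.854)
  expect_lt(abs(x2$retro - (-0.416)), 0.01)
  x3 <- ed$table[ed$table$child_id == "x3", ]
  expect_lt(abs(x3$retro - (-0.278)), 0.01)
  # per-sibling components: q - 1 finite entries per child
  expect_equal(unname(rowSums(!is.na(ed$components))), rep(3, 4))
})

test_that("direct + indirect = total holds for every fitted model", {
  for (seed in 1:5) {
    model <- fitted_sim_model(q = 4, n = 25, seed = seed)
    ed <- effect_decomposition(model)
    expect_lt(max(abs(ed$table$direct + ed$table$indirect_sum -
                        ed$table$total)), 1e-10)
    expect_true(all(model$c_diag >= 1 - 1e-12))
    expect_gte(model$R2, 0)
    expect_lte(model$R2, 1 + 1e-10)
  }
  # orthogonal limit: no indirect transmission at all
  m <- model_from_components(diag(3), c(0.5, -0.3, 0.2))
  ed <- effect_decomposition(m)
  expect_equal(ed$table$indirect_sum, rep(0, 3))
  expect_equal(ed$table$total, ed$table$direct)
})

test_that("CD decomposition matches both closed forms and the residual oracle", {
  # orthogonal: indirect CD vanishes
  m <- model_from_components(diag(3), c(0.5, -0.3, 0.2))
  cd <- coefficient_of_determination(m)
  expect_equal(cd$indirect_cd, 0)
  expect_equal(cd$total_cd, sum(c(0.5, -0.3, 0.2)^2))

  set.seed(204)
  config <- simulation_config(q = 3, n = 200, seed = 204)
  data <- simulate_dataset(config)
  model <- fit_path_model(data[1:3, ], data["y", ])
  cd <- coefficient_of_determination(model)
  # residual-sum oracle on standardized data
  ys <- as.vector(scale(data["y", ]))
  xs <- scale(t(data[1:3, ]))
  fit <- lm(ys ~ xs)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((ys - mean(ys))^2)
  expect_equal(cd$total_cd, 1 - ss_res / ss_tot, tolerance = 1e-8)
  # and the sum-of-products form
  expect_equal(cd$total_cd, sum(model$b_star * model$R_xy),
               tolerance = 1e-10)
  expect_equal(cd$direct_cd + cd$indirect_cd, cd$total_cd,
               tolerance = 1e-10)
  expect_equal(cd$direct_ratio, cd$direct_cd / cd$total_cd)
  expect_equal(cd$indirect_ratio, abs(cd$indirect_cd) / cd$total_cd)
})
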