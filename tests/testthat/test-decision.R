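test_that("decision coefficients match hand arithmetic and the fixture", {
  # q = 2 hand oracle: b* = (1, 1), r_12 = -0.6 -> DC_1 = 1 + 2(-0.6) = -0.2
  m <- model_from_components(matrix(c(1, -0.6, -0.6, 1), 2), c(1, 1))
  dcs <- decision_coefficients(m)
  expect_equal(unname(dcs$dc), c(-0.2, -0.2))
  expect_equal(diag(dcs$subdivision), c(x1 = 1, x2 = 1))

  fx <- table2_fixture()
  dc <- decision_coefficients(fx$model)$dc
  expect_equal(dc, fx$expected$dc, tolerance = 0.005)
})

test_that("the subdivision matrix is symmetric and column sums give the DCs", {
  set.seed(31)
  for (rep in 1:10) {
    q <- sample(2:6, 1)
    model <- model_from_components(random_spd_correlation(q), rnorm(q))
    dcs <- decision_coefficients(model)
    expect_equal(dcs$subdivision, t(dcs$subdivision), tolerance = 1e-12)
    expect_equal(colSums(dcs$subdivision), dcs$dc)
    # algebraic identity: sum_j DC_j = 2 R^2 - sum_j (b*_j)^2
    cd <- coefficient_of_determination(model)
    expect_equal(sum(dcs$dc), 2 * cd$total_cd - sum(model$b_star^2),
                 tolerance = 1e-10)
  }
})

test_that("orthogonal siblings give nonnegative DCs and zero cutoffs", {
  b <- c(0.5, -0.4, 0.3)
  m <- model_from_components(diag(3), b, n = 20)
  dcs <- decision_coefficients(m)
  expect_equal(unname(dcs$dc), b^2)
  expect_equal(unname(dcs$subdivision[upper.tri(dcs$subdivision)]),
               rep(0, 3))
  for (a in c(0.01, 0.05, 0.1))
    expect_equal(unname(dc_cutoff(m, a)), rep(0, 3))
})

test_that("the cutoff reproduces a t-table oracle and clamps R^2 at 1", {
  # n=10, q=4, |r_jy - b*_j| = 0.5, c_jj = 2, R^2 = 0.9, alpha = 0.05:
  # cutoff = 2 * t_{0.025}(5) * 0.5 * sqrt(2 * 0.1 / 5) = 0.5141
  b <- rep((-2 + sqrt(4 + 14.4)) / 8, 4)       # sum(b * (b + 0.5)) = 0.9
  ids <- paste0("x", 1:4)
  model <- path_model("parent", ids, n = 10, R_x = diag(4),
                      R_xy = b + 0.5, b_star = b, c_diag = rep(2, 4),
                      check = FALSE)
  expect_equal(model$R2, 0.9, tolerance = 1e-12)
  expect_equal(unname(dc_cutoff(model, 0.05)), rep(0.5141, 4),
               tolerance = 1e-3)
  expect_equal(unname(dc_cutoff(model, 0.05)),
               rep(2 * qt(0.975, 5) * 0.5 * sqrt(2 * 0.1 / 5), 4))

  # R^2 = 1 (and anything above, reachable only via rounded inputs)
  # collapses all cutoffs to zero
  b1 <- rep(0.4, 4)
  saturated <- path_model("parent", ids, n = 10, R_x = diag(4),
                          R_xy = rep(0.625, 4), b_star = b1,
                          c_diag = rep(1, 4), check = FALSE)
  expect_equal(saturated$R2, 1)
  expect_equal(unname(dc_cutoff(saturated, 0.05)), rep(0, 4))

  # zero indirect effect (r_jy = b*_j) zeroes the cutoff at every level
  zero_ind <- model_from_components(diag(2), c(0.3, 0.4), n = 10)
  expect_equal(unname(dc_cutoff(zero_ind, 0.01)), c(0, 0))
})

test_that("cutoff arguments are validated", {
  m <- model_from_components(diag(2), c(0.3, 0.4), n = 4)
  expect_equal(m$n - m$q - 1, 1)  # smallest legal df
  expect_silent(dc_cutoff(m, 0.05))
  tiny <- model_from_components(diag(2), c(0.3, 0.4), n = 3)
  expect_error(dc_cutoff(tiny, 0.05), "degrees of freedom")
  expect_error(dc_cutoff(m, 0), "alpha")
  expect_error(dc_cutoff(m, 1), "alpha")
})

test_that("cutoffs increase as the significance level tightens", {
  set.seed(17)
  for (rep in 1:10) {
    model <- fitted_sim_model(q = 3, n = 20, seed = 300 + rep)
    alphas <- c(0.01, 0.05, 0.1)
    cuts <- vapply(alphas, function(a) dc_cutoff(model, a), numeric(3))
    expect_true(all(diff(t(cuts)) <= 1e-14))  # alpha up => cutoff down
    expect_true(all(cuts >= 0))
  }
})

test_that("fixed-threshold selection and ranking behave deterministically", {
  fx <- table2_fixture()
  dc <- decision_coefficients(fx$model)$dc
  sel <- select_impacted(dc, 0.4)
  expect_setequal(names(which(sel$significant)), c("x2", "x3", "x4"))
  expect_identical(sel$ranking, c("x4", "x3", "x2", "x1"))

  # ties broken lexicographically by child id
  tied <- c(b = 1, a = -1, c = 0.5)
  expect_identical(select_impacted(tied, 0.1)$ranking, c("a", "b", "c"))

  # relabeling the children permutes but does not change the selection
  dc2 <- dc[c(3, 1, 4, 2)]
  sel2 <- select_impacted(dc2, 0.4)
  expect_setequal(names(which(sel2$significant)),
                  names(which(sel$significant)))
  expect_error(select_impacted(dc, c(1, 2)), "length")
})

test_that("impact direction follows the DC sign and flips with it", {
  fx <- table2_fixture()
  dc <- decision_coefficients(fx$model)$dc
  expect_identical(impact_direction(dc), fx$expected$direction)
  expect_identical(unname(impact_direction(0)), "neutral")
  flipped <- impact_direction(-dc)
  swap <- c(activated = "inhibited", inhibited = "activated",
            neutral = "neutral")
  expect_identical(flipped, setNames(swap[impact_direction(dc)],
                                     names(dc)))
})

test_that("decision percentages normalize |DC| to 100 within each parent", {
  expect_equal(unname(decision_percentages(c(x1 = -2.5))), 100)
  expect_equal(unname(decision_percentages(c(a = 3, b = -3))), c(50, 50))
  # printed-value arithmetic: |DC| = (0.148, 0.670, 3.697, 9.300)
  dp <- decision_percentages(c(0.148, -0.670, 3.697, -9.300))
  expect_equal(unname(dp), c(1.07, 4.85, 26.76, 67.32), tolerance = 0.01)
  expect_equal(sum(dp), 100)
  expect_error(decision_percentages(c(0, 0)), "undefined")
})

test_that("decision_analysis assembles a coherent per-parent report", {
  model <- fitted_sim_model(q = 4, n = 30, seed = 77)
  da <- decision_analysis(model)
  r <- da$report
  expect_equal(nrow(r), 4L)
  expect_equal(r$direct_factor + r$indirect_factor, r$dc, tolerance = 1e-12)
  expect_equal(sum(r$decision_percentage), 100, tolerance = 1e-8)
  expect_identical(r$direction, unname(impact_direction(r$dc)))
  expect_true(all(c("cutoff_0.01", "cutoff_0.05", "cutoff_0.10") %in%
                    names(r)))
  expect_identical(r$most_impacted, abs(r$dc) >= 0.4)
  # significant_at is consistent with the cutoff columns
  for (i in seq_len(4)) {
    hit <- c(0.01, 0.05, 0.1)[abs(r$dc[i]) >=
      unlist(r[i, c("cutoff_0.01", "cutoff_0.05", "cutoff_0.10")])]
    expected <- if (length(hit) == 0) "none" else
      paste(sprintf("%.2f", hit), collapse = ",")
    expect_identical(r$significant_at[i], expected)
  }
})
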