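test_that("quadratic model rows expand in the canonical term order", {
  expect_equal(unname(quadratic_row(c(0, 0, 0))), c(1, rep(0, 9)))
  expect_equal(unname(quadratic_row(c(1, 1, 1))), rep(1, 10))
  expect_equal(unname(quadratic_row(c(1, 2, 3))),
               c(1, 1, 2, 3, 2, 3, 6, 1, 4, 9))
  # p = 1 + k + k(k-1)/2 + k
  for (k in 2:5)
    expect_length(quadratic_row(rep(1, k)), 1 + 2 * k + k * (k - 1) / 2)
})

test_that("zero-noise surfaces are recovered exactly", {
  set.seed(42)
  des <- ccd_design(make_factors(3), n_center = 6)
  beta <- random_beta(3)
  des <- simulate_design_responses(des, beta, noise_sd = 0, response = "y")
  m <- fit_quadratic(des, "y", scale = "coded")
  expect_equal(unname(m$coefficients), unname(beta), tolerance = 1e-8)
  expect_equal(m$r2, 1, tolerance = 1e-10)
  expect_equal(m$press, 0, tolerance = 1e-8)
  expect_equal(m$pred_r2, 1, tolerance = 1e-8)
  # zero residual variance: signal-to-noise saturates, t-tests undefined
  expect_identical(m$adequate_precision, Inf)
  expect_true(all(is.nan(m$term_p)))
})

test_that("PRESS equals brute-force leave-one-out refitting", {
  set.seed(7)
  for (rep in 1:10) {
    des <- ccd_design(make_factors(3), n_center = 4)
    des <- simulate_design_responses(des, random_beta(3), noise_sd = 2,
                                     seed = 100 + rep, response = "y")
    m <- fit_quadratic(des, "y")
    coded <- design_coded(des)
    MM <- quadratic_model_matrix(coded)
    press_loo <- sum(vapply(seq_len(nrow(des)), function(i) {
      b <- qr.coef(qr(MM[-i, , drop = FALSE]), des$y[-i])
      (des$y[i] - drop(MM[i, ] %*% b))^2
    }, numeric(1)))
    expect_equal(m$press, press_loo, tolerance = 1e-8)
  }
})

test_that("diagnostics are invariant to the coded/actual reparameterization", {
  des <- flp_design()
  for (resp in c("size_nm", "ee_pct", "dl_pct")) {
    mc <- fit_quadratic(des, resp, scale = "coded")
    ma <- fit_quadratic(des, resp, scale = "actual")
    expect_equal(mc$r2, ma$r2, tolerance = 1e-10)
    expect_equal(mc$adj_r2, ma$adj_r2, tolerance = 1e-10)
    expect_equal(mc$pred_r2, ma$pred_r2, tolerance = 1e-10)
    expect_equal(mc$model_f_p, ma$model_f_p, tolerance = 1e-10)
    # identical predictions at the design points
    coded <- design_coded(des)
    expect_equal(predict(mc, coded, units = "coded"),
                 predict(ma, coded, units = "coded"), tolerance = 1e-8)
    expect_false(isTRUE(all.equal(mc$coefficients, ma$coefficients,
                                  check.attributes = FALSE)))
  }
})

test_that("R-squared orderings hold on noisy fits", {
  set.seed(12)
  for (rep in 1:5) {
    des <- ccd_design(make_factors(3), n_center = 6)
    des <- simulate_design_responses(des, random_beta(3), noise_sd = 4,
                                     seed = rep, response = "y")
    m <- fit_quadratic(des, "y")
    expect_lte(m$adj_r2, m$r2)
    expect_lte(m$pred_r2, m$r2)
    expect_gte(m$r2, 0); expect_lte(m$r2, 1)
  }
})

test_that("strong effects are declared significant, absent ones are not", {
  des <- ccd_design(make_factors(3), n_center = 6)
  beta <- stats::setNames(rep(0, 10), names(random_beta(3)))
  beta["(Intercept)"] <- 50; beta["f1"] <- 10
  des <- simulate_design_responses(des, beta, noise_sd = 0.1, seed = 5,
                                   response = "y")
  m <- fit_quadratic(des, "y")
  expect_lt(m$term_p[["f1"]], 0.001)
  expect_lt(m$model_f_p, 0.001)
  expect_gt(m$term_p[["f2:f3"]], 0.01)
  expect_lt(abs(m$coefficients[["f2:f3"]]), 0.5)
})

test_that("reduced term lists drop the requested terms", {
  des <- flp_design()
  m <- fit_quadratic(des, "dl_pct",
                     terms = c("fn_mM", "lipid_mM", "chol_pct",
                               "fn_mM:lipid_mM", "fn_mM:chol_pct",
                               "fn_mM^2", "lipid_mM^2"))
  expect_equal(m$p, 8)
  expect_false("lipid_mM:chol_pct" %in% names(m$coefficients))
  expect_error(fit_quadratic(des, "dl_pct", terms = "nope"), "unknown")
})

test_that("degenerate inputs raise informative errors", {
  des <- ccd_design(make_factors(3), n_center = 6)
  des$y <- rep(5, nrow(des))
  expect_error(fit_quadratic(des, "y"), "degenerate response")
  # collinear factors: f2 is a copy of f1
  f <- make_factors(2, centers = c(0, 0), widths = c(1, 1))
  d2 <- ccd_design(f, n_center = 2)
  d2$f2 <- d2$f1
  attr(d2, "coded")[, 2] <- attr(d2, "coded")[, 1]
  d2$y <- stats::rnorm(nrow(d2))
  expect_error(fit_quadratic(d2, "y"), "singular design")
  expect_error(fit_quadratic(des, "missing_col"), "not found")
})

test_that("equation text mirrors the fitted coefficients", {
  des <- flp_design()
  ma <- fit_quadratic(des, "size_nm", scale = "actual")
  eq <- rsm_equation(ma)
  expect_match(eq, "^size_nm = ")
  expect_match(eq, "fn_mM\\^2")
  rep <- rsm_report(ma)
  expect_equal(rep$diagnostics$r2, ma$r2)
  expect_length(rep$coefficients, 10)
})
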