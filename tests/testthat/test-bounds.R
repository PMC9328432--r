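test_that("LP bound on the enzyme pair matches the closed-form feasible point", {
  b <- lp_set_upper_bound(enzyme)
  expect_identical(b$status, "optimal")
  # the equality system pins both leading velocity coefficients to zero,
  # so r* = max(7.298/0.114, 8.696/0.222)
  expect_equal(b$r_star, 7.298 / 0.114, tolerance = 1e-6)
  cp <- conditionally_linear_feasible_point(enzyme, 1, 1)
  expect_equal(cp$r, max(7.298 / 0.114, 8.696 / 0.222))
  expect_lte(b$r_star, cp$r + 1e-8)
  # the certificate zeroes both linearized responses over the full grid
  lp <- linearize(enzyme, enzyme$design_space)
  z0 <- lp$F0 %*% b$certificate$theta0 + lp$a0
  z1 <- lp$F1 %*% b$certificate$theta1 + lp$a1
  expect_lt(max(abs(z0 - z1)), 1e-8)
  expect_lt(max(abs(z0)), 1e-6)
})

test_that("LP bound is stable under grid refinement", {
  fine <- make_enzyme_problem(grid_x1 = seq(0, 30, by = 0.25),
                              grid_x2 = seq(0, 40, by = 0.5))
  b1 <- lp_set_upper_bound(enzyme)
  b2 <- lp_set_upper_bound(fine)
  expect_equal(b1$r_star, b2$r_star, tolerance = 0.01)
})

test_that("beyond the LP bound every design is indistinguishable; below it not", {
  expect_true(zero_delta_check(enzyme, 65, n_random_designs = 15, seed = 8))
  expect_false(zero_delta_check(enzyme, 5, n_random_designs = 15, seed = 8))
  # r = 0 cannot vanish when the nominal means differ somewhere
  expect_false(zero_delta_check(enzyme, 0, n_random_designs = 5, seed = 8))
  # and the exchange search warns when asked to optimize beyond the bound
  expect_warning(kl_exchange(enzyme, 3, 70, n_starts = 2, seed = 1),
                 "indistinguishable")
})

test_that("zero-response certificate of conditional linearity verifies", {
  cp <- conditionally_linear_feasible_point(enzyme, 1, 1)
  lp <- linearize(enzyme, enzyme$design_space)
  expect_lt(max(abs(lp$F0 %*% cp$theta0 + lp$a0)), 1e-8)
  expect_lt(max(abs(lp$F1 %*% cp$theta1 + lp$a1)), 1e-8)
  # fixing the wrong coordinate does not annihilate the response
  expect_null(conditionally_linear_feasible_point(enzyme, 2, 2))
  # an already-linear model with nominal at zero contributes r = 0
  m_a <- regression_model("la", function(theta, X) theta[1] * X[, 1],
                          function(theta, X) matrix(X[, 1], ncol = 1), 1L, 1L)
  lin <- suppressWarnings(discrimination_problem(
    m_a, m_a, nominal_set(0, 1), nominal_set(0, 1),
    matrix(c(1, 2), ncol = 1)))
  cp0 <- conditionally_linear_feasible_point(lin, 1, 1)
  expect_equal(cp0$r, 0)
})

test_that("two linear models: LP optimum covers the zero vector, and a
           discriminable pair has a strictly positive bound", {
  m_a <- regression_model("la", function(theta, X) theta[1] * X[, 1],
                          function(theta, X) matrix(X[, 1], ncol = 1), 1L, 1L)
  m_b <- regression_model("lb", function(theta, X) theta[1] * X[, 1]^2,
                          function(theta, X) matrix(X[, 1]^2, ncol = 1), 1L, 1L)
  lin <- discrimination_problem(m_a, m_b, nominal_set(2, 1),
                                nominal_set(1.5, 0.5),
                                matrix(c(0.5, 1, 2), ncol = 1))
  b <- lp_set_upper_bound(lin)
  expect_identical(b$status, "optimal")
  # theta0 = theta1 = 0 solves the equality system; cuboids must reach 0
  expect_equal(b$r_star, max(2 / 1, 1.5 / 0.5))
  expect_gt(b$r_star, 0)
})

test_that("iterative bound search terminates immediately when already satisfied", {
  b <- set_upper_bound_search(ex1, 6, r_ini = 2, q = 1 + 1e-6,
                              n_starts = 5, seed = 3)
  expect_equal(b$r_star, 2)
  expect_equal(b$n_design_computations, 2L) # o(Inf) plus the single check
})

test_that("iterative bound search fails loudly when models are linearly
           indistinguishable at the unconstrained level", {
  m_a <- regression_model("la", function(theta, X) theta[1] * X[, 1],
                          function(theta, X) matrix(X[, 1], ncol = 1), 1L, 1L)
  lin <- suppressWarnings(discrimination_problem(
    m_a, m_a, nominal_set(1, 1), nominal_set(2, 1),
    matrix(c(1, 2), ncol = 1)))
  expect_error(suppressWarnings(
    set_upper_bound_search(lin, 2, 0.3, 1 + 1e-6, n_starts = 2, seed = 1)),
    "indistinguishable")
})

test_that("bound results serialize with their trace", {
  b <- lp_set_upper_bound(enzyme)
  f <- tempfile(fileext = ".json")
  write_bound_json(b, f, seed = 1)
  obj <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(obj$r_star, b$r_star)
  expect_identical(obj$status, "optimal")
  g <- glance(b)
  expect_equal(g$r_star, b$r_star)
})
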