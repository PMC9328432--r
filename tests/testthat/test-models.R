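test_that("toy problem matches its closed-form construction", {
  expect_equal(nrow(ex1$design_space), 101L)
  expect_equal(ex1$nominal0$nominal, exp(1))
  expect_equal(ex1$nominal1$nominal, 1)
  # unit cuboids [e-1, e+1] and [0, 2]
  b0 <- cuboid_bounds(ex1$nominal0, 1)
  b1 <- cuboid_bounds(ex1$nominal1, 1)
  expect_equal(c(b0$lower, b0$upper), c(exp(1) - 1, exp(1) + 1))
  expect_equal(c(b1$lower, b1$upper), c(0, 2))
  # the nominal mean functions agree at x = 1 and differ at x = 2
  expect_equal(model_mean(ex1$model0, exp(1), 1), exp(1))
  expect_equal(model_mean(ex1$model1, 1, 1), exp(1))
  expect_equal(model_mean(ex1$model0, exp(1), 2) - model_mean(ex1$model1, 1, 2),
               2 * exp(1) - exp(2))
  expect_gt(max(abs(ex1$cache$Delta)), 0)
  # gradient of the exponential model at theta = 1, x = 2 is 2 e^2
  expect_equal(model_gradient(ex1$model1, 1, 2)[1, 1], 2 * exp(2))
})

test_that("enzyme problem carries the inhibition-study nominals and SEs", {
  expect_equal(enzyme$nominal0$nominal, c(7.298, 4.386, 2.582))
  expect_equal(enzyme$nominal0$half_width, c(0.114, 0.233, 0.145))
  expect_equal(enzyme$nominal1$nominal, c(8.696, 8.066, 12.057))
  expect_equal(enzyme$nominal1$half_width, c(0.222, 0.488, 0.671))
  expect_equal(nrow(enzyme$design_space), 61L * 41L)
  # both velocities vanish without substrate, for any parameters
  X0 <- cbind(0, c(0, 10, 40))
  expect_equal(model_mean(enzyme$model0, c(5, 3, 2), X0), rep(0, 3))
  expect_equal(model_mean(enzyme$model1, c(9, 8, 12), X0), rep(0, 3))
})

test_that("analytic gradients match finite differences", {
  # exact for the linear model
  expect_equal(check_gradient(ex1$model0, exp(1), 1.37), 0)
  expect_lt(check_gradient(enzyme$model0, enzyme$nominal0$nominal,
                           c(15, 20), h = 1e-6), 1e-5)
  expect_lt(check_gradient(enzyme$model1, enzyme$nominal1$nominal,
                           c(30, 40), h = 1e-6), 1e-5)
  # random interior draws for every built-in model
  set.seed(11)
  for (i in seq_len(100)) {
    th1 <- runif(1, 0.2, 4)
    x1 <- runif(1, 1, 2)
    expect_lt(check_gradient(ex1$model1, th1, x1), 1e-5)
    th3 <- runif(3, c(2, 2, 2), c(12, 12, 20))
    x2 <- c(runif(1, 0.5, 30), runif(1, 0, 40))
    expect_lt(check_gradient(enzyme$model0, th3, x2), 1e-5)
    expect_lt(check_gradient(enzyme$model1, th3, x2), 1e-5)
  }
})

test_that("problem construction validates inputs and warns on indiscriminability", {
  expect_error(make_example1_problem(1, 2, -0.1), "grid_step")
  expect_error(make_enzyme_problem(grid_x1 = c(-1, 5)), "within")
  expect_error(
    discrimination_problem(ex1$model0, enzyme$model0,
                           ex1$nominal0, nominal_set(c(1, 1, 1), c(1, 1, 1)),
                           matrix(1:3, ncol = 1)),
    "same number of parameters")
  # identical linear models: mean functions coincide everywhere
  m <- ex1$model0
  expect_warning(
    discrimination_problem(m, m, nominal_set(2, 1), nominal_set(2, 1),
                           matrix(1:3, ncol = 1)),
    "discriminability")
})

test_that("cuboid dilation behaves at the corner cases r = 0, 1, Inf", {
  ns <- nominal_set(c(2, -1), c(0.5, 0))
  b0 <- cuboid_bounds(ns, 0)
  expect_equal(b0$lower, b0$upper)
  bi <- cuboid_bounds(ns, Inf)
  expect_equal(bi$lower, c(-Inf, -1)) # zero half-width stays degenerate
  expect_equal(bi$upper, c(Inf, -1))
  expect_error(cuboid_bounds(ns, -1), "r must be")
})
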