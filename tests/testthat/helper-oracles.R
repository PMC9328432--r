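# shared fixtures and independent oracles, built in code at test time

ex1 <- make_example1_problem()
ex1_small <- make_example1_problem(1, 2, 0.5) # {1.0, 1.5, 2.0}
enzyme <- make_enzyme_problem()
enzyme_coarse <- make_enzyme_problem(grid_x1 = seq(0, 30, by = 5),
                                     grid_x2 = seq(0, 40, by = 10))

# brute-force oracle for two stacked parameters: minimize the squared
# linearized distance over an ngrid x ngrid discretization of the cuboid
grid_search_delta_sq <- function(problem, design, r, ngrid = 201) {
  stopifnot(problem$m == 1)
  lp <- linearize(problem, design)
  b0 <- cuboid_bounds(problem$nominal0, r)
  b1 <- cuboid_bounds(problem$nominal1, r)
  t0 <- seq(b0$lower, b0$upper, length.out = ngrid)
  t1 <- seq(b1$lower, b1$upper, length.out = ngrid)
  gr <- expand.grid(t0 = t0, t1 = t1)
  # residual matrix: each column one (theta0, theta1) pair
  R <- outer(lp$a0 - lp$a1, rep(1, nrow(gr))) +
    lp$F0[, 1] %o% gr$t0 - lp$F1[, 1] %o% gr$t1
  min(colSums(R^2))
}

# closed-form unconstrained least-squares value via the pseudoinverse
pinv_rss <- function(problem, design) {
  lp <- linearize(problem, design)
  A <- cbind(lp$F0, -lp$F1)
  z <- lp$z_tilde
  fit <- pracma::pinv(A) %*% z
  sum((A %*% fit - z)^2)
}

# evaluate the quadratic-form path at stacked theta (independent of the
# norm path used by delta_sq_at)
quad_path_value <- function(problem, design, theta0, theta1) {
  qf <- delta_quad_form(problem, design)
  u <- c(theta0, theta1) - c(problem$nominal0$nominal, problem$nominal1$nominal)
  as.numeric(t(u) %*% qf$M %*% u + 2 * sum(qf$b * u) + qf$c)
}

# random one-parameter discrimination problem on a small grid (for the
# exchange-vs-enumeration stress test)
random_small_problem <- function(d) {
  a0 <- stats::runif(1, 0.5, 2)
  a1 <- stats::runif(1, 0.2, 1.2)
  m0 <- regression_model(
    "lin", function(theta, X) theta[1] * X[, 1],
    function(theta, X) matrix(X[, 1], ncol = 1), 1L, 1L)
  m1 <- regression_model(
    "pow", function(theta, X) exp(theta[1] * X[, 1]),
    function(theta, X) matrix(X[, 1] * exp(theta[1] * X[, 1]), ncol = 1), 1L, 1L)
  grid <- sort(stats::runif(d, 0.2, 2))
  discrimination_problem(m0, m1,
                         nominal_set(a0, stats::runif(1, 0.1, 1)),
                         nominal_set(a1, stats::runif(1, 0.1, 1)),
                         matrix(grid, ncol = 1), name = "random_small")
}
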