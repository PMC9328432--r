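test_that("r = 0 reduces to the nominal evaluation with the nominal minimizer", {
  d <- exact_design(c(1.3, 1.8), mult = c(2, 1))
  ev <- delta_sq(ex1, d, 0)
  expect_equal(ev$delta_sq, delta_sq_at(ex1, d, exp(1), 1))
  expect_equal(ev$theta0, exp(1))
  expect_equal(ev$theta1, 1)
  expect_error(delta_sq(ex1, d, -0.5), "r must be")
})

test_that("r = Inf equals the unconstrained least-squares residual", {
  set.seed(31)
  for (i in seq_len(20)) {
    prob <- if (i %% 2 == 0) ex1 else enzyme_coarse
    d <- random_design(prob, sample(3:8, 1))
    ev <- delta_sq(prob, d, Inf)
    expect_equal(ev$delta_sq, pinv_rss(prob, d), tolerance = 1e-8)
  }
})

test_that("box-constrained solution matches a 201 x 201 grid search", {
  set.seed(32)
  for (i in seq_len(8)) {
    d <- random_design(ex1, sample(2:6, 1))
    r <- runif(1, 0.05, 1.5)
    ev <- delta_sq(ex1, d, r)
    oracle <- grid_search_delta_sq(ex1, d, r, ngrid = 201)
    # the grid value can only overshoot the true minimum
    expect_lte(ev$delta_sq, oracle + 1e-6)
    expect_gte(oracle, ev$delta_sq - 1e-10)
    expect_lt(abs(ev$delta_sq - oracle), 1e-3 * (1 + oracle))
    # minimizer feasibility and value consistency
    b0 <- cuboid_bounds(ex1$nominal0, r)
    b1 <- cuboid_bounds(ex1$nominal1, r)
    expect_true(ev$theta0 >= b0$lower - 1e-10 && ev$theta0 <= b0$upper + 1e-10)
    expect_true(ev$theta1 >= b1$lower - 1e-10 && ev$theta1 <= b1$upper + 1e-10)
    expect_equal(ev$delta_sq,
                 delta_sq_at(ex1, d, ev$theta0, ev$theta1),
                 tolerance = 1e-9)
  }
})

test_that("criterion is nonincreasing and convex in r, for fixed designs", {
  set.seed(33)
  rs <- c(0, 0.05, 0.1, 0.2, 0.35, 0.5, 0.7, 1, 1.5, 2)
  for (prob in list(ex1, enzyme_coarse)) {
    for (i in 1:3) {
      d <- random_design(prob, 5)
      v <- vapply(rs, function(r) delta_sq(prob, d, r)$delta_sq, numeric(1))
      expect_true(all(diff(v) <= 1e-10))
      slopes <- diff(v) / diff(rs)
      expect_true(all(diff(slopes) >= -1e-8))
    }
  }
})

test_that("s-fold replication scales the criterion exactly s-fold", {
  set.seed(34)
  for (prob in list(ex1, enzyme_coarse)) {
    d <- random_design(prob, 4)
    for (r in c(0, 0.3, Inf)) {
      v1 <- delta_sq(prob, d, r)$delta_sq
      for (s in c(2, 3)) {
        vs <- delta_sq(prob, replicate_design(d, s), r)$delta_sq
        expect_equal(vs, s * v1, tolerance = 1e-9)
      }
    }
  }
})

test_that("criterion is concave over convex combinations of design measures", {
  set.seed(35)
  d <- nrow(ex1$design_space)
  for (i in seq_len(20)) {
    w1 <- rmultinom(1, 5, rep(1, d))[, 1]
    w2 <- rmultinom(1, 5, rep(1, d))[, 1]
    a <- runif(1)
    r <- runif(1, 0, 1)
    va <- delta_sq_weighted(ex1, a * w1 + (1 - a) * w2, r)
    v1 <- delta_sq_weighted(ex1, w1, r)
    v2 <- delta_sq_weighted(ex1, w2, r)
    expect_gte(va, a * v1 + (1 - a) * v2 - 1e-9)
  }
  # integer weights agree with the exact-design path
  w <- rmultinom(1, 6, rep(1, d))[, 1]
  dd <- exact_design(ex1$design_space[w > 0, , drop = FALSE], w[w > 0])
  expect_equal(delta_sq_weighted(ex1, w, 0.4), delta_sq(ex1, dd, 0.4)$delta_sq,
               tolerance = 1e-10)
})

test_that("degenerate zero-distance evaluations are flagged", {
  # all mass at x = 1 where the nominal means agree: delta^2 = 0 at r = 0
  ev <- delta_sq(ex1, exact_design(1, mult = 3), 0)
  expect_equal(ev$delta_sq, 0)
  expect_identical(ev$solver_status, "degenerate")
})

test_that("criterion evaluations expose tidy, glance and JSON output", {
  ev <- delta_sq(enzyme_coarse, random_design(enzyme_coarse, 4, seed = 36), 2)
  td <- tidy(ev)
  expect_equal(nrow(td), 6L)
  expect_equal(td$estimate, unname(ev$minimizer))
  g <- glance(ev)
  expect_equal(g$delta_sq, ev$delta_sq)
  f <- tempfile(fileext = ".json")
  write_delta_json(ev, f)
  obj <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(obj$delta_sq, ev$delta_sq)
  expect_equal(obj$theta0, ev$theta0)
})

test_that("exact distance agrees with the linearization where it must", {
  # for two linear models the linearization is exact, any r
  m_a <- regression_model("la", function(theta, X) theta[1] * X[, 1],
                          function(theta, X) matrix(X[, 1], ncol = 1), 1L, 1L)
  m_b <- regression_model("lb", function(theta, X) theta[1] * X[, 1]^2,
                          function(theta, X) matrix(X[, 1]^2, ncol = 1), 1L, 1L)
  lin <- discrimination_problem(m_a, m_b, nominal_set(1, 0.5),
                                nominal_set(0.8, 0.5),
                                matrix(seq(0.5, 2, by = 0.5), ncol = 1))
  d <- exact_design(c(0.5, 1, 2))
  for (r in c(0, 0.3, 1)) {
    ed <- exact_distance(lin, d, r, n_starts = 5, seed = 4)
    expect_equal(ed$value, sqrt(delta_sq(lin, d, r)$delta_sq),
                 tolerance = 1e-6)
  }
  # r = 0 is the plain nominal distance for any pair
  d2 <- exact_design(c(1.2, 2))
  ed0 <- exact_distance(ex1, d2, 0)
  expect_equal(ed0$value, sqrt(delta_sq(ex1, d2, 0)$delta_sq))
  # nonlinear pair: report the linearization diagnostic, no hard bound
  s <- kl_exchange(ex1, 6, 0.1, n_starts = 5, seed = 5)
  ed <- exact_distance(ex1, s$best_design, 0.1, n_starts = 10, seed = 6)
  ratio <- ed$value / sqrt(s$best_delta_sq)
  expect_true(is.finite(ratio) && ratio > 0)
  expect_error(exact_distance(ex1, d2, Inf), "finite")
})

test_that("chi-square discrimination bound has its closed-form values", {
  expect_equal(correct_decision_lower_bound(0, 1, 5), 0)
  # delta = 2 sigma, n = 1: P[chi2_1 <= 1] = P(|Z| <= 1)
  expect_equal(correct_decision_lower_bound(2 * 0.3, 0.3, 1),
               pnorm(1) - pnorm(-1), tolerance = 1e-12)
  # monotone in delta, antitone in sigma
  v <- vapply(seq(0, 3, by = 0.5), correct_decision_lower_bound,
              numeric(1), sigma = 0.5, n = 4)
  expect_true(all(diff(v) >= 0))
  vs <- vapply(c(0.2, 0.4, 0.8), function(s)
    correct_decision_lower_bound(1, s, 4), numeric(1))
  expect_true(all(diff(vs) <= 0))
})
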