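test_that("exact designs canonicalize, expand, and round-trip through files", {
  d <- exact_design(c(2, 1, 2, 1.5))
  expect_equal(d$x1, c(1, 1.5, 2))
  expect_equal(d$mult, c(1L, 1L, 2L))
  expect_equal(design_size(d), 4L)
  expect_equal(design_points(d)[, 1], c(1, 1.5, 2, 2))
  # same multiset built differently compares equal
  d2 <- exact_design(c(1, 1.5, 2), mult = c(1, 1, 2))
  expect_equal(d, d2)
  # csv and json round trips
  fc <- tempfile(fileext = ".csv")
  fj <- tempfile(fileext = ".json")
  write_design_csv(d, fc)
  write_design_json(d, fj, seed = 3)
  expect_equal(read_design_csv(fc), d)
  expect_equal(read_design_json(fj), d)
  dd <- exact_design(rbind(c(3, 0), c(3, 0), c(15, 20)))
  expect_equal(dd$mult, c(2L, 1L))
  expect_error(exact_design(numeric(0)), "at least one")
})

test_that("exchange matches enumeration on the reduced toy grid", {
  # 3-point grid, n = 2: all six multisets enumerable
  en <- exhaustive_search(ex1_small, 2, 0, max_multisets = 10)
  expect_equal(en$n_evaluations, 6)
  kl <- kl_exchange(ex1_small, 2, 0, n_starts = 10, seed = 1)
  expect_equal(kl$best_delta_sq, en$best_delta_sq, tolerance = 1e-12)
  expect_equal(kl$best_design, en$best_design)
  # at r = 0 the optimum stacks all mass on the largest nominal difference
  dlt <- abs(ex1_small$cache$Delta)
  xstar <- unname(ex1_small$design_space[which.max(dlt), 1])
  expect_equal(en$best_design$x1, xstar)
  expect_equal(en$best_design$mult, 2L)
  expect_equal(xstar, 2) # for this pair the difference grows toward x = 2
  expect_error(exhaustive_search(ex1, 6, 0, max_multisets = 10),
               "max_multisets")
})

test_that("tiny flexible sets concentrate the design at the difference maximizer", {
  s <- kl_exchange(ex1, 6, 0.01, n_starts = 10, seed = 2)
  expect_equal(nrow(s$best_design), 1L)
  expect_equal(s$best_design$x1, 2)
  expect_equal(s$best_design$mult, 6L)
})

test_that("exchange is reproducible, monotone along accepted moves, and matches
           enumeration on random small instances", {
  a <- kl_exchange(ex1_small, 3, 0.2, n_starts = 5, seed = 99)
  b <- kl_exchange(ex1_small, 3, 0.2, n_starts = 5, seed = 99)
  expect_identical(a$best_delta_sq, b$best_delta_sq)
  expect_identical(a$best_design, b$best_design)
  expect_identical(a$per_start, b$per_start)
  for (tr in a$traces) expect_true(all(diff(tr) > 0))

  set.seed(100)
  for (i in seq_len(20)) {
    prob <- random_small_problem(d = sample(3:6, 1))
    n <- sample(2:4, 1)
    r <- sample(c(0, runif(1, 0, 1)), 1)
    en <- exhaustive_search(prob, n, r)
    kl <- suppressWarnings(kl_exchange(prob, n, r, n_starts = 10, seed = i))
    expect_gte(en$best_delta_sq + 1e-12, kl$best_delta_sq)
    expect_equal(kl$best_delta_sq, en$best_delta_sq,
                 tolerance = 1e-9)
  }
})

test_that("optimal value is nonincreasing in the dilation", {
  rs <- c(0.01, 0.1, 0.3, 0.5, 0.7, 1)
  o <- vapply(rs, function(r)
    kl_exchange(ex1, 6, r, n_starts = 10, seed = 7)$best_delta_sq, numeric(1))
  expect_true(all(diff(o) <= 1e-9))
})

test_that("replication efficiency is exactly s and self-efficiency is one", {
  d <- exact_design(c(1.2, 1.9), mult = c(2, 2))
  expect_equal(efficiency(ex1, d, d, 0.3), 1)
  expect_equal(efficiency(ex1, replicate_design(d, 3), d, 0.3), 3,
               tolerance = 1e-9)
  # no design beats the enumerated optimum
  en <- exhaustive_search(ex1_small, 2, 0.1)
  set.seed(41)
  for (i in 1:5) {
    expect_lte(efficiency(ex1_small, random_design(ex1_small, 2), en$best_design,
                          0.1), 1 + 1e-9)
  }
  # efficiency is undefined against a zero-criterion reference
  expect_error(efficiency(ex1, d, exact_design(1, mult = 2), 0),
               "undefined")
})

test_that("search results expose tidy, glance and serialization", {
  s <- kl_exchange(ex1_small, 2, 0.2, n_starts = 3, seed = 5)
  td <- tidy(s)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("x1", "mult"))
  g <- glance(s)
  expect_equal(g$best_delta_sq, s$best_delta_sq)
  expect_equal(g$n_support, nrow(s$best_design))
  f <- tempfile(fileext = ".json")
  write_search_json(s, f)
  obj <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(obj$best_delta_sq, s$best_delta_sq)
  expect_equal(obj$meta$package, "deltadiscrim")
  p <- autoplot(s)
  expect_s3_class(p, "ggplot")
})
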