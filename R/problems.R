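#' Define a model-discrimination problem
#'
#' Couples two rival regression models (with equal numbers of parameters),
#' their flexible nominal sets, and a finite design space. On construction
#' the stacked gradients and nominal response differences are pre-computed
#' over the design space, which makes criterion evaluation and design search
#' fast.
#'
#' The *discriminability condition* requires the two nominal mean functions
#' to differ at at least one design-space point; if it fails, a warning is
#' issued (every design then has zero criterion value at the point nominals).
#'
#' @param model0,model1 [regression_model()] objects with equal `dim_param`
#'   and `dim_x`.
#' @param nominal0,nominal1 [nominal_set()] objects for the two models.
#' @param design_space matrix or data frame of candidate design points
#'   (one row per point, `dim_x` columns); rows must be distinct.
#' @param name optional identifier.
#'
#' @return An object of class `discrimination_problem`.
#' @export
discrimination_problem <- function(model0, model1, nominal0, nominal1,
                                   design_space, name = "custom") {
  stopifnot(inherits(model0, "regression_model"),
            inherits(model1, "regression_model"),
            inherits(nominal0, "nominal_set"),
            inherits(nominal1, "nominal_set"))
  if (model0$dim_param != model1$dim_param) {
    stop_input("the two models must have the same number of parameters")
  }
  if (model0$dim_x != model1$dim_x) {
    stop_input("the two models must share the design-point dimension")
  }
  m <- model0$dim_param
  if (length(nominal0$nominal) != m || length(nominal1$nominal) != m) {
    stop_input("nominal vectors must have length %d", m)
  }
  ok0 <- all(nominal0$nominal > model0$param_box[, 1] &
               nominal0$nominal < model0$param_box[, 2])
  ok1 <- all(nominal1$nominal > model1$param_box[, 1] &
               nominal1$nominal < model1$param_box[, 2])
  if (!ok0 || !ok1) stop_input("nominal values must lie strictly inside the parameter box")

  X <- as_point_matrix(design_space, model0$dim_x)
  if (nrow(X) == 0L) stop_input("design_space must be nonempty")
  if (anyDuplicated(X)) stop_input("design_space must not contain duplicate points")

  G <- cbind(model_gradient(model0, nominal0$nominal, X),
             -model_gradient(model1, nominal1$nominal, X))
  Delta <- model_mean(model0, nominal0$nominal, X) -
    model_mean(model1, nominal1$nominal, X)
  if (any(!is.finite(G)) || any(!is.finite(Delta))) {
    bad <- which(!is.finite(Delta) | rowSums(!is.finite(G)) > 0)[1]
    stop_input("nonfinite mean or gradient at design-space point (%s)",
               paste(signif(X[bad, ], 6), collapse = ", "))
  }
  if (max(abs(Delta)) <= 1e-12) {
    warn(paste0("discriminability condition violated: the nominal mean ",
                "functions coincide on the whole design space"))
  }

  structure(
    list(name = name, model0 = model0, model1 = model1,
         nominal0 = nominal0, nominal1 = nominal1,
         design_space = X, m = m, dim_x = model0$dim_x,
         cache = list(G = G, Delta = Delta)),
    class = "discrimination_problem"
  )
}

#' @export
print.discrimination_problem <- function(x, ...) {
  cat(sprintf(paste0("<discrimination_problem> %s\n",
                     "  models: %s vs %s (m = %d)\n",
                     "  design space: %d point(s) in %d dimension(s)\n",
                     "  max |nominal mean difference|: %.4g\n"),
              x$name, x$model0$name, x$model1$name, x$m,
              nrow(x$design_space), x$dim_x, max(abs(x$cache$Delta))))
  invisible(x)
}

#' Design space of a problem as a tibble
#'
#' @param problem a [discrimination_problem()].
#' @return Tibble with one row per candidate design point.
#' @export
design_space_tbl <- function(problem) {
  tibble::as_tibble(as.data.frame(problem$design_space))
}

problem_hash <- function(problem) {
  rlang::hash(list(problem$name,
                   problem$nominal0$nominal, problem$nominal0$half_width,
                   problem$nominal1$nominal, problem$nominal1$half_width,
                   problem$design_space))
}

#' Linear-versus-exponential toy discrimination problem
#'
#' Builds the one-parameter pair \eqn{\eta_0(\theta, x) = \theta x} and
#' \eqn{\eta_1(\theta, x) = e^{\theta x}} on an equidistant grid, with
#' nominal values \eqn{\tilde\theta_0 = e}, \eqn{\tilde\theta_1 = 1} and unit
#' cuboids \eqn{[e - 1, e + 1]} and \eqn{[0, 2]} (half-widths 1). At the
#' nominals the two mean functions agree at \eqn{x = 1} and differ elsewhere
#' on the default grid.
#'
#' @param grid_start,grid_end,grid_step endpoints and step of the design
#'   grid; the defaults give the 101-point grid \eqn{\{1.00, 1.01, \dots,
#'   2.00\}}.
#' @return A [discrimination_problem()].
#' @export
make_example1_problem <- function(grid_start = 1, grid_end = 2, grid_step = 0.01) {
  if (!is_scalar_num(grid_step) || grid_step <= 0) stop_input("grid_step must be > 0")
  grid <- seq(grid_start, grid_end, by = grid_step)
  m0 <- regression_model(
    "linear", mean = function(theta, X) theta[1] * X[, 1],
    gradient = function(theta, X) matrix(X[, 1], ncol = 1L),
    dim_param = 1L, dim_x = 1L)
  m1 <- regression_model(
    "exponential", mean = function(theta, X) exp(theta[1] * X[, 1]),
    gradient = function(theta, X) matrix(X[, 1] * exp(theta[1] * X[, 1]), ncol = 1L),
    dim_param = 1L, dim_x = 1L)
  discrimination_problem(
    m0, m1,
    nominal_set(exp(1), 1), nominal_set(1, 1),
    design_space = matrix(grid, ncol = 1L),
    name = "example1")
}

#' Enzyme-kinetics discrimination problem (competitive vs noncompetitive
#' inhibition)
#'
#' Builds the two three-parameter Michaelis--Menten-type inhibition models
#' for reaction velocity as a function of substrate concentration \eqn{x_1}
#' and inhibitor concentration \eqn{x_2}:
#' competitive inhibition
#' \eqn{\eta_0 = \theta_{01} x_1 / \{\theta_{02}(1 + x_2/\theta_{03}) + x_1\}}
#' and noncompetitive inhibition
#' \eqn{\eta_1 = \theta_{11} x_1 / \{(\theta_{12} + x_1)(1 + x_2/\theta_{13})\}}.
#' Nominal parameter values are the Dextromethorphan--Sertraline initial-study
#' estimates and the cuboid half-widths are their standard errors:
#' \eqn{\hat\theta_0 = (7.298, 4.386, 2.582)} with SEs
#' \eqn{(0.114, 0.233, 0.145)}, and
#' \eqn{\hat\theta_1 = (8.696, 8.066, 12.057)} with SEs
#' \eqn{(0.222, 0.488, 0.671)}. Parameter boxes are
#' \eqn{\theta_1 \in (0, \infty)}, \eqn{\theta_2 \in (0, 60]},
#' \eqn{\theta_3 \in (0, 30]}.
#'
#' The design rectangle is \eqn{[0, 30] \times [0, 40]}; as the methods here
#' work on a finite design space it is discretized, by default to a 61 x 41
#' grid (steps 0.5 in \eqn{x_1}, 1 in \eqn{x_2}).
#'
#' @param grid_x1,grid_x2 grids of substrate / inhibitor concentrations,
#'   within `[0, 30]` and `[0, 40]`.
#' @return A [discrimination_problem()].
#' @export
make_enzyme_problem <- function(grid_x1 = seq(0, 30, by = 0.5),
                                grid_x2 = seq(0, 40, by = 1)) {
  if (any(grid_x1 < 0 | grid_x1 > 30) || any(grid_x2 < 0 | grid_x2 > 40)) {
    stop_input("grids must lie within [0, 30] x [0, 40]")
  }
  box <- cbind(lower = c(0, 0, 0), upper = c(Inf, 60, 30))
  m0 <- regression_model(
    "competitive",
    mean = function(theta, X) {
      den <- theta[2] * (1 + X[, 2] / theta[3]) + X[, 1]
      theta[1] * X[, 1] / den
    },
    gradient = function(theta, X) {
      den <- theta[2] * (1 + X[, 2] / theta[3]) + X[, 1]
      cbind(X[, 1] / den,
            -theta[1] * X[, 1] * (1 + X[, 2] / theta[3]) / den^2,
            theta[1] * X[, 1] * theta[2] * X[, 2] / (theta[3]^2 * den^2))
    },
    dim_param = 3L, dim_x = 2L, param_box = box)
  m1 <- regression_model(
    "noncompetitive",
    mean = function(theta, X) {
      theta[1] * X[, 1] / ((theta[2] + X[, 1]) * (1 + X[, 2] / theta[3]))
    },
    gradient = function(theta, X) {
      P <- theta[2] + X[, 1]
      Q <- 1 + X[, 2] / theta[3]
      cbind(X[, 1] / (P * Q),
            -theta[1] * X[, 1] / (P^2 * Q),
            theta[1] * X[, 1] * X[, 2] / (P * Q^2 * theta[3]^2))
    },
    dim_param = 3L, dim_x = 2L, param_box = box)
  discrimination_problem(
    m0, m1,
    nominal_set(c(7.298, 4.386, 2.582), c(0.114, 0.233, 0.145)),
    nominal_set(c(8.696, 8.066, 12.057), c(0.222, 0.488, 0.671)),
    design_space = as.matrix(expand.grid(x1 = grid_x1, x2 = grid_x2)),
    name = "enzyme")
}

#' List the built-in discrimination problems
#' @return Character vector of problem names accepted by [get_problem()].
#' @export
list_problems <- function() c("example1", "enzyme")

#' Build a built-in discrimination problem by name
#'
#' @param name `"example1"` or `"enzyme"`.
#' @param ... passed to the problem constructor
#'   ([make_example1_problem()] or [make_enzyme_problem()]).
#' @return A [discrimination_problem()].
#' @export
get_problem <- function(name, ...) {
  switch(match.arg(name, list_problems()),
         example1 = make_example1_problem(...),
         enzyme = make_enzyme_problem(...))
}
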