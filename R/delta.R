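#' Linearize both models of a problem at their nominal values
#'
#' For a design \eqn{D = (x_1, \dots, x_n)} returns the matrices
#' \eqn{F_k(D)} of gradient rows \eqn{\nabla\eta_k(\tilde\theta_k, x_i)}, the
#' offsets \eqn{a_k(D) = (\eta_k(\tilde\theta_k, x_i))_i - F_k(D)
#' \tilde\theta_k}, and the artificial observations
#' \eqn{\tilde z = a_1(D) - a_0(D)} of the response-difference model. For a
#' model that is linear in its parameters, \eqn{a_k(D) = 0}.
#'
#' The design may contain arbitrary points at which the models are defined;
#' it need not be a subset of the problem's design space.
#'
#' @param problem a [discrimination_problem()].
#' @param design an [exact_design()], or a matrix/vector of design points.
#' @return A list of class `linearized_pair` with elements `F0`, `F1`,
#'   `a0`, `a1`, `z_tilde`, and the expanded point matrix `X`.
#' @export
linearize <- function(problem, design) {
  X <- if (inherits(design, "exact_design")) design_points(design)
       else as_point_matrix(design, problem$dim_x)
  t0 <- problem$nominal0$nominal
  t1 <- problem$nominal1$nominal
  F0 <- model_gradient(problem$model0, t0, X)
  F1 <- model_gradient(problem$model1, t1, X)
  a0 <- model_mean(problem$model0, t0, X) - as.numeric(F0 %*% t0)
  a1 <- model_mean(problem$model1, t1, X) - as.numeric(F1 %*% t1)
  bad <- which(rowSums(!is.finite(cbind(F0, F1, a0, a1))) > 0)
  if (length(bad) > 0) {
    stop_input("nonfinite linearization at design point (%s)",
               paste(signif(X[bad[1], ], 6), collapse = ", "))
  }
  structure(list(F0 = F0, F1 = F1, a0 = a0, a1 = a1,
                 z_tilde = a1 - a0, X = X),
            class = "linearized_pair")
}

#' Squared linearized distance at fixed parameter values
#'
#' Evaluates \eqn{\|a_0(D) + F_0(D)\theta_0 - a_1(D) - F_1(D)\theta_1\|^2},
#' the squared distance between the two linearized mean vectors at the given
#' parameters (which need not belong to the flexible nominal sets).
#'
#' @inheritParams linearize
#' @param theta0,theta1 parameter vectors of length `m`.
#' @return Nonnegative scalar.
#' @export
delta_sq_at <- function(problem, design, theta0, theta1) {
  lp <- linearize(problem, design)
  if (length(theta0) != problem$m || length(theta1) != problem$m) {
    stop_input("theta0 and theta1 must have length %d", problem$m)
  }
  v <- lp$a0 + as.numeric(lp$F0 %*% as.numeric(theta0)) -
    lp$a1 - as.numeric(lp$F1 %*% as.numeric(theta1))
  sum(v^2)
}

#' Quadratic form of the squared criterion
#'
#' The squared linearized distance is a quadratic in the stacked parameter
#' \eqn{\theta = (\theta_0^T, \theta_1^T)^T}:
#' \eqn{(\theta - \tilde\theta)^T M (\theta - \tilde\theta) +
#' 2 b^T (\theta - \tilde\theta) + c}, where \eqn{M} is the information
#' matrix of the response-difference model (regressors
#' \eqn{(\nabla\eta_0^T, -\nabla\eta_1^T)}), \eqn{b} weights the regressors
#' by the nominal mean difference, and \eqn{c} is the sum of squared nominal
#' mean differences over the design.
#'
#' @inheritParams linearize
#' @return List with components `M` (`2m x 2m`), `b` (`2m`), `c` (scalar).
#' @export
delta_quad_form <- function(problem, design) {
  lp <- linearize(problem, design)
  G <- cbind(lp$F0, -lp$F1)
  Delta <- model_mean(problem$model0, problem$nominal0$nominal, lp$X) -
    model_mean(problem$model1, problem$nominal1$nominal, lp$X)
  list(M = crossprod(G), b = as.numeric(crossprod(G, Delta)), c = sum(Delta^2))
}

# internal: box-constrained minimization of ||G u + Delta||^2, |u| <= w
delta_solve_core <- function(G, Delta, w) {
  p <- ncol(G)
  if (all(w == 0)) {
    return(list(value = sum(Delta^2), u = rep(0, p),
                status = 0L))
  }
  fit <- cpp_bvls(G, -Delta, -w, w)
  u <- as.numeric(fit$x)
  u <- pmin(pmax(u, -w), w) # enforce cuboid membership, then re-evaluate
  value <- sum((as.numeric(G %*% u) + Delta)^2)
  list(value = value, u = u, status = as.integer(fit$status))
}

#' Evaluate the delta criterion for a design
#'
#' Minimizes the squared linearized distance between the two models' mean
#' vectors over the dilated flexible nominal sets
#' \eqn{\tilde\Theta_0(r) \times \tilde\Theta_1(r)}. The minimization is a
#' box-constrained least-squares problem in the response-difference model
#' with artificial observations, solved by an active-set method; `r = 0`
#' reduces to the nominal evaluation and `r = Inf` to unconstrained least
#' squares (minimum-norm solution under rank deficiency, which leaves the
#' criterion value unaffected).
#'
#' @inheritParams linearize
#' @param r dilation of the flexible nominal sets, in `[0, Inf]`.
#' @return An object of class `delta_eval`: a list with `delta_sq`, the
#'   attaining stacked `minimizer` (and `theta0`, `theta1`), logical
#'   `at_bound` flags for active cuboid faces, `solver_status`
#'   (`"converged"` or `"degenerate"`), `r` and the design size `n`.
#' @export
delta_sq <- function(problem, design, r) {
  if (!is_scalar_num(r) || r < 0) stop_input("r must be >= 0 (Inf allowed)")
  lp <- linearize(problem, design)
  G <- cbind(lp$F0, -lp$F1)
  Delta <- -lp$z_tilde + as.numeric(G %*% stacked_nominal(problem))
  w <- stacked_half_widths(problem, r)
  sol <- delta_solve_core(G, Delta, w)
  theta <- stacked_nominal(problem) + sol$u
  m <- problem$m
  degen <- sol$status != 0L || sol$value <= 1e-12
  structure(
    list(delta_sq = sol$value,
         minimizer = theta,
         theta0 = theta[seq_len(m)],
         theta1 = theta[m + seq_len(m)],
         at_bound = is.finite(w) & (abs(sol$u) >= w - 1e-10),
         solver_status = if (degen) "degenerate" else "converged",
         r = r, n = nrow(lp$X)),
    class = "delta_eval")
}

#' @export
print.delta_eval <- function(x, ...) {
  cat(sprintf("<delta_eval> delta^2 = %.6g (r = %s, n = %d, %s)\n",
              x$delta_sq, format(x$r), x$n, x$solver_status))
  invisible(x)
}

#' @describeIn delta_sq tidy method: one row per stacked parameter
#'   coordinate with the attaining value and active-face flag.
#' @param x a `delta_eval` object.
#' @param ... unused.
#' @export
tidy.delta_eval <- function(x, ...) {
  m <- length(x$theta0)
  tibble::tibble(
    model = rep(c(0L, 1L), each = m),
    term = rep(paste0("theta", seq_len(m)), 2),
    estimate = x$minimizer,
    at_bound = x$at_bound)
}

#' @describeIn delta_sq glance method: one-row summary tibble.
#' @export
glance.delta_eval <- function(x, ...) {
  tibble::tibble(delta_sq = x$delta_sq, r = x$r, n = x$n,
                 solver_status = x$solver_status)
}

#' Serialize a criterion evaluation to JSON
#'
#' @param x a `delta_eval` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_delta_json <- function(x, path) {
  obj <- list(meta = pkg_meta(),
              delta_sq = x$delta_sq,
              r = if (is.finite(x$r)) x$r else "inf",
              n = x$n, solver_status = x$solver_status,
              theta0 = x$theta0, theta1 = x$theta1,
              at_bound = x$at_bound)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Delta criterion of a weighted design measure
#'
#' Evaluates the criterion for a nonnegative measure on the design space
#' given by per-point weights (the counting-measure view generalized to
#' fractional weights). Used, e.g., to examine concavity of the criterion
#' over convex combinations of designs.
#'
#' @param problem a [discrimination_problem()].
#' @param weights nonnegative vector, one weight per design-space point.
#' @param r dilation of the flexible nominal sets.
#' @return Scalar criterion value \eqn{\delta_r^2}.
#' @export
delta_sq_weighted <- function(problem, weights, r) {
  weights <- as.numeric(weights)
  if (length(weights) != nrow(problem$design_space) || any(weights < 0)) {
    stop_input("weights must be nonnegative, one per design-space point")
  }
  keep <- weights > 0
  if (!any(keep)) return(0)
  s <- sqrt(weights[keep])
  G <- problem$cache$G[keep, , drop = FALSE] * s
  Delta <- problem$cache$Delta[keep] * s
  delta_solve_core(G, Delta, stacked_half_widths(problem, r))$value
}

#' Exact (non-linearized) distance between the mean-value sets
#'
#' Minimizes the Euclidean distance
#' \eqn{\|(\eta_0(\theta_0, x_i))_i - (\eta_1(\theta_1, x_i))_i\|} over the
#' dilated flexible nominal sets by multistart bounded quasi-Newton
#' optimization, initialized at the minimizer of the linearized criterion
#' plus random cuboid draws. This is a validation oracle for the quality of
#' the linearization, not a design criterion: it need not dominate or be
#' dominated by the linearized value.
#'
#' @inheritParams delta_sq
#' @param n_starts number of random starts added to the delta minimizer.
#' @param seed optional RNG seed.
#' @return List with `value` (the distance, not squared), `theta0`,
#'   `theta1`, and `solver_status`.
#' @export
exact_distance <- function(problem, design, r, n_starts = 10, seed = NULL) {
  if (!is_scalar_num(r) || !is.finite(r) || r < 0) {
    stop_input("exact_distance requires finite r >= 0")
  }
  X <- if (inherits(design, "exact_design")) design_points(design)
       else as_point_matrix(design, problem$dim_x)
  b0 <- cuboid_bounds(problem$nominal0, r)
  b1 <- cuboid_bounds(problem$nominal1, r)
  lower <- c(b0$lower, b1$lower)
  upper <- c(b0$upper, b1$upper)
  m <- problem$m

  if (r == 0 || all(upper == lower)) {
    d0 <- model_mean(problem$model0, problem$nominal0$nominal, X) -
      model_mean(problem$model1, problem$nominal1$nominal, X)
    return(list(value = sqrt(sum(d0^2)),
                theta0 = problem$nominal0$nominal,
                theta1 = problem$nominal1$nominal,
                solver_status = "converged"))
  }

  fn <- function(th) {
    d <- model_mean(problem$model0, th[seq_len(m)], X) -
      model_mean(problem$model1, th[m + seq_len(m)], X)
    sum(d^2)
  }
  gr <- function(th) {
    d <- model_mean(problem$model0, th[seq_len(m)], X) -
      model_mean(problem$model1, th[m + seq_len(m)], X)
    g0 <- model_gradient(problem$model0, th[seq_len(m)], X)
    g1 <- model_gradient(problem$model1, th[m + seq_len(m)], X)
    2 * c(as.numeric(crossprod(g0, d)), -as.numeric(crossprod(g1, d)))
  }

  seed_set(seed)
  de <- delta_sq(problem, design, r)
  starts <- rbind(de$minimizer,
                  matrix(stats::runif(n_starts * 2 * m, lower, upper),
                         ncol = 2 * m, byrow = TRUE))
  # coordinates with zero half-width stay fixed at the nominal
  free <- upper > lower
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    th0 <- pmin(pmax(starts[i, ], lower), upper)
    res <- tryCatch({
      if (all(free)) {
        stats::optim(th0, fn, gr, method = "L-BFGS-B", lower = lower,
                     upper = upper, control = list(factr = 1e4, maxit = 500))
      } else {
        fixed <- th0
        fnr <- function(v) { fixed[free] <- v; fn(fixed) }
        grr <- function(v) { fixed[free] <- v; gr(fixed)[free] }
        o <- stats::optim(th0[free], fnr, grr, method = "L-BFGS-B",
                          lower = lower[free], upper = upper[free],
                          control = list(factr = 1e4, maxit = 500))
        fixed[free] <- o$par
        list(par = fixed, value = o$value, convergence = o$convergence)
      }
    }, error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) {
    return(list(value = NA_real_, theta0 = NULL, theta1 = NULL,
                solver_status = "degenerate"))
  }
  list(value = sqrt(max(best$value, 0)),
       theta0 = best$par[seq_len(m)],
       theta1 = best$par[m + seq_len(m)],
       solver_status = if (best$convergence == 0) "converged" else "degenerate")
}

#' Chi-square lower bound on the probability of correct discrimination
#'
#' Under i.i.d. normal errors with standard deviation `sigma`, the
#' probability that the likelihood-ratio rule picks the true model is at
#' least \eqn{P[R \le d/2]} where \eqn{R} is the norm of the error vector
#' and \eqn{d} the distance between the two models' mean-value sets; since
#' \eqn{R^2/\sigma^2 \sim \chi^2_n}, the bound equals
#' \eqn{P[\chi^2_n \le d^2 / (4\sigma^2)]}. Here the linearized criterion
#' value is plugged in for \eqn{d}, so the result is an approximation of the
#' bound, exact when both models are linear.
#'
#' @param delta_value nonnegative plug-in distance (on the delta scale, not
#'   squared).
#' @param sigma error standard deviation, > 0.
#' @param n number of observations of the design.
#' @return Probability in `[0, 1]`.
#' @export
correct_decision_lower_bound <- function(delta_value, sigma, n) {
  stopifnot(is_scalar_num(delta_value), delta_value >= 0,
            is_scalar_num(sigma), sigma > 0, is_count(n))
  stats::pchisq(delta_value^2 / (4 * sigma^2), df = n)
}
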