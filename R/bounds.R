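new_bound_result <- function(r_star, method, trace, n_design_computations,
                             status, certificate = NULL, o_inf_sq = NULL) {
  structure(
    list(r_star = r_star, method = method, trace = trace,
         n_design_computations = n_design_computations,
         status = status, certificate = certificate, o_inf_sq = o_inf_sq),
    class = "bound_result")
}

#' @export
print.bound_result <- function(x, ...) {
  cat(sprintf("<bound_result> method = %s, status = %s\n", x$method, x$status))
  if (is.finite(x$r_star %||% NA_real_)) {
    cat(sprintf("  set upper bound r* = %.6g\n", x$r_star))
  }
  if (!is.null(x$n_design_computations)) {
    cat(sprintf("  design computations: %d\n", x$n_design_computations))
  }
  invisible(x)
}

#' @describeIn set_upper_bound_search tidy method: the search trace
#'   (one row per design computation) or the LP certificate coordinates.
#' @param x a `bound_result`.
#' @param ... unused.
#' @export
tidy.bound_result <- function(x, ...) {
  if (inherits(x$trace, "data.frame")) tibble::as_tibble(x$trace)
  else tibble::tibble(info = format(x$trace))
}

#' @describeIn set_upper_bound_search glance method: one-row summary.
#' @export
glance.bound_result <- function(x, ...) {
  tibble::tibble(method = x$method, r_star = x$r_star %||% NA_real_,
                 status = x$status,
                 n_design_computations = x$n_design_computations %||% NA_integer_)
}

#' @describeIn set_upper_bound_search autoplot method: optimal criterion
#'   value against the dilation r, with the unconstrained level.
#' @param object a `bound_result` from the iterative search.
#' @export
autoplot.bound_result <- function(object, ...) {
  stopifnot(inherits(object$trace, "data.frame"))
  ggplot2::ggplot(object$trace, ggplot2::aes(x = .data$r, y = .data$o_sq)) +
    ggplot2::geom_hline(yintercept = object$o_inf_sq, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_vline(xintercept = object$r_star, colour = "red",
                        linetype = 3) +
    ggplot2::labs(x = "dilation r", y = "optimal delta^2",
                  title = sprintf("set upper bound r* = %.4g", object$r_star))
}

#' Iterative search for a set upper bound on the dilation parameter
#'
#' A *set upper bound* is a dilation \eqn{r^*} beyond which enlarging the
#' flexible nominal sets changes neither the optimal design nor the optimal
#' criterion value, i.e. \eqn{o(r) = o(\infty)} for all \eqn{r \ge r^*}.
#' The search first computes the unconstrained level \eqn{o(\infty)} and
#' then walks upward in \eqn{r}: after each design search it extrapolates
#' the chord through the last two \eqn{(r, o(r))} points down to the level
#' \eqn{o(\infty)} (a valid lower bound on the crossing, since \eqn{o(r)} is
#' convex and nonincreasing in \eqn{r}), inflates the proposal by a safety
#' factor, and stops as soon as \eqn{o(r) \le q \, o(\infty)}. Once the
#' stopping level is bracketed, a short bisection polish localizes the
#' crossing so that the returned bound is near-minimal. Each step costs one
#' design search ([kl_exchange()]); the whole computation typically needs
#' order ten of them.
#'
#' @param problem a [discrimination_problem()].
#' @param n design size.
#' @param r_ini initial dilation (> 0).
#' @param q multiplicative stopping tolerance on the criterion value
#'   (> 1), e.g. `1 + 1e-6`: the search stops at the first r with
#'   \eqn{o(r) \le q\, o(\infty)} (on the delta scale).
#' @param n_starts,seed,tol passed to [kl_exchange()] for every design
#'   search; subsequent searches derive their seeds from `seed`.
#' @param inflate multiplicative safety factor applied to each chord
#'   proposal.
#' @param refine_rel relative bracket width below which the bisection
#'   polish stops.
#' @param max_steps cap on the number of design computations.
#' @return A `bound_result` with `r_star`, the search `trace` (tibble with
#'   one row per design computation: `r`, `o_sq`, `phase`),
#'   `n_design_computations`, and the unconstrained level `o_inf_sq`.
#' @export
set_upper_bound_search <- function(problem, n, r_ini, q, n_starts = 20,
                                   seed = NULL, tol = 1e-12, inflate = 1.05,
                                   refine_rel = 0.01, max_steps = 40) {
  if (!is_scalar_num(r_ini) || r_ini <= 0) stop_input("r_ini must be > 0")
  if (!is_scalar_num(q) || q <= 1) stop_input("q must be > 1")

  comp <- 0L
  trace <- list()
  next_seed <- function() {
    if (is.null(seed)) NULL else (as.integer(seed) + comp) %% .Machine$integer.max
  }
  search_at <- function(r, phase) {
    s <- kl_exchange(problem, n, r, n_starts = n_starts, seed = next_seed(),
                     tol = tol)
    comp <<- comp + 1L
    trace[[comp]] <<- tibble::tibble(step = comp, r = r,
                                     o_sq = s$best_delta_sq, phase = phase)
    s$best_delta_sq
  }

  o_inf_sq <- search_at(Inf, "unconstrained")
  if (o_inf_sq <= tol) {
    stop_input(paste0("o(Inf) = 0: the models are linearly indistinguishable ",
                      "(discriminability fails at the unconstrained level); ",
                      "r* = 0 trivially"))
  }
  o_inf <- sqrt(o_inf_sq)
  level <- q * o_inf
  passes <- function(o_sq) sqrt(o_sq) <= level

  r1 <- r_ini
  o1 <- search_at(r1, "chord")
  if (passes(o1)) {
    return(new_bound_result(r1, "search", dplyr::bind_rows(trace), comp,
                            "converged", o_inf_sq = o_inf_sq))
  }

  # second point before chords can be drawn
  r2 <- 2 * r_ini
  o2 <- search_at(r2, "chord")
  r_lo <- r1
  while (!passes(o2) && comp < max_steps) {
    s1 <- sqrt(o1); s2 <- sqrt(o2)
    r_next <- if (s1 - s2 > 1e-14 * (1 + s1)) {
      r2 + (s2 - o_inf) * (r2 - r1) / (s1 - s2)
    } else {
      2 * r2 # flat segment above the level: step out
    }
    r_next <- max(inflate * r_next, r2 * inflate)
    r_lo <- r2
    r1 <- r2; o1 <- o2
    r2 <- r_next
    o2 <- search_at(r2, "chord")
  }
  if (!passes(o2)) {
    return(new_bound_result(r2, "search", dplyr::bind_rows(trace), comp,
                            "step_limit", o_inf_sq = o_inf_sq))
  }

  # bracket [r_lo, r2]: bisect to localize the crossing
  r_hi <- r2
  while ((r_hi - r_lo) > refine_rel * r_hi && comp < max_steps) {
    mid <- (r_lo + r_hi) / 2
    if (passes(search_at(mid, "bisect"))) r_hi <- mid else r_lo <- mid
  }
  new_bound_result(r_hi, "search", dplyr::bind_rows(trace), comp,
                   "converged", o_inf_sq = o_inf_sq)
}

#' LP computation of a set upper bound
#'
#' For some model pairs there is a dilation \eqn{r^*} beyond which the two
#' linearized mean-value sets intersect over the design \eqn{\bar D} that
#' takes one trial at every design-space point -- and then \eqn{\delta_r} is
#' identically zero for every design and every size \eqn{n} once
#' \eqn{r \ge r^*}. The minimal such \eqn{r} solves the linear program
#' \deqn{\min r \ \mathrm{s.t.}\ F_0(\bar D)\theta_0 + a_0(\bar D) =
#'  F_1(\bar D)\theta_1 + a_1(\bar D),\quad
#'  |\theta_{kj} - \tilde\theta_{kj}| \le r \tilde\sigma_{kj},\quad r \ge 0.}
#'
#' The equality system has one row per design-space point but only
#' \eqn{2m} unknowns, so it is first reduced by least squares: if it is
#' inconsistent the LP is infeasible; otherwise its solution set is an
#' affine subspace, and the remaining program in the subspace coordinates
#' (a tiny LP, or a closed form when the solution is unique) is solved
#' exactly. The returned certificate \eqn{(\theta_0, \theta_1)} is
#' re-verified against the equality constraints and cuboid membership.
#'
#' @param problem a [discrimination_problem()].
#' @param tol_eq feasibility tolerance for the equality system (relative to
#'   the response scale).
#' @return A `bound_result` with `method = "lp"`, `status` `"optimal"` or
#'   `"infeasible"`, the optimal `r_star` and the attaining `certificate`
#'   (list with `theta0`, `theta1`).
#' @export
lp_set_upper_bound <- function(problem, tol_eq = 1e-8) {
  G <- problem$cache$G
  Delta <- problem$cache$Delta
  theta_til <- stacked_nominal(problem)
  hw <- c(problem$nominal0$half_width, problem$nominal1$half_width)
  p <- 2 * problem$m

  # equality system in u = theta - theta_til:  G u = -Delta
  sv <- svd(G)
  scale <- max(1, max(abs(Delta)))
  rank <- sum(sv$d > max(dim(G)) * .Machine$double.eps * sv$d[1])
  u_p <- sv$v[, seq_len(rank), drop = FALSE] %*%
    ((crossprod(sv$u[, seq_len(rank), drop = FALSE], -Delta)) / sv$d[seq_len(rank)])
  u_p <- as.numeric(u_p)
  resid <- max(abs(as.numeric(G %*% u_p) + Delta))
  if (resid > tol_eq * scale) {
    return(new_bound_result(NA_real_, "lp",
                            list(residual = resid, nullity = p - rank),
                            0L, "infeasible"))
  }
  N <- if (rank < p) sv$v[, (rank + 1):p, drop = FALSE] else NULL

  solve_unique <- function(u) {
    # smallest r whose cuboids contain theta_til + u
    ratios <- ifelse(hw > 0, abs(u) / hw, ifelse(abs(u) <= tol_eq, 0, Inf))
    max(ratios)
  }

  if (is.null(N)) {
    r_star <- solve_unique(u_p)
    u_opt <- u_p
  } else {
    k <- ncol(N)
    # LP in (t+, t-, r) >= 0: min r  s.t.  +-(u_p + N t) <= r * hw
    cc <- c(rep(0, 2 * k), 1)
    A <- rbind(cbind(N, -N, -hw), cbind(-N, N, -hw))
    b <- c(-u_p, u_p)
    fixed <- hw == 0 # these coordinates must match exactly
    if (any(fixed)) {
      Aeq <- cbind(N[fixed, , drop = FALSE], -N[fixed, , drop = FALSE],
                   rep(0, sum(fixed)))
      beq <- -u_p[fixed]
      A <- A[!c(fixed, fixed), , drop = FALSE]
      b <- b[!c(fixed, fixed)]
    } else {
      Aeq <- NULL; beq <- NULL
    }
    lp <- tryCatch(
      pracma::linprog(cc, A = A, b = b, Aeq = Aeq, beq = beq,
                      maxiter = 200, maximize = FALSE),
      error = function(e) NULL)
    if (is.null(lp) || is.null(lp$x)) {
      return(new_bound_result(NA_real_, "lp",
                              list(residual = resid, nullity = k),
                              0L, "solver_failure"))
    }
    t_opt <- lp$x[seq_len(k)] - lp$x[k + seq_len(k)]
    u_opt <- u_p + as.numeric(N %*% t_opt)
    r_star <- solve_unique(u_opt)
  }

  if (!is.finite(r_star)) {
    return(new_bound_result(NA_real_, "lp",
                            list(residual = resid,
                                 reason = "zero half-width with nonzero required displacement"),
                            0L, "infeasible"))
  }
  theta <- theta_til + u_opt
  m <- problem$m
  cert <- list(theta0 = theta[seq_len(m)], theta1 = theta[m + seq_len(m)])
  ok_eq <- max(abs(as.numeric(G %*% u_opt) + Delta)) <= 1e-8 * scale
  ok_box <- all(abs(u_opt) <= r_star * hw + 1e-8)
  new_bound_result(r_star, "lp",
                   list(residual = resid, nullity = p - rank,
                        certificate_verified = ok_eq && ok_box),
                   0L, if (ok_eq && ok_box) "optimal" else "certificate_failure",
                   certificate = cert)
}

#' Feasible point from conditional linearity
#'
#' If each model becomes linear once a proper subset of its parameters is
#' fixed at the nominal values (e.g. Michaelis--Menten-type models, which
#' are linear in the leading velocity coefficient), then setting the
#' "linear" coefficients to zero and the remaining ones to their nominals
#' annihilates both linearized responses at every design point, yielding a
#' feasible point of the LP of [lp_set_upper_bound()] and hence a closed-form
#' set upper bound: the smallest \eqn{r} whose cuboids contain the
#' constructed points.
#'
#' @param problem a [discrimination_problem()].
#' @param linear0,linear1 integer indices of the coefficients in which model
#'   0 / model 1 is linear when the remaining parameters are fixed.
#' @param tol verification tolerance for the zero-response certificate.
#' @return List with `r`, `theta0`, `theta1`, or `NULL` when the
#'   construction does not apply (responses not annihilated, or a zero
#'   half-width forces an infinite dilation).
#' @export
conditionally_linear_feasible_point <- function(problem, linear0, linear1,
                                                tol = 1e-8) {
  m <- problem$m
  th0 <- problem$nominal0$nominal
  th1 <- problem$nominal1$nominal
  th0[linear0] <- 0
  th1[linear1] <- 0
  X <- problem$design_space
  lp <- linearize(problem, X)
  scale <- max(1, max(abs(lp$a0)), max(abs(lp$a1)))
  z0 <- max(abs(as.numeric(lp$F0 %*% th0) + lp$a0))
  z1 <- max(abs(as.numeric(lp$F1 %*% th1) + lp$a1))
  if (z0 > tol * scale || z1 > tol * scale) return(NULL)
  u <- c(th0 - problem$nominal0$nominal, th1 - problem$nominal1$nominal)
  hw <- c(problem$nominal0$half_width, problem$nominal1$half_width)
  ratios <- ifelse(hw > 0, abs(u) / hw, ifelse(abs(u) <= tol, 0, Inf))
  r <- max(ratios)
  if (!is.finite(r)) return(NULL)
  list(r = r, theta0 = th0, theta1 = th1)
}

#' Check that the criterion vanishes on random designs
#'
#' Beyond an LP-certified set upper bound, every design has
#' \eqn{\delta_r = 0}. This utility evaluates the criterion on random
#' `n`-point designs and reports whether all values are (numerically) zero.
#'
#' @param problem a [discrimination_problem()].
#' @param r dilation.
#' @param n_random_designs number of random designs drawn.
#' @param seed optional RNG seed.
#' @param n design size of the random designs.
#' @param tol zero tolerance on \eqn{\delta^2}.
#' @return `TRUE` iff all sampled designs have \eqn{\delta_r^2 \le} `tol`.
#' @export
zero_delta_check <- function(problem, r, n_random_designs = 20, seed = NULL,
                             n = 6, tol = 1e-9) {
  if (!is_scalar_num(r) || r < 0) stop_input("r must be >= 0")
  seed_set(seed)
  d <- nrow(problem$design_space)
  idx <- matrix(sample.int(d, n * n_random_designs, replace = TRUE), nrow = n)
  w <- stacked_half_widths(problem, r)
  vals <- cpp_eval_designs(problem$cache$G, problem$cache$Delta, w, idx)
  all(vals <= tol)
}

#' Serialize a bound result to JSON
#'
#' @param x a `bound_result`.
#' @param path output path.
#' @param seed optional seed recorded in the metadata.
#' @return `path`, invisibly.
#' @export
write_bound_json <- function(x, path, seed = NULL) {
  obj <- list(meta = pkg_meta(seed = seed),
              method = x$method, status = x$status,
              r_star = x$r_star,
              n_design_computations = x$n_design_computations,
              o_inf_sq = x$o_inf_sq,
              certificate = x$certificate,
              trace = if (inherits(x$trace, "data.frame"))
                as.data.frame(x$trace) else x$trace)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
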