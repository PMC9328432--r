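#' Bounded multistart nonlinear least-squares fit
#'
#' Fits a regression model to observations by Levenberg--Marquardt least
#' squares ([minpack.lm::nls.lm]) with box constraints, from several start
#' points, and returns the best fit. Under i.i.d. normal errors the residual
#' sum of squares is, up to constants, \eqn{-2\sigma^2} times the maximized
#' log-likelihood, so comparing RSS across rival models implements the
#' likelihood-ratio decision.
#'
#' @param model a [regression_model()].
#' @param design an [exact_design()] or a matrix/vector of design points.
#' @param y numeric observations (length n).
#' @param starts matrix of start values, one row per start.
#' @param lower,upper parameter bounds; default to the model's `param_box`
#'   (open zero lower bounds are nudged inward).
#' @return List with `theta` (best estimate), `rss`, `converged` (any start
#'   converged), and `n_failed` (starts that errored or failed to
#'   converge).
#' @export
fit_nls <- function(model, design, y, starts, lower = NULL, upper = NULL) {
  X <- if (inherits(design, "exact_design")) design_points(design)
       else as_point_matrix(design, model$dim_x)
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop_input("length(y) must match the design size")
  if (is.null(dim(starts))) starts <- matrix(starts, nrow = 1L)
  if (is.null(lower)) lower <- ifelse(model$param_box[, 1] == 0, 1e-9,
                                      model$param_box[, 1])
  if (is.null(upper)) upper <- model$param_box[, 2]

  resid_fn <- function(th) model$mean(th, X) - y
  jac_fn <- function(th) model$gradient(th, X)

  best <- NULL
  n_failed <- 0L
  ctrl <- minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12, ptol = 1e-12)
  for (i in seq_len(nrow(starts))) {
    th0 <- pmin(pmax(as.numeric(starts[i, ]), lower), upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = th0, lower = lower, upper = upper,
                         fn = resid_fn, jac = jac_fn, control = ctrl),
      error = function(e) NULL)
    ok <- !is.null(fit) && fit$info %in% 1:4 && all(is.finite(fit$par))
    if (!ok) { n_failed <- n_failed + 1L; next }
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(theta = as.numeric(fit$par), rss = rss)
    }
  }
  if (is.null(best)) {
    return(list(theta = rep(NA_real_, model$dim_param), rss = Inf,
                converged = FALSE, n_failed = n_failed))
  }
  c(best, list(converged = TRUE, n_failed = n_failed))
}

#' Likelihood-ratio model decision from residual sums of squares
#'
#' Under equal parameter counts and i.i.d. normal errors, the likelihood
#' ratio of the two fitted models exceeds one exactly when model 0 attains
#' the smaller residual sum of squares; ties decide for model 0.
#'
#' @param rss0,rss1 residual sums of squares of the two fitted models.
#' @return `0L` if model 0 is selected, else `1L`.
#' @export
lr_decide <- function(rss0, rss1) {
  if (rss0 <= rss1) 0L else 1L
}
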