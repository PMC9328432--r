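#' Draw a perturbed parameter vector from a flexible nominal set
#'
#' Each component is drawn independently and uniformly from
#' \eqn{[\tilde\theta_j - c\,\tilde\sigma_j,
#' \tilde\theta_j + c\,\tilde\sigma_j]}. With `c = 0` the nominal vector is
#' returned exactly. Used to perturb the data-generating process in the
#' Monte-Carlo robustness study, with a fresh draw per replicate.
#'
#' @param nominal a [nominal_set()].
#' @param c nonnegative perturbation multiplier.
#' @param u optional vector of uniforms on `[0, 1]` (one per component) to
#'   use instead of fresh `runif()` draws; this enables common random
#'   numbers across study arms.
#' @return Parameter vector.
#' @export
perturb_params <- function(nominal, c, u = NULL) {
  stopifnot(is_scalar_num(c), c >= 0)
  m <- length(nominal$nominal)
  if (is.null(u)) u <- stats::runif(m)
  nominal$nominal + c * nominal$half_width * (2 * u - 1)
}

#' Simulate observations with additive normal errors
#'
#' \eqn{y_i = \eta(\theta, x_i) + \varepsilon_i} with i.i.d.
#' \eqn{N(0, \sigma^2)} errors; `sigma = 0` returns the exact means.
#' Negative observations are possible and retained.
#'
#' @param design an [exact_design()] (or point matrix).
#' @param model a [regression_model()].
#' @param theta data-generating parameter vector.
#' @param sigma error standard deviation (>= 0).
#' @param eps optional pre-drawn standard-normal vector (length n).
#' @return Tibble with the design-point coordinates and a `y` column;
#'   attributes `theta_true` and `model` record the generator.
#' @export
simulate_normal <- function(design, model, theta, sigma, eps = NULL) {
  stopifnot(is_scalar_num(sigma), sigma >= 0)
  X <- if (inherits(design, "exact_design")) design_points(design)
       else as_point_matrix(design, model$dim_x)
  eta <- model_mean(model, theta, X)
  if (is.null(eps)) eps <- stats::rnorm(nrow(X))
  y <- eta + sigma * eps
  out <- tibble::as_tibble(as.data.frame(X))
  out$y <- y
  attr(out, "theta_true") <- theta
  attr(out, "model") <- model$name
  out
}

#' Simulate observations with mean-matched multiplicative log-normal errors
#'
#' Multiplicative log-normal errors allow arbitrarily inflated error
#' variance without producing negative observations (which would invalidate
#' likelihood fitting under the normal working model). The construction is
#' per-point variance-matched and mean-exact:
#' \eqn{y_i = \eta_i \exp(\varepsilon_i - s_i^2/2)} with
#' \eqn{\varepsilon_i \sim N(0, s_i^2)} and
#' \eqn{s_i^2 = \log\{1 + (\sigma/\eta_i)^2\}}, so that
#' \eqn{E[y_i] = \eta_i} and \eqn{SD[y_i] = \sigma} exactly, and
#' \eqn{y_i > 0} always.
#'
#' @inheritParams simulate_normal
#' @param sigma_target target per-observation standard deviation (> 0).
#' @return As [simulate_normal()].
#' @export
simulate_lognormal_rescaled <- function(design, model, theta, sigma_target,
                                        eps = NULL) {
  stopifnot(is_scalar_num(sigma_target), sigma_target > 0)
  X <- if (inherits(design, "exact_design")) design_points(design)
       else as_point_matrix(design, model$dim_x)
  eta <- model_mean(model, theta, X)
  if (any(eta <= 0)) {
    stop_input("log-normal errors require strictly positive means at all design points")
  }
  s2 <- log(1 + (sigma_target / eta)^2)
  if (is.null(eps)) eps <- stats::rnorm(nrow(X))
  y <- eta * exp(sqrt(s2) * eps - s2 / 2)
  out <- tibble::as_tibble(as.data.frame(X))
  out$y <- y
  attr(out, "theta_true") <- theta
  attr(out, "model") <- model$name
  out
}
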