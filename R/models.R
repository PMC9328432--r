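#' Define a nonlinear regression model
#'
#' A regression model is a mean function \eqn{\eta(\theta, x)} together with
#' its gradient in \eqn{\theta} and a box of admissible parameter values.
#' Both `mean` and `gradient` must be vectorized over design points: they
#' receive a parameter vector of length `dim_param` and an `n x dim_x` matrix
#' of design points, and return a length-`n` numeric vector and an
#' `n x dim_param` matrix, respectively.
#'
#' @param name identifier used in printing and serialization.
#' @param mean function `(theta, X) -> numeric(n)`.
#' @param gradient function `(theta, X) -> matrix(n, dim_param)`.
#' @param dim_param number of parameters \eqn{m}.
#' @param dim_x dimension of a design point (1 or 2 for the built-in models).
#' @param param_box `dim_param x 2` matrix of lower/upper parameter bounds;
#'   defaults to the whole space. Bounds may be infinite.
#'
#' @return An object of class `regression_model`.
#' @seealso [check_gradient()], [make_example1_problem()],
#'   [make_enzyme_problem()]
#' @export
regression_model <- function(name, mean, gradient, dim_param, dim_x = 1L,
                             param_box = NULL) {
  stopifnot(is.character(name), length(name) == 1L,
            is.function(mean), is.function(gradient),
            is_count(dim_param), is_count(dim_x))
  dim_param <- as.integer(dim_param)
  dim_x <- as.integer(dim_x)
  if (is.null(param_box)) {
    param_box <- cbind(lower = rep(-Inf, dim_param), upper = rep(Inf, dim_param))
  }
  param_box <- matrix(as.numeric(param_box), ncol = 2L,
                      dimnames = list(NULL, c("lower", "upper")))
  if (nrow(param_box) != dim_param || any(param_box[, 1] > param_box[, 2])) {
    stop_input("param_box must be a %d x 2 matrix with lower <= upper", dim_param)
  }
  structure(
    list(name = name, mean = mean, gradient = gradient,
         dim_param = dim_param, dim_x = dim_x, param_box = param_box),
    class = "regression_model"
  )
}

#' Evaluate a model mean at design points
#'
#' @param model a [regression_model()].
#' @param theta parameter vector.
#' @param x a design point (vector) or an `n x dim_x` matrix of points.
#' @return Numeric vector of mean responses.
#' @export
model_mean <- function(model, theta, x) {
  X <- as_point_matrix(x, model$dim_x)
  as.numeric(model$mean(as.numeric(theta), X))
}

#' Evaluate a model gradient at design points
#'
#' @inheritParams model_mean
#' @return `n x dim_param` matrix of gradients.
#' @export
model_gradient <- function(model, theta, x) {
  X <- as_point_matrix(x, model$dim_x)
  g <- model$gradient(as.numeric(theta), X)
  matrix(as.numeric(g), nrow = nrow(X), ncol = model$dim_param)
}

#' Check an analytic gradient against central finite differences
#'
#' Compares the model's analytic gradient with a central finite-difference
#' approximation of the mean function at a single design point.
#'
#' @inheritParams model_mean
#' @param h finite-difference step.
#' @return Maximum absolute deviation over the parameter components.
#' @export
check_gradient <- function(model, theta, x, h = 1e-6) {
  theta <- as.numeric(theta)
  X <- as_point_matrix(x, model$dim_x)
  ana <- model_gradient(model, theta, X)
  num <- matrix(NA_real_, nrow = nrow(X), ncol = model$dim_param)
  for (j in seq_len(model$dim_param)) {
    tp <- theta; tm <- theta
    tp[j] <- tp[j] + h
    tm[j] <- tm[j] - h
    fp <- model_mean(model, tp, X)
    fm <- model_mean(model, tm, X)
    if (any(!is.finite(fp)) || any(!is.finite(fm))) {
      stop_input(
        "mean of model '%s' is not finite at a perturbed parameter; check param_box",
        model$name)
    }
    num[, j] <- (fp - fm) / (2 * h)
  }
  max(abs(ana - num))
}

#' @export
print.regression_model <- function(x, ...) {
  cat(sprintf("<regression_model> %s: %d parameter(s), %d-dimensional design points\n",
              x$name, x$dim_param, x$dim_x))
  invisible(x)
}

#' Define a flexible nominal set
#'
#' A flexible nominal set is a cuboid centered at a nominal parameter vector
#' \eqn{\tilde\theta} with per-coordinate half-widths \eqn{\tilde\sigma};
#' dilating it by \eqn{r \ge 0} gives
#' \eqn{\prod_j [\tilde\theta_j - r\tilde\sigma_j,
#' \tilde\theta_j + r\tilde\sigma_j]}. `r = 0` is the point nominal and
#' `r = Inf` the whole space (in coordinates with positive half-width).
#'
#' @param nominal nominal parameter vector \eqn{\tilde\theta}.
#' @param half_width nonnegative vector of unit-cuboid half-widths
#'   \eqn{\tilde\sigma} (same length as `nominal`).
#' @return An object of class `nominal_set`.
#' @export
nominal_set <- function(nominal, half_width) {
  nominal <- as.numeric(nominal)
  half_width <- as.numeric(half_width)
  if (length(half_width) != length(nominal) || any(half_width < 0) ||
      any(!is.finite(half_width)) || any(!is.finite(nominal))) {
    stop_input("half_width must be a finite nonnegative vector matching nominal")
  }
  structure(list(nominal = nominal, half_width = half_width),
            class = "nominal_set")
}

#' Cuboid bounds of a dilated flexible nominal set
#'
#' @param nominal a [nominal_set()].
#' @param r dilation in `[0, Inf]`.
#' @return List with components `lower` and `upper`.
#' @export
cuboid_bounds <- function(nominal, r) {
  if (!is_scalar_num(r) || r < 0) stop_input("r must be a scalar >= 0 (Inf allowed)")
  w <- ifelse(nominal$half_width == 0, 0, r * nominal$half_width)
  list(lower = nominal$nominal - w, upper = nominal$nominal + w)
}

#' @export
print.nominal_set <- function(x, ...) {
  cat("<nominal_set>\n  nominal:    ", paste(signif(x$nominal, 6), collapse = ", "),
      "\n  half-width: ", paste(signif(x$half_width, 6), collapse = ", "), "\n")
  invisible(x)
}
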