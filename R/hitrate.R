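#' Monte-Carlo study configuration
#'
#' @param n_reps number of replicates N per (design, true model) cell.
#' @param c parameter-perturbation multiplier: each replicate draws the
#'   data-generating parameters uniformly from the nominal +- c x half-width
#'   cuboid (`c = 0` uses the nominals exactly).
#' @param sigma target error standard deviation.
#' @param error_model `"normal"` (additive) or `"lognormal_rescaled"`
#'   (multiplicative, mean-exact and variance-matched per point).
#' @param seed RNG seed; every stochastic run records it in the output.
#' @param n_starts number of start points of each nonlinear fit (the
#'   nominal plus `n_starts - 1` uniform draws from the unit cuboid).
#' @param fit_width half-width multiplier of the fitting box: parameter
#'   bounds are the model's box intersected with nominal +- `fit_width` x
#'   half-width (prevents divergence of the optimizer).
#' @return List of class `mc_config`.
#' @export
mc_config <- function(n_reps, c = 0, sigma, error_model = c("normal",
                                                            "lognormal_rescaled"),
                      seed = NULL, n_starts = 5, fit_width = 50) {
  stopifnot(is_count(n_reps), is_scalar_num(c), c >= 0,
            is_scalar_num(sigma), sigma > 0, is_count(n_starts),
            is_scalar_num(fit_width), fit_width > 0)
  structure(list(n_reps = as.integer(n_reps), c = c, sigma = sigma,
                 error_model = match.arg(error_model),
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 n_starts = as.integer(n_starts), fit_width = fit_width),
            class = "mc_config")
}

#' Error-variance base value of the enzyme-kinetics study
#'
#' Residual standard-deviation estimate from the encompassing-model fit of
#' the initial 120-observation experiment, used as the base value for
#' simulation error standard deviations (the confirmatory normal-error
#' study uses `2 * enzyme_sigma_hat()`, the large-sample log-normal study
#' `5 * enzyme_sigma_hat()`).
#'
#' @return The scalar 0.1526.
#' @export
enzyme_sigma_hat <- function() 0.1526

fit_bounds <- function(model, nominal, fit_width) {
  lower <- pmax(ifelse(model$param_box[, 1] == 0, 1e-9, model$param_box[, 1]),
                nominal$nominal - fit_width * nominal$half_width)
  upper <- pmin(model$param_box[, 2],
                nominal$nominal + fit_width * nominal$half_width)
  list(lower = lower, upper = upper)
}

#' Monte-Carlo hit rates of the likelihood-ratio discrimination rule
#'
#' For each design and each assumption about which model is true, runs
#' `config$n_reps` replicates of: draw perturbed data-generating parameters,
#' simulate observations, fit both models by bounded multistart nonlinear
#' least squares, and decide by the smaller residual sum of squares. The
#' *hit rate* is the percentage of replicates in which the true model is
#' selected.
#'
#' Within a replicate, the two true-model arms share their underlying
#' random draws (common random numbers): the error vector, the perturbation
#' uniforms, and the fit-start uniforms are drawn once per replicate and
#' reused for both arms. This makes the study symmetric under relabeling of
#' the two models and reduces the variance of design comparisons; replicates
#' remain independent.
#'
#' Replicates in which a fit fails for every start of either model are
#' counted in `n_failed` and cannot score as correct (the hit rate keeps
#' N in the denominator).
#'
#' @param problem a [discrimination_problem()].
#' @param designs a named list of [exact_design()]s (a single design is
#'   accepted); all must have the same size n.
#' @param config an [mc_config()].
#' @return A tibble of class `hit_rate_table` with one row per
#'   (design, true model): columns `design`, `true_model` (0/1), `c`,
#'   `sigma`, `error_model`, `N`, `n_correct`, `n_failed`, `hit_rate`
#'   (percent), and the binomial Monte-Carlo standard error `mc_se`
#'   (percentage points).
#' @export
hit_rate_study <- function(problem, designs, config) {
  stopifnot(inherits(config, "mc_config"))
  if (inherits(designs, "exact_design")) designs <- list(design = designs)
  if (is.null(names(designs)) || any(names(designs) == "")) {
    names(designs) <- paste0("design", seq_along(designs))
  }
  sizes <- vapply(designs, design_size, integer(1))
  if (length(unique(sizes)) != 1L) {
    stop_input("all designs in a study must have the same size n")
  }

  m <- problem$m
  N <- config$n_reps
  models <- list(problem$model0, problem$model1)
  nominals <- list(problem$nominal0, problem$nominal1)
  bounds <- lapply(1:2, function(k) {
    fit_bounds(models[[k]], nominals[[k]], config$fit_width)
  })
  lognormal <- config$error_model == "lognormal_rescaled"

  rows <- list()
  for (di in seq_along(designs)) {
    X <- design_points(designs[[di]])
    n_obs <- nrow(X)
    if (!is.null(config$seed)) {
      set.seed((config$seed + di - 1L) %% .Machine$integer.max)
    }
    correct <- matrix(0L, nrow = 2, ncol = 1)
    failed <- c(0L, 0L)
    n_correct <- c(0L, 0L)
    for (rep in seq_len(N)) {
      u_par <- stats::runif(m)
      eps <- stats::rnorm(n_obs)
      u_start <- matrix(stats::runif((config$n_starts - 1L) * m), ncol = m)
      for (k in 1:2) {
        theta_true <- perturb_params(nominals[[k]], config$c, u = u_par)
        eta <- model_mean(models[[k]], theta_true, X)
        y <- if (lognormal) {
          if (any(eta <= 0)) {
            stop_input("log-normal errors require positive means at all design points")
          }
          s2 <- log(1 + (config$sigma / eta)^2)
          eta * exp(sqrt(s2) * eps - s2 / 2)
        } else {
          eta + config$sigma * eps
        }
        rss <- numeric(2)
        ok <- logical(2)
        for (j in 1:2) {
          nm <- nominals[[j]]
          starts <- rbind(nm$nominal,
                          matrix(rep(nm$nominal, each = nrow(u_start)),
                                 ncol = m) +
                            (2 * u_start - 1) *
                            matrix(rep(nm$half_width, each = nrow(u_start)),
                                   ncol = m))
          fit <- fit_nls(models[[j]], X, y, starts,
                         lower = bounds[[j]]$lower, upper = bounds[[j]]$upper)
          rss[j] <- fit$rss
          ok[j] <- fit$converged
        }
        if (!all(ok)) {
          failed[k] <- failed[k] + 1L
          next
        }
        if (lr_decide(rss[1], rss[2]) == (k - 1L)) {
          n_correct[k] <- n_correct[k] + 1L
        }
      }
    }
    for (k in 1:2) {
      p <- n_correct[k] / N
      rows[[length(rows) + 1L]] <- tibble::tibble(
        design = names(designs)[di], true_model = k - 1L,
        c = config$c, sigma = config$sigma,
        error_model = config$error_model, N = N,
        n_correct = n_correct[k], n_failed = failed[k],
        hit_rate = 100 * p,
        mc_se = 100 * sqrt(p * (1 - p) / N))
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("hit_rate_table", class(out))
  attr(out, "seed") <- config$seed
  out
}

#' @describeIn hit_rate_study autoplot method: hit rates by design and true
#'   model, with Monte-Carlo error bars.
#' @param object a `hit_rate_table`.
#' @param ... unused.
#' @export
autoplot.hit_rate_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$true_model <- factor(df$true_model, levels = c(0, 1),
                          labels = c("model 0 true", "model 1 true"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$design, y = .data$hit_rate,
                                   colour = .data$true_model)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$hit_rate - 2 * .data$mc_se,
                   ymax = .data$hit_rate + 2 * .data$mc_se),
      width = 0.2, position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(x = NULL, y = "hit rate (%)", colour = NULL)
}

#' Write a hit-rate table to CSV with a metadata header
#'
#' @param x a `hit_rate_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hit_rate_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
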