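new_delta_search <- function(problem, r, n, method, best_idx, best_value,
                             per_start, traces, n_evaluations, seed) {
  best_design <- exact_design(problem$design_space[best_idx, , drop = FALSE])
  # store the value re-evaluated through the public path for exact agreement
  best_value <- delta_sq(problem, best_design, r)$delta_sq
  structure(
    list(best_design = best_design, best_delta_sq = best_value,
         r = r, n = n, method = method,
         per_start = per_start, traces = traces,
         n_evaluations = n_evaluations, seed = seed,
         problem_name = problem$name),
    class = "delta_search")
}

#' @export
print.delta_search <- function(x, ...) {
  cat(sprintf(paste0("<delta_search> %s on '%s': best delta^2 = %.6g ",
                     "(r = %s, n = %d, %g evaluations)\n"),
              x$method, x$problem_name, x$best_delta_sq, format(x$r), x$n,
              x$n_evaluations))
  print(x$best_design)
  invisible(x)
}

#' Maximize the delta criterion by a KL-type exchange heuristic
#'
#' From each random start (`n` points sampled uniformly with replacement
#' from the design space) the search repeatedly scans, in a randomized
#' position order, every exchange of one occupied point for one candidate
#' point, applies the best exchange if it improves the criterion by more
#' than `tol`, and stops at a local maximum. The best design over all starts
#' is returned. With a fixed `seed` the search is fully reproducible.
#'
#' @param problem a [discrimination_problem()].
#' @param n design size.
#' @param r dilation of the flexible nominal sets, in `[0, Inf]`.
#' @param n_starts number of random restarts.
#' @param seed optional RNG seed.
#' @param tol minimal accepted improvement of \eqn{\delta^2}.
#' @return An object of class `delta_search` with components `best_design`,
#'   `best_delta_sq`, `per_start` (tibble of per-start results), `traces`
#'   (per-start vectors of accepted criterion values), `n_evaluations`, and
#'   `seed`.
#' @export
kl_exchange <- function(problem, n, r, n_starts = 20, seed = NULL, tol = 1e-12) {
  if (!is_count(n)) stop_input("n must be a positive integer")
  if (!is_scalar_num(r) || r < 0) stop_input("r must be >= 0 (Inf allowed)")
  if (!is_count(n_starts)) stop_input("n_starts must be a positive integer")
  seed_set(seed)
  d <- nrow(problem$design_space)
  starts <- matrix(sample.int(d, n * n_starts, replace = TRUE), nrow = n)
  w <- stacked_half_widths(problem, r)
  res <- cpp_kl_exchange(problem$cache$G, problem$cache$Delta, w, starts, tol)
  per_start <- tibble::tibble(start = seq_len(n_starts),
                              delta_sq = as.numeric(res$per_start),
                              n_scans = as.integer(res$per_start_iters))
  out <- new_delta_search(problem, r, n, "kl_exchange",
                          as.integer(res$best_idx), res$best_value,
                          per_start, res$traces, res$n_evaluations, seed)
  if (out$best_delta_sq <= tol) {
    warn(sprintf(paste0("best delta^2 = %.3g <= tol: designs are ",
                        "indistinguishable at r = %s (r may exceed the set ",
                        "upper bound)"), out$best_delta_sq, format(r)))
  }
  out
}

# all n-multisets of 1..d, as an n x K index matrix
multiset_index_matrix <- function(d, n) {
  comb <- utils::combn(d + n - 1L, n)
  comb - (seq_len(n) - 1L)
}

#' Maximize the delta criterion by complete enumeration
#'
#' Enumerates all \eqn{\binom{d + n - 1}{n}} n-point multisets of the
#' design space and returns the exact optimum. Feasible only for small
#' problems; the combinatorial bound `max_multisets` guards against
#' accidental explosion.
#'
#' @inheritParams kl_exchange
#' @param max_multisets upper limit on the number of enumerated designs.
#' @return A `delta_search` object (see [kl_exchange()]); `per_start` holds
#'   the single enumeration result.
#' @export
exhaustive_search <- function(problem, n, r, max_multisets = 2e5) {
  if (!is_count(n)) stop_input("n must be a positive integer")
  d <- nrow(problem$design_space)
  K <- choose(d + n - 1, n)
  if (K > max_multisets) {
    stop_input(paste0("enumeration of %.0f multisets exceeds max_multisets = %.0f; ",
                      "use kl_exchange()"), K, max_multisets)
  }
  idx <- multiset_index_matrix(d, n)
  w <- stacked_half_widths(problem, r)
  vals <- cpp_eval_designs(problem$cache$G, problem$cache$Delta, w, idx)
  best <- which.max(vals)
  per_start <- tibble::tibble(start = 1L, delta_sq = vals[best],
                              n_scans = NA_integer_)
  new_delta_search(problem, r, n, "exhaustive",
                   idx[, best], vals[best], per_start,
                   list(vals[best]), ncol(idx), NULL)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @describeIn kl_exchange tidy method: the best design as a tibble
#'   (support points and multiplicities).
#' @param x a `delta_search` object.
#' @param ... unused.
#' @export
tidy.delta_search <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x$best_design))
}

#' @describeIn kl_exchange glance method: one-row summary tibble.
#' @export
glance.delta_search <- function(x, ...) {
  tibble::tibble(method = x$method, problem = x$problem_name,
                 r = x$r, n = x$n, best_delta_sq = x$best_delta_sq,
                 n_support = nrow(x$best_design),
                 n_evaluations = x$n_evaluations,
                 seed = if (is.null(x$seed)) NA_integer_ else as.integer(x$seed))
}

#' @describeIn kl_exchange autoplot method: the support of the best design
#'   (multiplicities against design points).
#' @param object a `delta_search` object.
#' @export
autoplot.delta_search <- function(object, ...) {
  df <- tidy(object)
  if (!"x2" %in% names(df)) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$x1, y = .data$mult)) +
      ggplot2::geom_segment(ggplot2::aes(xend = .data$x1, yend = 0)) +
      ggplot2::geom_point() +
      ggplot2::labs(x = "design point", y = "replications",
                    title = sprintf("delta-optimal design (r = %s, n = %d)",
                                    format(object$r), object$n))
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$x1, y = .data$x2,
                                     size = .data$mult)) +
      ggplot2::geom_point(alpha = 0.8) +
      ggplot2::labs(x = "substrate x1", y = "inhibitor x2",
                    size = "replications",
                    title = sprintf("delta-optimal design (r = %s, n = %d)",
                                    format(object$r), object$n))
  }
}

#' @importFrom rlang .data
NULL

#' Serialize a search result to JSON
#'
#' @param x a `delta_search` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_search_json <- function(x, path) {
  obj <- list(meta = pkg_meta(seed = x$seed),
              method = x$method, problem = x$problem_name,
              r = if (is.finite(x$r)) x$r else "inf",
              n = x$n, best_delta_sq = x$best_delta_sq,
              best_design = as.data.frame(x$best_design),
              per_start = as.data.frame(x$per_start),
              traces = lapply(x$traces, as.numeric),
              n_evaluations = x$n_evaluations)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
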