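#' Exact designs
#'
#' An exact design is a multiset of \eqn{n} design points, stored in its
#' counting-measure view: a tibble with one row per distinct point
#' (coordinate columns `x1`, ... ) and an integer `mult` column of
#' multiplicities summing to \eqn{n}. Rows are kept in canonical
#' (lexicographic) order so that equal designs compare equal.
#'
#' @param points matrix/data frame of design points (one row per point,
#'   repeats allowed) or, for one-dimensional design spaces, a numeric
#'   vector.
#' @param mult optional multiplicities (recycled length-1 allowed); defaults
#'   to 1 per row of `points`.
#' @param dim_x design-point dimension; inferred from `points` when missing.
#'
#' @return A tibble of class `exact_design`.
#' @export
exact_design <- function(points, mult = NULL, dim_x = NULL) {
  if (is.null(dim_x)) {
    dim_x <- if (is.null(dim(points))) 1L else ncol(points)
  }
  X <- as_point_matrix(points, dim_x)
  if (is.null(mult)) mult <- rep(1L, nrow(X))
  if (length(mult) == 1L) mult <- rep(mult, nrow(X))
  mult <- as.integer(mult)
  if (length(mult) != nrow(X) || any(mult < 0) || any(is.na(mult))) {
    stop_input("mult must be nonnegative integers, one per design point")
  }
  keep <- mult > 0
  X <- X[keep, , drop = FALSE]
  mult <- mult[keep]
  if (sum(mult) < 1L) stop_input("an exact design needs at least one point")

  df <- tibble::as_tibble(as.data.frame(X))
  df$mult <- mult
  df <- dplyr::summarise(dplyr::group_by(df, dplyr::across(-"mult")),
                         mult = sum(.data$mult), .groups = "drop")
  df <- dplyr::arrange(df, dplyr::across(-"mult"))
  class(df) <- c("exact_design", class(df))
  df
}

#' @export
print.exact_design <- function(x, ...) {
  cat(sprintf("<exact_design> n = %d observation(s) at %d support point(s)\n",
              design_size(x), nrow(x)))
  NextMethod()
}

#' Number of observations of an exact design
#' @param design an [exact_design()].
#' @return Integer \eqn{n}.
#' @export
design_size <- function(design) sum(design$mult)

#' Expand an exact design to its point list
#'
#' @param design an [exact_design()].
#' @return `n x dim_x` matrix with one row per observation (repeats
#'   expanded).
#' @export
design_points <- function(design) {
  X <- as.matrix(design[setdiff(names(design), "mult")])
  storage.mode(X) <- "double"
  X[rep(seq_len(nrow(X)), design$mult), , drop = FALSE]
}

#' Replicate a design s-fold
#'
#' @param design an [exact_design()].
#' @param s positive integer replication factor.
#' @return The design with all multiplicities multiplied by `s`.
#' @export
replicate_design <- function(design, s) {
  if (!is_count(s)) stop_input("s must be a positive integer")
  exact_design(as.matrix(design[setdiff(names(design), "mult")]),
               design$mult * as.integer(s))
}

#' Uniformly random n-point design on a problem's design space
#'
#' @param problem a [discrimination_problem()].
#' @param n design size.
#' @param seed optional RNG seed.
#' @return An [exact_design()].
#' @export
random_design <- function(problem, n, seed = NULL) {
  if (!is_count(n)) stop_input("n must be a positive integer")
  seed_set(seed)
  idx <- sample.int(nrow(problem$design_space), n, replace = TRUE)
  exact_design(problem$design_space[idx, , drop = FALSE])
}

# map design rows to design-space row indices (error if a point is missing)
design_space_index <- function(problem, design) {
  X <- design_points(design)
  sp <- problem$design_space
  idx <- integer(nrow(X))
  for (i in seq_len(nrow(X))) {
    dd <- colSums(abs(t(sp) - X[i, ]))
    j <- which.min(dd)
    if (dd[j] > 1e-8) {
      stop_input("design point (%s) is not in the problem's design space",
                 paste(signif(X[i, ], 6), collapse = ", "))
    }
    idx[i] <- j
  }
  idx
}

#' Relative delta-efficiency of two designs
#'
#' Computes \eqn{\delta_r^2(D_1) / \delta_r^2(D_2)}: by positive homogeneity
#' of the criterion this is a statistically interpretable relative
#' efficiency (an s-fold replication of a design is exactly s times as
#' efficient).
#'
#' @param problem a [discrimination_problem()].
#' @param design1,design2 [exact_design()] objects.
#' @param r dilation of the flexible nominal sets.
#' @return Scalar efficiency; errors if \eqn{\delta_r^2(D_2) = 0}.
#' @export
efficiency <- function(problem, design1, design2, r) {
  d2 <- delta_sq(problem, design2, r)$delta_sq
  if (d2 <= 1e-12) stop_input("efficiency undefined: reference design has delta^2 = 0")
  delta_sq(problem, design1, r)$delta_sq / d2
}

#' Read / write exact designs
#'
#' Designs are exchanged as plain CSV (coordinate columns plus `mult`) or as
#' JSON with package metadata. Reading canonicalizes the design, so a
#' write/read round trip is the identity.
#'
#' @param design an [exact_design()].
#' @param path file path.
#' @return `read_design_*` return an [exact_design()]; the writers return
#'   `path` invisibly.
#' @name design_io
NULL

#' @rdname design_io
#' @export
write_design_csv <- function(design, path) {
  utils::write.csv(as.data.frame(design), path, row.names = FALSE)
  invisible(path)
}

#' @rdname design_io
#' @export
read_design_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!"mult" %in% names(df)) stop_input("design CSV must have a 'mult' column")
  exact_design(as.matrix(df[setdiff(names(df), "mult")]), df$mult)
}

#' @rdname design_io
#' @param seed optional seed recorded in the JSON metadata.
#' @export
write_design_json <- function(design, path, seed = NULL) {
  obj <- list(meta = pkg_meta(seed = seed),
              points = as.data.frame(design[setdiff(names(design), "mult")]),
              mult = design$mult)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname design_io
#' @export
read_design_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  exact_design(as.matrix(obj$points), obj$mult)
}
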