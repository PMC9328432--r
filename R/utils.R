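#' @importFrom rlang abort warn %||%
#' @importFrom Rcpp sourceCpp
#' @useDynLib deltadiscrim, .registration = TRUE
NULL

# user-input error (CLI maps these to exit code 1)
stop_input <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "deltadiscrim_input_error")
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)

# coerce a design point (or point set) to an n x dim_x matrix
as_point_matrix <- function(x, dim_x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) {
    x <- if (dim_x == 1L) matrix(as.numeric(x), ncol = 1L)
         else matrix(as.numeric(x), ncol = dim_x, byrow = TRUE)
  }
  storage.mode(x) <- "double"
  if (ncol(x) != dim_x) {
    stop_input("design points have %d coordinate(s); expected %d", ncol(x), dim_x)
  }
  colnames(x) <- paste0("x", seq_len(dim_x))
  x
}

# stacked cuboid half-widths r * sigma, with the convention 0 * Inf = 0
stacked_half_widths <- function(problem, r) {
  hw <- c(problem$nominal0$half_width, problem$nominal1$half_width)
  w <- ifelse(hw == 0, 0, r * hw)
  w[is.na(w)] <- 0
  w
}

stacked_nominal <- function(problem) {
  c(problem$nominal0$nominal, problem$nominal1$nominal)
}

seed_set <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

pkg_meta <- function(seed = NULL, command = NULL, problem = NULL) {
  out <- list(
    package = "deltadiscrim",
    version = as.character(utils::packageVersion("deltadiscrim"))
  )
  if (!is.null(seed)) out$seed <- as.integer(seed)
  if (!is.null(command)) out$command <- command
  if (!is.null(problem)) out$problem_hash <- problem_hash(problem)
  out
}
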