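# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, restoring the previous
#' RNG state afterwards so callers' random streams are untouched. With
#' `seed = NULL` the current stream is used as-is.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Column standard deviations (ddof = 1 by default), without forming copies
# per column.
col_sds <- function(m, ddof = 1L) {
  n <- nrow(m)
  mu <- colMeans(m)
  ss <- colSums(m * m) - n * mu * mu
  ss[ss < 0] <- 0  # guard tiny negative rounding
  sqrt(ss / (n - ddof))
}

# Full-precision decimal formatting: survives a text round-trip bit-exactly.
fmt_num <- function(x) sprintf("%.17g", x)

stop_if_not <- function(cond, ...) {
  if (!isTRUE(cond)) stop(..., call. = FALSE)
}

# Extract the numeric matrix from any of the package's matrix-bearing types.
as_values <- function(x) {
  if (inherits(x, "neural_responses")) return(x$values)
  if (is.matrix(x)) {
    y <- x
    class(y) <- NULL
    return(y)
  }
  if (is.numeric(x)) return(as.matrix(x))
  stop("cannot extract a numeric matrix from an object of class ",
       paste(class(x), collapse = "/"), call. = FALSE)
}
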