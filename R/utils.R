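# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code under a fixed RNG state, restoring the caller's state
#'
#' All randomized operations in the package route their draws through this
#' helper so that every function is a pure function of (inputs, seed) and
#' never perturbs the session RNG. The generator family is fixed to
#' Mersenne-Twister with "Rejection" sampling so a recorded seed reproduces
#' draws bit-exactly across R versions >= 3.6.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  old_kind <- RNGkind()
  on.exit({
    RNGkind(old_kind[1L], old_kind[2L], old_kind[3L])
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  }, add = TRUE)
  RNGkind("Mersenne-Twister", "Inversion", "Rejection")
  set.seed(as.integer(seed))
  code
}

# Stop with a consistent message when a scalar argument is out of range.
check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (integer && x != round(x)) {
    stop(sprintf("'%s' must be an integer", name), call. = FALSE)
  }
  if ((strict_lower && x <= lower) || (!strict_lower && x < lower) || x > upper) {
    stop(sprintf("'%s' = %s is outside its allowed range", name, format(x)),
         call. = FALSE)
  }
  invisible(x)
}

# Validate a genes x columns count matrix; returns it with dimnames enforced.
check_counts <- function(counts, name = "counts") {
  if (inherits(counts, "Matrix")) counts <- as.matrix(counts)
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop(sprintf("'%s' must be a numeric genes x columns matrix", name),
         call. = FALSE)
  }
  if (any(counts < 0)) {
    stop(sprintf("'%s' contains negative entries", name), call. = FALSE)
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop(sprintf("'%s' must carry gene ids (rownames) and column ids (colnames)",
                 name), call. = FALSE)
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    stop(sprintf("'%s' has duplicated gene or column ids", name), call. = FALSE)
  }
  counts
}

# Row-wise variance of a numeric matrix without forming residual copies per gene.
row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2L) return(rep(NA_real_, nrow(x)))
  m <- rowMeans(x)
  (rowSums(x * x) - n * m * m) / (n - 1)
}
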