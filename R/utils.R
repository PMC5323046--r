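# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code with a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, runs `code`, and
#' restores the previous state on exit, so simulation functions are
#' deterministic without clobbering the session RNG.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# Derive a reproducible substream seed (< 2^31) from a master seed and one or
# more stream indices. Products stay below 2^53 so double arithmetic is exact.
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- (as.numeric(master) %% 2147483647)
  for (k in idx) {
    s <- (s * 69069 + as.numeric(k) * 6619 + 12345) %% 2147483647
  }
  as.integer(s) + 1L
}

# Geometric mean, NA-safe for strictly positive input.
geomean <- function(x) exp(mean(log(x)))

# Robust scale: MAD rescaled for Gaussian consistency.
rmad <- function(x, center = stats::median(x)) {
  stats::mad(x, center = center, constant = 1.4826)
}

stop_named <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop_named(fmt, ...)
  invisible(TRUE)
}

# Column presence check for data.frame contracts.
need_cols <- function(df, cols, what = "input table") {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop_named("%s is missing required column(s): %s", what,
               paste(miss, collapse = ", "))
  }
  invisible(TRUE)
}
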