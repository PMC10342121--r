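# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `expr` with the global random-number state set from `seed` and
#' restores the previous state afterwards, so deterministic generators do
#' not disturb the caller's random stream. With `seed = NULL` the
#' expression runs against the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number or NULL", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Gaussian profile parameterized by peak height, center and FWHM.
FWHM_SIGMA <- 2 * sqrt(2 * log(2))

gauss_band <- function(x, center, fwhm, amplitude = 1) {
  sigma <- fwhm / FWHM_SIGMA
  amplitude * exp(-((x - center)^2) / (2 * sigma^2))
}

# Area under a Gaussian of given peak height and FWHM.
gauss_area <- function(amplitude, fwhm) {
  amplitude * (fwhm / FWHM_SIGMA) * sqrt(2 * pi)
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("xm_config_error", "xm_error")))
}

stop_domain <- function(...) {
  stop(errorCondition(paste0(...), class = c("xm_domain_error", "xm_error")))
}

stop_numeric <- function(msg, diagnostics = NULL) {
  stop(errorCondition(msg, diagnostics = diagnostics,
                      class = c("xm_numeric_error", "xm_error")))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("xm_data_error", "xm_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Linear interpolation of the two half-maximum crossings of a single band.
# Returns NA if either crossing is missing inside the trace.
half_max_width <- function(x, y) {
  imax <- which.max(y)
  half <- y[imax] / 2
  left <- NA_real_
  for (i in seq(imax, 2L)) {
    if (y[i - 1L] <= half && y[i] >= half) {
      left <- x[i - 1L] + (half - y[i - 1L]) / (y[i] - y[i - 1L]) * (x[i] - x[i - 1L])
      break
    }
  }
  right <- NA_real_
  for (i in seq(imax, length(y) - 1L)) {
    if (y[i + 1L] <= half && y[i] >= half) {
      right <- x[i] + (y[i] - half) / (y[i] - y[i + 1L]) * (x[i + 1L] - x[i])
      break
    }
  }
  if (is.na(left) || is.na(right)) return(NA_real_)
  right - left
}
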