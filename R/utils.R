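#' Sample skewness
#'
#' Third standardized moment \eqn{m_3 / m_2^{3/2}} with biased (population)
#' central moments, the convention used when characterizing expression
#' distributions per region before cross-platform discretization.
#'
#' @param x numeric vector, length >= 3, non-constant.
#' @return scalar skewness.
#' @export
sample_skewness <- function(x) {
  x <- check_finite_numeric(x, "x")
  if (length(x) < 3L) stop("skewness needs at least 3 values")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("skewness undefined for constant values")
  mean((x - m)^3) / m2^1.5
}

#' Sample kurtosis
#'
#' Fourth standardized moment \eqn{m_4 / m_2^2}. Reported raw (non-excess) by
#' default; `excess = TRUE` subtracts 3.
#'
#' @param x numeric vector, length >= 4, non-constant.
#' @param excess logical; subtract 3 if `TRUE`.
#' @return scalar kurtosis.
#' @export
sample_kurtosis <- function(x, excess = FALSE) {
  x <- check_finite_numeric(x, "x")
  if (length(x) < 4L) stop("kurtosis needs at least 4 values")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("kurtosis undefined for constant values")
  k <- mean((x - m)^4) / m2^2
  if (excess) k - 3 else k
}

check_finite_numeric <- function(x, what) {
  if (!is.numeric(x)) stop(sprintf("%s must be numeric", what))
  if (anyNA(x) || any(!is.finite(x))) {
    stop(sprintf("%s contains missing or non-finite values", what))
  }
  as.numeric(x)
}

#' @keywords internal
msg <- function(..., verbose = getOption("nicheGRN.verbose", FALSE)) {
  if (isTRUE(verbose)) message(sprintf(...))
  invisible(NULL)
}

# Median with the mean-of-middle convention for even counts (stats::median
# already does this; kept as a named wrapper so the summarization contract is
# explicit at call sites).
mid_median <- function(x) stats::median(x)
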