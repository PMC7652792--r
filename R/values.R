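#' Beta-value from methylated/unmethylated intensities
#'
#' The beta-value of a CpG probe is the methylated fraction
#' \eqn{\beta = M / (M + U + \alpha)}, where the offset \eqn{\alpha}
#' (default 100) regularizes the ratio when the overall intensity is low.
#'
#' @param meth,unmeth Non-negative intensity vectors (recycled to a common
#'   length).
#' @param alpha Non-negative count-like offset added to the denominator.
#' @return A numeric vector of beta-values in `[0, 1)`.
#' @examples
#' beta_from_intensities(900, 0)        # 0.9
#' beta_from_intensities(5000, 5000)    # ~0.495
#' @export
beta_from_intensities <- function(meth, unmeth, alpha = 100) {
  check_intensities(meth, unmeth)
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha < 0) {
    stop("`alpha` must be a single non-negative number.", call. = FALSE)
  }
  meth / (meth + unmeth + alpha)
}

#' M-value from methylated/unmethylated intensities
#'
#' The M-value is the log2 intensity ratio
#' \eqn{M\text{-value} = \log_2((M + \alpha) / (U + \alpha))}, with a small
#' offset \eqn{\alpha} (default 1) damping the effect of intensity estimation
#' error near zero. M-values near 0 indicate hemimethylation; positive values
#' indicate predominantly methylated copies.
#'
#' @inheritParams beta_from_intensities
#' @param alpha Non-negative offset added to numerator and denominator. Must be
#'   positive wherever an intensity is zero.
#' @return A numeric vector of M-values.
#' @examples
#' m_from_intensities(3, 0)        # log2(4/1) = 2
#' m_from_intensities(1023, 255)   # 2
#' @export
m_from_intensities <- function(meth, unmeth, alpha = 1) {
  check_intensities(meth, unmeth)
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha < 0) {
    stop("`alpha` must be a single non-negative number.", call. = FALSE)
  }
  if (alpha == 0 && any(meth == 0 | unmeth == 0, na.rm = TRUE)) {
    stop("zero intensity with `alpha` = 0 gives an undefined log-ratio.",
         call. = FALSE)
  }
  log2((meth + alpha) / (unmeth + alpha))
}

#' Convert beta-values to M-values
#'
#' Applies the logit-like map \eqn{M = \log_2(\beta / (1 - \beta))} after
#' clamping beta into `[eps, 1 - eps]` so that boundary values 0 and 1 stay
#' finite. The map is strictly monotone and inverted exactly by [m_to_beta()]
#' on the clamped domain.
#'
#' @param beta Numeric vector of beta-values in `[0, 1]`; `NA` passes through.
#' @param eps Clamping constant in `(0, 0.5)`.
#' @return A numeric vector of M-values.
#' @examples
#' beta_to_m(c(0.5, 0.8))  # 0, 2
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  if (!is.numeric(beta)) stop("`beta` must be numeric.", call. = FALSE)
  if (!is.numeric(eps) || length(eps) != 1L || eps <= 0 || eps >= 0.5) {
    stop("`eps` must be a single number in (0, 0.5).", call. = FALSE)
  }
  bad <- !is.na(beta) & (beta < 0 | beta > 1)
  if (any(bad)) {
    stop("beta-values outside [0, 1]: ",
         paste(utils::head(signif(beta[bad], 4), 5), collapse = ", "),
         call. = FALSE)
  }
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' Convert M-values to beta-values
#'
#' The inverse of [beta_to_m()]: \eqn{\beta = 2^M / (2^M + 1)}. Output is
#' strictly inside `(0, 1)` for finite input.
#'
#' @param m Numeric vector of finite M-values; `NA` passes through.
#' @return A numeric vector of beta-values in `(0, 1)`.
#' @examples
#' m_to_beta(c(0, 2))  # 0.5, 0.8
#' @export
m_to_beta <- function(m) {
  if (!is.numeric(m)) stop("`m` must be numeric.", call. = FALSE)
  if (any(!is.finite(m) & !is.na(m))) {
    stop("M-values must be finite.", call. = FALSE)
  }
  # plogis(x * log(2)) = 2^x / (2^x + 1), stable for large |m|
  stats::plogis(m * log(2))
}

check_intensities <- function(meth, unmeth) {
  if (!is.numeric(meth) || !is.numeric(unmeth)) {
    stop("intensities must be numeric.", call. = FALSE)
  }
  if (any(meth < 0, na.rm = TRUE) || any(unmeth < 0, na.rm = TRUE)) {
    stop("intensities must be non-negative.", call. = FALSE)
  }
  invisible(NULL)
}
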