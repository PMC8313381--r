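#' Methylation level from allele intensities
#'
#' The beta-value is the proportion-scale methylation level computed from
#' the methylated (M) and unmethylated (U) allele intensities as
#' `max(M,0) / (max(M,0) + max(U,0) + offset)`.  The positive offset
#' stabilises the ratio at low total intensity and keeps the result strictly
#' below 1.
#'
#' @param m_int methylated-allele intensity (negative values are clamped to 0).
#' @param u_int unmethylated-allele intensity (clamped likewise).
#' @param offset positive stabilising constant added to the denominator
#'   (default 100, the array convention).
#' @return beta-values in `[0, 1)`; vectorised.
#' @examples
#' beta_from_intensities(100, 0)    # 0.5
#' beta_from_intensities(300, 100)  # 0.6
#' @export
beta_from_intensities <- function(m_int, u_int, offset = 100) {
  if (!is.numeric(offset) || length(offset) != 1L || !is.finite(offset) || offset <= 0)
    stop("'offset' must be a single positive number")
  m <- pmax(m_int, 0)
  u <- pmax(u_int, 0)
  m / (m + u + offset)
}

#' Convert between beta-values and M-values
#'
#' M-values are the log2-odds transform of beta-values,
#' `M = log2(beta / (1 - beta))`, the scale on which differential analysis
#' is carried out: M = 0 means half-methylated, positive M more than 50%
#' methylated.  `beta_from_m()` is the exact inverse, `2^M / (1 + 2^M)`.
#'
#' Beta-values of exactly 0 or 1 (which intensity-derived values never
#' produce, but user-supplied files may) are clipped to
#' `[eps, 1 - eps]` with a warning, or rejected when `on_boundary = "error"`.
#'
#' @param beta beta-values in `[0, 1]`.
#' @param m finite M-values.
#' @param on_boundary `"clip"` (default) or `"error"`: handling of beta
#'   exactly 0 or 1.
#' @param eps clipping tolerance (default 1e-6).
#' @return numeric vector (or matrix, matching the input shape).
#' @examples
#' m_from_beta(0.5)   # 0
#' m_from_beta(0.8)   # 2
#' beta_from_m(2)     # 0.8
#' @export
m_from_beta <- function(beta, on_boundary = c("clip", "error"), eps = 1e-6) {
  on_boundary <- match.arg(on_boundary)
  if (any(!is.finite(beta)) || any(beta < 0) || any(beta > 1))
    stop("beta-values must be finite and in [0, 1]")
  bad <- beta <= 0 | beta >= 1
  if (any(bad)) {
    if (on_boundary == "error")
      stop(sum(bad), " beta-value(s) at the 0/1 boundary")
    warning(sum(bad), " beta-value(s) at the 0/1 boundary clipped to [",
            eps, ", ", 1 - eps, "]")
    beta <- pmin(pmax(beta, eps), 1 - eps)
  }
  log2(beta / (1 - beta))
}

#' @rdname m_from_beta
#' @export
beta_from_m <- function(m) {
  if (any(!is.finite(m))) stop("M-values must be finite")
  # 1/(1 + 2^-m) is stable for large |m| in both directions
  1 / (1 + 2^(-m))
}

#' Classify beta-values as hypo-, intermediate or hypermethylated
#'
#' Uses the conventional thresholds 0.2 (hypomethylation) and 0.8
#' (hypermethylation); comparisons are strict, so a beta-value exactly at a
#' threshold is `intermediate`.
#'
#' @param beta beta-values in `[0, 1]`.
#' @param lo,hi thresholds with `0 <= lo < hi <= 1`.
#' @return factor with levels `hypo`, `intermediate`, `hyper`.
#' @examples
#' classify_methylation(c(0.1, 0.5, 0.9))
#' @export
classify_methylation <- function(beta, lo = 0.2, hi = 0.8) {
  if (!(is.numeric(lo) && is.numeric(hi) && length(lo) == 1L && length(hi) == 1L))
    stop("'lo' and 'hi' must be single numbers")
  if (!(lo >= 0 && lo < hi && hi <= 1))
    stop("thresholds must satisfy 0 <= lo < hi <= 1")
  if (any(!is.finite(beta)) || any(beta < 0) || any(beta > 1))
    stop("beta-values must be finite and in [0, 1]")
  out <- rep("intermediate", length(beta))
  out[beta < lo] <- "hypo"
  out[beta > hi] <- "hyper"
  factor(out, levels = c("hypo", "intermediate", "hyper"))
}
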