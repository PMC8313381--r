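#' Probe-wise least-squares fits under a shared design
#'
#' Fits `E(y_j) = X alpha_j` by ordinary least squares for every probe
#' (row of `Y`), with a shared samples-by-parameters design matrix.  When a
#' contrast matrix is supplied, the contrast estimates
#' `beta_jt = (C' alpha_j)_t` and their unscaled variances
#' `v_t = diag(C' (X'X)^-1 C)` are computed as well.
#'
#' @param Y probe-by-sample numeric matrix.
#' @param X design matrix (samples x parameters), full column rank.
#' @param contrasts optional contrast matrix `C` (parameters x contrasts).
#' @return object of class `"linear_fit"`: list with `coefficients`
#'   (probes x parameters), `sigma2` (residual variances), `df_residual`,
#'   `design`, and — when contrasts are given — `contrasts`, `beta`
#'   (probes x contrasts), `v` (unscaled contrast variances) and `vcov_unscaled`
#'   (`C'(X'X)^-1 C`).
#' @export
fit_linear_models <- function(Y, X, contrasts = NULL) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  if (ncol(Y) != nrow(X)) stop("ncol(Y) must equal nrow(X)")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]] %||%
      qx$pivot[(qx$rank + 1L):ncol(X)]
    stop("design matrix is rank deficient; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  n <- nrow(X)
  d <- n - qx$rank
  if (d < 1L) stop("no residual degrees of freedom (n <= rank(X))")
  xtx_inv <- chol2inv(qr.R(qx))
  dimnames(xtx_inv) <- list(colnames(X), colnames(X))
  A <- Y %*% X %*% xtx_inv                      # probe-wise alpha-hat
  colnames(A) <- colnames(X)
  res <- Y - A %*% t(X)
  s2 <- rowSums(res^2) / d
  out <- list(coefficients = A, sigma2 = unname(s2), df_residual = d,
              design = X)
  if (!is.null(contrasts)) {
    C <- as.matrix(contrasts)
    if (nrow(C) != ncol(X)) stop("contrast matrix rows must match design columns")
    out$contrasts <- C
    out$beta <- A %*% C
    out$vcov_unscaled <- t(C) %*% xtx_inv %*% C
    out$v <- diag(out$vcov_unscaled)
  }
  class(out) <- "linear_fit"
  out
}

#' Tissue-by-sex cell-means design and sex-difference contrasts
#'
#' `design_tissue_sex()` builds the 6-column cell-means design
#' (tissue x sex, columns `ATM.male`, `ATM.female`, ..., `NTM.female`),
#' erroring when a cell is empty and warning on singleton cells.
#' `sex_within_tissue_contrasts()` returns the 6 x 3 contrast matrix of the
#' male-minus-female difference within each tissue (columns `ATM`, `CAM`,
#' `NTM`); every column sums to zero.
#'
#' @param samples sample sheet (see [validate_sample_sheet()]).
#' @return design matrix, or contrast matrix.
#' @export
design_tissue_sex <- function(samples) {
  samples <- validate_sample_sheet(samples)
  cells <- expand.grid(sex = c("male", "female"),
                       tissue = c("ATM", "CAM", "NTM"),
                       stringsAsFactors = FALSE)
  lev <- paste(cells$tissue, cells$sex, sep = ".")
  f <- factor(paste(samples$tissue, samples$sex, sep = "."), levels = lev)
  cnt <- table(f)
  if (any(cnt == 0L))
    stop("empty tissue-by-sex cell(s): ",
         paste(names(cnt)[cnt == 0L], collapse = ", "))
  if (any(cnt == 1L))
    warning("singleton tissue-by-sex cell(s): ",
            paste(names(cnt)[cnt == 1L], collapse = ", "),
            " (their within-cell variance is inestimable)")
  X <- stats::model.matrix(~ 0 + f)
  colnames(X) <- lev
  rownames(X) <- samples$sample_id
  X
}

#' @rdname design_tissue_sex
#' @export
sex_within_tissue_contrasts <- function() {
  lev <- paste(rep(c("ATM", "CAM", "NTM"), each = 2L),
               c("male", "female"), sep = ".")
  C <- matrix(0, 6L, 3L, dimnames = list(lev, c("ATM", "CAM", "NTM")))
  for (t in c("ATM", "CAM", "NTM")) {
    C[paste(t, "male", sep = "."), t] <- 1
    C[paste(t, "female", sep = "."), t] <- -1
  }
  C
}

# Newton inversion of trigamma (solve trigamma(x) = y), y > 0
.trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2L)
    x <- x + dif
    if (abs(dif) / x < 1e-8) break
  }
  x
}

#' Empirical-Bayes prior for the residual variances
#'
#' Fits a scaled inverse-chi-square prior `s2 ~ s0^2 * d0 / chisq(d0)` to
#' the observed probe variances by moment matching on the log scale: the
#' mean and spread of `log s2` are matched to their theoretical values using
#' digamma/trigamma identities, with the trigamma equation solved by Newton
#' iteration.  When the observed spread of `log s2` is at or below its pure
#' sampling floor the prior degrees of freedom are infinite (all variances
#' shrink fully to `s0^2`).
#'
#' @param s2 positive residual variances (one per probe).
#' @param df residual degrees of freedom (scalar or per-probe, >= 1).
#' @return list with `d0` (prior df, possibly `Inf`) and `s02` (prior
#'   variance).
#' @export
estimate_variance_prior <- function(s2, df) {
  if (length(s2) < 2L) stop("need >= 2 probes")
  df <- rep_len(df, length(s2))
  if (any(df < 1L)) stop("residual df must be >= 1")
  if (all(s2 <= 0)) stop("all residual variances are zero")
  pos <- s2 > 0
  if (!all(pos)) {
    warning(sum(!pos), " zero residual variance(s) excluded from prior estimation")
    s2 <- s2[pos]; df <- df[pos]
  }
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- mean((e - emean)^2 * n / (n - 1L) - trigamma(df / 2))
  if (evar > 0) {
    d0 <- 2 * .trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # spread of log s2 at/below its sampling floor: fully shared variance,
    # estimated by the arithmetic mean (unbiased for s02 at d0 = Inf)
    d0 <- Inf
    s02 <- mean(s2)
  }
  list(d0 = d0, s02 = s02)
}

#' Moderated t and F statistics with shrunken variances
#'
#' Shrinks each probe's residual variance toward the prior,
#' `s2_tilde = (d0 * s02 + d * s2) / (d0 + d)`, and forms the moderated
#' t-statistic `beta_t / (s_tilde * sqrt(v_t))` per contrast with two-sided
#' p-values on `d + d0` degrees of freedom, plus a joint moderated F over
#' all contrasts (contrast quadratic form over `r * s2_tilde`, `r` the
#' number of contrasts) with p-values from `F(r, d + d0)`.  `d0 = 0`
#' reproduces the classical statistics; `d0 = Inf` gives the normal-theory
#' limit.  Benjamini-Hochberg adjusted F p-values are included.
#'
#' @param fit a [fit_linear_models()] result with contrasts.
#' @param prior list with `d0` and `s02` (see [estimate_variance_prior()]),
#'   or NULL to estimate it from `fit`.
#' @return object of class `"moderated_stats"`: data frame with per-contrast
#'   `t_*` and `p_*` columns, `F`, `p_F`, `p_BH`, plus attributes `d0`,
#'   `s02`, `s2_shrunk`, `df_total`.
#' @export
moderated_statistics <- function(fit, prior = NULL) {
  stopifnot(inherits(fit, "linear_fit"))
  if (is.null(fit$beta)) stop("fit has no contrasts; refit with 'contrasts ='")
  if (is.null(prior)) prior <- estimate_variance_prior(fit$sigma2, fit$df_residual)
  d0 <- prior$d0; s02 <- prior$s02
  d <- fit$df_residual
  if (d0 < 0) stop("prior df must be >= 0")
  if (d0 + d <= 0) stop("total degrees of freedom are zero")
  s2t <- if (is.infinite(d0)) rep(s02, length(fit$sigma2)) else
    (d0 * s02 + d * fit$sigma2) / (d0 + d)
  dft <- d + d0
  r <- ncol(fit$beta)
  tmat <- fit$beta / (sqrt(s2t) %o% sqrt(fit$v))
  pmat <- 2 * pt(abs(tmat), df = dft, lower.tail = FALSE)
  Vinv <- solve(fit$vcov_unscaled)
  quad <- rowSums((fit$beta %*% Vinv) * fit$beta)
  Fst <- quad / (r * s2t)
  pF <- pf(Fst, r, dft, lower.tail = FALSE)
  out <- data.frame(probe_id = rownames(fit$coefficients) %||%
                      seq_len(nrow(fit$coefficients)),
                    stringsAsFactors = FALSE, row.names = NULL)
  for (t in seq_len(r)) {
    nm <- colnames(fit$beta)[t] %||% t
    out[[paste0("t_", nm)]] <- tmat[, t]
    out[[paste0("p_", nm)]] <- pmat[, t]
  }
  out$F <- Fst
  out$p_F <- pF
  out$p_BH <- bh_adjust(pF)
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  attr(out, "s2_shrunk") <- s2t
  attr(out, "df_total") <- dft
  class(out) <- c("moderated_stats", "data.frame")
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validation wrapper over the standard step-up adjustment: sorted ascending,
#' `p~_(i) = min_{j >= i} min(1, m p_(j) / j)`, mapped back to input order.
#'
#' @param p p-values in `[0, 1]` (NA allowed, propagated).
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(!is.finite(p[ok])) || any(p[ok] < 0) || any(p[ok] > 1))
    stop("p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Moderated-F screen of sex differences within tissues
#'
#' One-call wrapper for the comparison stage: builds the tissue-by-sex
#' cell-means design and male-minus-female contrasts, fits probe-wise linear
#' models, estimates the variance prior empirically, and returns moderated
#' t/F statistics with BH-adjusted F p-values.
#'
#' @param Y probe-by-sample M-value matrix.
#' @param samples sample sheet.
#' @param prior optional `(d0, s02)` override.
#' @return a [moderated_statistics()] data frame.
#' @export
moderated_screen <- function(Y, samples, prior = NULL) {
  al <- .align_samples(as.matrix(Y), samples)
  X <- design_tissue_sex(al$samples)
  fit <- fit_linear_models(al$x, X, contrasts = sex_within_tissue_contrasts())
  moderated_statistics(fit, prior = prior)
}
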