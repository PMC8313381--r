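#' Univariate Cox proportional-hazards fit
#'
#' Fits `h(t) = h0(t) exp(b1 * x)` by maximising the Breslow partial
#' likelihood (Newton-Raphson via [survival::coxph()], tolerance 1e-9, up to
#' 50 iterations).  A constant covariate, an event-free sample, or a
#' monotone partial likelihood (perfect separation) is flagged rather than
#' silently returned.
#'
#' @param time positive event/censoring times.
#' @param event 1 = event, 0 = censored.
#' @param x numeric covariate (e.g. gene expression).
#' @return object of class `"cox_fit"`: list with `b1` (log hazard ratio),
#'   `se`, `z`, `wald_p`, `converged`, `degenerate`, `n`, `n_events`.
#' @export
cox_fit_univariate <- function(time, event, x) {
  if (length(time) != length(event) || length(time) != length(x))
    stop("'time', 'event' and 'x' lengths differ")
  if (any(!is.finite(time)) || any(time <= 0)) stop("times must be positive")
  if (!all(event %in% c(0, 1))) stop("'event' must be 0/1")
  out <- list(b1 = NA_real_, se = NA_real_, z = NA_real_, wald_p = NA_real_,
              converged = FALSE, degenerate = TRUE,
              n = length(time), n_events = sum(event))
  class(out) <- "cox_fit"
  if (sum(event) < 1L) {
    warning("no events; hazard ratio unidentifiable")
    return(out)
  }
  if (isTRUE(all.equal(var(x), 0)) || !all(is.finite(x))) {
    warning("constant (or non-finite) covariate; hazard ratio unidentifiable")
    return(out)
  }
  infinite <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ x, ties = "breslow",
                    control = survival::coxph.control(eps = 1e-9, iter.max = 50L)),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be", conditionMessage(w)))
        infinite <<- TRUE
      invokeRestart("muffleWarning")
    })
  b1 <- unname(fit$coefficients[1L])
  se <- sqrt(fit$var[1L, 1L])
  out$b1 <- b1
  out$se <- se
  out$z <- b1 / se
  out$wald_p <- 2 * pnorm(abs(b1 / se), lower.tail = FALSE)
  out$converged <- !infinite
  out$degenerate <- FALSE
  out
}

#' @export
print.cox_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("Univariate Cox fit: degenerate (unidentifiable)\n")
  } else {
    cat(sprintf(
      "Univariate Cox fit: b1 = %.4f (se %.4f), HR = %.3f, Wald p = %.3g%s\n",
      x$b1, x$se, exp(x$b1), x$wald_p,
      if (!x$converged) "  [non-converged: monotone likelihood]" else ""))
  }
  cat(sprintf("  n = %d, events = %d\n", x$n, x$n_events))
  invisible(x)
}

#' Screen genes by univariate Cox models
#'
#' Fits one univariate Cox model per gene on continuous expression, adjusts
#' the Wald p-values with Benjamini-Hochberg across genes, and reports the
#' direction of the expression-survival association: `"+"` means higher
#' expression is associated with *longer* survival (negative log hazard
#' ratio), `"-"` the reverse.
#'
#' @param expr gene-by-subject expression matrix.
#' @param time,event per-subject survival outcome, aligned with the columns
#'   of `expr` (matched by name when both are named).
#' @return data frame: `gene`, `b1`, `se`, `p`, `p_BH`, `sign`, `converged`.
#' @export
screen_genes <- function(expr, time, event) {
  expr <- as.matrix(expr)
  if (!is.null(colnames(expr)) && !is.null(names(time))) {
    if (!setequal(colnames(expr), names(time)))
      stop("subjects in 'expr' and 'time' do not match")
    expr <- expr[, names(time), drop = FALSE]
  }
  if (ncol(expr) != length(time) || length(time) != length(event))
    stop("subjects misaligned between expression matrix and survival outcome")
  g <- nrow(expr)
  b1 <- se <- p <- rep(NA_real_, g)
  conv <- logical(g)
  for (i in seq_len(g)) {
    f <- suppressWarnings(cox_fit_univariate(time, event, expr[i, ]))
    if (!f$degenerate) {
      b1[i] <- f$b1; se[i] <- f$se; p[i] <- f$wald_p; conv[i] <- f$converged
    }
  }
  data.frame(gene = rownames(expr) %||% seq_len(g),
             b1 = b1, se = se, p = p, p_BH = bh_adjust(p),
             sign = ifelse(is.na(b1), NA_character_, ifelse(b1 < 0, "+", "-")),
             converged = conv, stringsAsFactors = FALSE, row.names = NULL)
}

#' Split subjects by an expression threshold
#'
#' @param expr numeric vector of expression values.
#' @param threshold finite cut point; values `<= threshold` are `low`, the
#'   rest `high`.
#' @return factor with levels `low`, `high`; warns when one group is empty.
#' @export
dichotomize <- function(expr, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L || !is.finite(threshold))
    stop("'threshold' must be a single finite number")
  g <- factor(ifelse(expr <= threshold, "low", "high"), levels = c("low", "high"))
  if (any(table(g) == 0L))
    warning("all subjects fall on one side of the threshold")
  g
}

#' Kaplan-Meier product-limit curves per group
#'
#' @param time,event survival outcome.
#' @param group group labels (one curve per group; every group must be
#'   non-empty).
#' @return data frame of class `"km_curves"`: `group`, `time`, `n_risk`,
#'   `n_event`, `survival` (rows only at observed event/censoring times).
#' @export
km_estimate <- function(time, event, group) {
  if (length(time) != length(event) || length(time) != length(group))
    stop("input lengths differ")
  group <- as.factor(group)
  if (any(table(group) == 0L) || nlevels(droplevels(group)) < nlevels(group))
    stop("every group must contain at least one record")
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  grp <- if (is.null(fit$strata)) rep(levels(group)[1L], length(fit$time)) else
    rep(sub("^group=", "", names(fit$strata)), fit$strata)
  out <- data.frame(group = grp, time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, survival = fit$surv,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("km_curves", "data.frame")
  out
}
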