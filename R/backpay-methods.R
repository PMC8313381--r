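#' @export
print.backpay <- function(x, ...) {
  cfg <- x$config
  sel <- select_differential(x)
  cat("Sign-constrained Bayesian trajectory-pattern mixture\n")
  cat(sprintf("  probes: %d   samples: %d (male %d / female %d)\n",
              nrow(x$table), nrow(x$samples),
              sum(x$samples$stratum == 1L), sum(x$samples$stratum == 2L)))
  cat(sprintf("  sweeps: %d (burn-in %d)   seed: %d\n",
              cfg$n_iter, cfg$burn_in, cfg$seed))
  cat(sprintf("  differential probes (q < %g, pma > %g): %d\n",
              cfg$q_cut, cfg$pb, nrow(sel)))
  invisible(x)
}

#' @export
summary.backpay <- function(object, ...) {
  sel <- select_differential(object)
  patt <- if (nrow(sel)) sort(table(sel$pattern), decreasing = TRUE) else table(character(0))
  out <- list(n_probes = nrow(object$table),
              n_selected = nrow(sel),
              q_cut = object$config$q_cut, pb = object$config$pb,
              pattern_counts = patt,
              discordant_selected = if (nrow(sel)) sum(is_discordant_pattern(sel$pattern)) else 0L,
              null_prob_quartiles = stats::quantile(object$table$p0, c(0.25, 0.5, 0.75)),
              sign_constraints_held = object$sign_constraints_held)
  class(out) <- "summary.backpay"
  out
}

#' @export
print.summary.backpay <- function(x, ...) {
  cat(sprintf("%d of %d probes differential at q < %g, pma > %g (%d sex-discordant)\n",
              x$n_selected, x$n_probes, x$q_cut, x$pb, x$discordant_selected))
  cat("null-probability quartiles:",
      paste(sprintf("%.3f", x$null_prob_quartiles), collapse = " / "), "\n")
  if (length(x$pattern_counts)) {
    cat("selected patterns:\n")
    print(x$pattern_counts)
  }
  invisible(x)
}

#' Posterior-mean cluster slopes
#'
#' @param object a fitted [backpay()] model.
#' @param ... unused.
#' @return a 2 x 9 x 2 array (stratum x cluster x slope) of posterior-mean
#'   slopes, averaged over the cluster's member probes; Flat coordinates are
#'   exactly zero.
#' @export
coef.backpay <- function(object, ...) object$beta_mean

#' @export
fitted.backpay <- function(object, ...) {
  enc <- object$samples
  fit <- object$data * 0
  for (ci in seq_len(nrow(enc))) {
    s <- enc$stratum[ci]
    fit[, ci] <- object$a_mean[, s] +
      object$beta_probe_mean[, s, 1L] * enc$x1[ci] +
      object$beta_probe_mean[, s, 2L] * enc$x2[ci]
  }
  fit
}

#' @export
residuals.backpay <- function(object, ...) object$data - fitted(object)

#' Plot posterior trajectory patterns
#'
#' Draws the tissue-group means (ATM, CAM, NTM) of the selected probes, one
#' panel per stratum, coloured by assigned pattern.
#'
#' @param x a fitted [backpay()] model.
#' @param max_probes cap on probes drawn (default 50).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.backpay <- function(x, max_probes = 50L, ...) {
  sel <- select_differential(x)
  if (nrow(sel) == 0L) {
    warning("no differential probes to plot")
    return(invisible(NULL))
  }
  sel <- head(sel, max_probes)
  traj <- export_pattern_trajectories(sel, x$data, x$samples)
  patt <- unique(sel$pattern)
  cols <- setNames(hcl.colors(max(3L, length(patt)), "Dark 3")[seq_along(patt)], patt)
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  for (s in c("male", "female")) {
    sub <- traj[traj$stratum == s, ]
    m <- matrix(sub$mean_mvalue, nrow = 3L,
                dimnames = list(c("ATM", "CAM", "NTM"), NULL))
    pat_of <- sub$pattern[seq(1L, nrow(sub), by = 3L)]
    matplot(1:3, m, type = "l", lty = 1, col = cols[pat_of],
            xaxt = "n", xlab = "tissue", ylab = "M-value", main = s, ...)
    axis(1, at = 1:3, labels = c("ATM", "CAM", "NTM"))
  }
  invisible(traj)
}
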