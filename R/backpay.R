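#' Encode tissue groups as regression indicators
#'
#' CAM is the reference tissue: each sample is encoded as
#' `x1 = 1` if ATM, `x2 = 1` if NTM, and `(0, 0)` for CAM.  Strata are the
#' two sexes (male = stratum 1, female = stratum 2).
#'
#' @param samples data frame with columns `sample_id`, `tissue`
#'   (ATM/CAM/NTM) and `sex` (male/female).
#' @return data frame with columns `sample_id`, `tissue`, `sex`, `stratum`,
#'   `x1`, `x2`.
#' @export
encode_design <- function(samples) {
  need <- c("sample_id", "tissue", "sex")
  if (!all(need %in% names(samples)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  tissue <- as.character(samples$tissue)
  sex <- as.character(samples$sex)
  bad <- !tissue %in% c("ATM", "CAM", "NTM")
  if (any(bad))
    stop("unknown tissue label for sample(s): ",
         paste(samples$sample_id[bad], collapse = ", "))
  bad <- !sex %in% c("male", "female")
  if (any(bad))
    stop("unknown sex label for sample(s): ",
         paste(samples$sample_id[bad], collapse = ", "))
  data.frame(sample_id = as.character(samples$sample_id),
             tissue = tissue, sex = sex,
             stratum = match(sex, c("male", "female")),
             x1 = as.integer(tissue == "ATM"),
             x2 = as.integer(tissue == "NTM"),
             stringsAsFactors = FALSE)
}

#' Gaussian log-likelihood of one stratum under one trajectory cluster
#'
#' The mixture's component likelihood: observations `y_i` are Gaussian with
#' mean `a + x1_i * beta1 + x2_i * beta2` and variance `sigma2`.  Exposed so
#' the sampler's membership computations can be checked against an
#' independent normal-density oracle.
#'
#' @param y numeric vector of M-values for one probe in one stratum.
#' @param x1,x2 ATM / NTM indicator vectors (same length as `y`).
#' @param a intercept.
#' @param beta1,beta2 cluster slopes (0 for Flat coordinates).
#' @param sigma2 positive noise variance.
#' @return the log-likelihood (a scalar).
#' @export
log_component_likelihood <- function(y, x1, x2, a, beta1, beta2, sigma2) {
  if (!is.numeric(sigma2) || length(sigma2) != 1L || !is.finite(sigma2) || sigma2 <= 0)
    stop("'sigma2' must be a single positive number")
  if (any(!is.finite(c(y, x1, x2, a, beta1, beta2)))) stop("non-finite inputs")
  mu <- a + x1 * beta1 + x2 * beta2
  sum(dnorm(y, mu, sqrt(sigma2), log = TRUE))
}

#' Empirical pattern probabilities from retained membership draws
#'
#' @param z_male,z_female integer matrices (retained draws x probes) of
#'   per-stratum cluster memberships in 1..9.
#' @return list with `prob` (probes x 81 matrix, columns named by
#'   [pattern_labels()], rows summing to 1), `p0` (null-pattern
#'   probability), `pma` (per-probe maximum pattern probability), and
#'   `modal` (the argmax pattern label; ties broken by lowest pattern index).
#' @export
pattern_probabilities <- function(z_male, z_female) {
  z_male <- as.matrix(z_male); z_female <- as.matrix(z_female)
  if (nrow(z_male) == 0L) stop("zero retained draws")
  if (!identical(dim(z_male), dim(z_female)))
    stop("'z_male' and 'z_female' dimensions differ")
  if (!all(z_male %in% 1:9) || !all(z_female %in% 1:9))
    stop("memberships must be integers in 1..9")
  p <- ncol(z_male)
  R <- nrow(z_male)
  counts <- matrix(0L, p, 81L, dimnames = list(colnames(z_male), pattern_labels()))
  for (r in seq_len(R)) {
    idx <- (z_male[r, ] - 1L) * 9L + z_female[r, ]
    ii <- cbind(seq_len(p), idx)
    counts[ii] <- counts[ii] + 1L
  }
  prob <- counts / R
  modal_idx <- max.col(prob, ties.method = "first")
  list(prob = prob,
       p0 = unname(prob[, null_pattern()]),
       pma = prob[cbind(seq_len(p), modal_idx)],
       modal = pattern_labels()[modal_idx])
}

#' Bayesian q-values from posterior null probabilities
#'
#' The q-value at a probe is the estimated Bayesian false discovery rate
#' incurred by calling every probe whose posterior null-pattern probability
#' is at most that probe's: sort the null probabilities ascending and take
#' cumulative means; tied values share the cumulative mean at the last tied
#' rank.
#'
#' @param p0 numeric vector of posterior null probabilities in `[0, 1]`.
#' @return q-values in `[0, 1]`, in the input order.
#' @examples
#' bayesian_qvalues(c(0.01, 0.2, 0.6))  # 0.01, 0.105, 0.27
#' @export
bayesian_qvalues <- function(p0) {
  if (length(p0) == 0L) return(numeric(0))
  if (any(!is.finite(p0)) || any(p0 < 0) || any(p0 > 1))
    stop("null probabilities must be finite and in [0, 1]")
  ord <- order(p0)
  cm <- cumsum(p0[ord]) / seq_along(p0)
  cm[rank(p0, ties.method = "max")]
}

.stratum_data <- function(y, enc, s) {
  cols <- which(enc$stratum == s)
  tissue <- enc$tissue[cols]
  list(Y = y[, cols, drop = FALSE],
       idxA = which(tissue == "ATM"),
       idxN = which(tissue == "NTM"),
       idxC = which(tissue == "CAM"),
       nA = sum(tissue == "ATM"),
       nN = sum(tissue == "NTM"),
       n = length(cols))
}

# Data-driven initial memberships: slope signs that clear 3 standard errors.
# Per-probe variances carry only ~2 df here, so they are shrunk toward the
# across-probe median before thresholding; a noisy tiny variance would
# otherwise hand null probes spurious signs, seeding pseudo-flat sign
# clusters (an established cluster with a near-zero slope is a metastable
# trap for the sampler, so the initialisation errs toward FlatFlat — strong
# effects escape it in a handful of sweeps, null probes would not escape
# the trap).
.init_memberships <- function(sd1, enc) {
  p <- nrow(sd1$Y)
  mA <- if (sd1$nA) rowMeans(sd1$Y[, sd1$idxA, drop = FALSE]) else numeric(p)
  mN <- if (sd1$nN) rowMeans(sd1$Y[, sd1$idxN, drop = FALSE]) else numeric(p)
  mC <- rowMeans(sd1$Y[, sd1$idxC, drop = FALSE])
  # pooled within-tissue variance inside the stratum (floored)
  ss <- 0; df <- 0L
  for (idx in list(sd1$idxA, sd1$idxN, sd1$idxC)) {
    if (length(idx) > 1L) {
      sub <- sd1$Y[, idx, drop = FALSE]
      ss <- ss + rowSums((sub - rowMeans(sub))^2)
      df <- df + length(idx) - 1L
    }
  }
  s2 <- if (df > 0L) pmax(ss / df, 1e-4) else pmax(apply(sd1$Y, 1L, var), 1e-4)
  s2 <- (df * s2 + 4 * median(s2)) / (df + 4)
  g1 <- if (sd1$nA) sign(mA - mC) * (abs(mA - mC) >
          3 * sqrt(s2 * (1 / sd1$nA + 1 / length(sd1$idxC)))) else 0
  g2 <- if (sd1$nN) sign(mN - mC) * (abs(mN - mC) >
          3 * sqrt(s2 * (1 / sd1$nN + 1 / length(sd1$idxC)))) else 0
  sg <- cluster_signs()
  match(paste(g1, g2), paste(sg[, 1L], sg[, 2L]))
}

#' Fit the sign-constrained Bayesian mixture of trajectory patterns
#'
#' Clusters each probe, separately within the male and female strata, into
#' one of nine trajectory clusters defined by the signs of the two tissue
#' slopes (ATM and NTM indicators, CAM reference); the cross-stratum pair of
#' clusters is the probe's *pattern*.  Within a stratum, cluster `h` models
#' a member probe's M-values as
#' `y = a_j + x1 * b_j1 + x2 * b_j2 + e`, `e ~ N(0, sigma2_h)`, where the
#' probe's slope `b_jk` is constrained to the cluster's sign — a point mass
#' at zero for Flat coordinates, otherwise a half-normal whose precision
#' `tau_sh` is shared across the cluster's members (the cluster couples its
#' probes through the slope scale and the noise level while each probe
#' keeps its own effect magnitude) — and `a_j` is a probe-specific
#' intercept.
#'
#' Inference is by a partially-collapsed Gibbs sampler: memberships are
#' drawn with each probe's constrained slope integrated out analytically
#' (closed form, so joining a sign cluster always costs a probe its own
#' Occam factor), after which slopes, intercepts, precisions, noise
#' variances and mixture weights are drawn from their full conditionals.
#' Clusters are identified by their fixed sign constraints, so no
#' relabelling is ever needed.
#'
#' Priors: `tau_sh ~ Gamma(a_tau, b_tau)` (default mean 7/5 = 1.4),
#' `sigma2_h ~ Inv-Gamma(2, 1)`, intercepts `a_j ~ N(probe stratum mean,
#' v_a)`, mixture weights Dirichlet(1, ..., 1) per stratum.
#'
#' @param y probe-by-sample matrix of M-values (finite; rownames are probe
#'   IDs).
#' @param samples sample sheet with `sample_id`, `tissue`, `sex`; both sexes
#'   and all three tissues must be present.
#' @param n_iter total Gibbs sweeps (default 30000).
#' @param burn_in sweeps discarded (default 10000; must be `< n_iter`).
#' @param pb posterior-probability threshold used by
#'   [select_differential()] (default 0.5).
#' @param q_cut Bayesian q-value threshold for selection (default 0.05).
#' @param a_tau,b_tau shape and rate of the Gamma prior on the slope
#'   precisions (defaults 7 and 5).
#' @param v_a prior variance of the probe intercepts (default 10, M-value
#'   scale).
#' @param sigma_prior length-2 `c(shape, rate)` of the inverse-gamma prior
#'   on the cluster noise variances (default `c(2, 1)`).
#' @param seed integer seed; identical data + arguments + seed give
#'   bit-identical results.
#' @param keep_draws keep the retained membership draws (needed by
#'   [pattern_probabilities()] re-computation and diagnostics; default TRUE).
#' @param verbose print progress.
#' @return an object of class `"backpay"`: a list with the per-probe
#'   posterior `table` (probe_id, pattern, pma, p0, qvalue), the full
#'   probes-by-81 `pattern_prob` matrix, posterior-mean parameter summaries
#'   (`beta_mean` — member-averaged slopes per stratum and cluster,
#'   `beta_probe_mean`, `tau_mean`, `sigma2_mean`, `a_mean`), the
#'   retained draws (`draws$z_male`, `draws$z_female` when `keep_draws`),
#'   and the run configuration.  Methods: `print`, `summary`, `coef`,
#'   `fitted`, `residuals`, `plot`.
#' @seealso [select_differential()], [pattern_probabilities()],
#'   [bayesian_qvalues()]
#' @export
backpay <- function(y, samples, n_iter = 30000L, burn_in = 10000L,
                    pb = 0.5, q_cut = 0.05, a_tau = 7, b_tau = 5,
                    v_a = 10, sigma_prior = c(2, 1), seed = 1L,
                    keep_draws = TRUE, verbose = FALSE) {
  cl <- match.call()
  if (!is.matrix(y)) y <- as.matrix(y)
  if (any(!is.finite(y))) stop("'y' must be finite (drop missing probes first)")
  al <- .align_samples(y, samples)
  y <- al$x
  enc <- encode_design(al$samples)
  if (!all(1:2 %in% enc$stratum))
    stop("both strata (male and female) must contain at least one sample")
  n_iter <- as.integer(n_iter); burn_in <- as.integer(burn_in)
  if (!(burn_in >= 0L && burn_in < n_iter)) stop("need 0 <= burn_in < n_iter")
  if (!(pb > 0 && pb < 1)) stop("'pb' must be in (0, 1)")
  stopifnot(a_tau > 0, b_tau > 0, v_a > 0, length(sigma_prior) == 2L,
            all(sigma_prior > 0))
  p <- nrow(y)
  if (p < 1L) stop("'y' has no probes")
  probe_ids <- rownames(y) %||% paste0("probe_", seq_len(p))
  rownames(y) <- probe_ids

  set.seed(as.integer(seed))
  sg <- cluster_signs()
  nz1 <- which(sg[, 1L] != 0L); s1v <- sg[nz1, 1L]
  nz2 <- which(sg[, 2L] != 0L); s2v <- sg[nz2, 2L]
  m_h <- (sg[, 1L] != 0L) + (sg[, 2L] != 0L)
  a0 <- sigma_prior[1L]; b0 <- sigma_prior[2L]

  sd_s <- list(.stratum_data(y, enc, 1L), .stratum_data(y, enc, 2L))
  sumy <- lapply(sd_s, function(d) rowSums(d$Y))
  ybar <- lapply(seq_along(sd_s), function(s) sumy[[s]] / sd_s[[s]]$n)

  # --- state ---
  z <- cbind(.init_memberships(sd_s[[1L]], enc), .init_memberships(sd_s[[2L]], enc))
  a <- cbind(ybar[[1L]], ybar[[2L]])
  tau <- matrix(a_tau / b_tau, 2L, 9L)
  sigma2 <- rep(mean(apply(y, 1L, var)) / 2 + 0.05, 9L)
  bpro <- array(0, c(p, 2L, 2L))      # probe-level slopes (0 on Flat coords)

  n_keep <- n_iter - burn_in
  counts81 <- matrix(0L, p, 81L, dimnames = list(probe_ids, pattern_labels()))
  if (keep_draws) {
    zdraw <- list(male = matrix(0L, n_keep, p, dimnames = list(NULL, probe_ids)),
                  female = matrix(0L, n_keep, p, dimnames = list(NULL, probe_ids)))
  }
  beta_sum <- array(0, c(2L, 9L, 2L)); occ <- matrix(0, 2L, 9L)
  tau_sum <- matrix(0, 2L, 9L)
  sigma2_sum <- numeric(9L); a_sum <- a * 0; bpro_sum <- bpro * 0
  sign_ok <- TRUE
  log2c <- log(2)

  for (it in seq_len(n_iter)) {
    for (s in 1:2) {
      d <- sd_s[[s]]
      zs <- z[, s]
      Mv <- tabulate(zs, 9L)
      lpi <- log(.rdirichlet1(1 + Mv))
      # per-sweep probe statistics at the current intercepts
      Yc <- d$Y - a[, s]
      S1 <- if (d$nA) rowSums(Yc[, d$idxA, drop = FALSE]) else numeric(p)
      S2 <- if (d$nN) rowSums(Yc[, d$idxN, drop = FALSE]) else numeric(p)
      TSS <- rowSums(Yc^2)
      invs2 <- 1 / sigma2
      taus <- tau[s, ]
      # Memberships: categorical from the per-probe marginal likelihood with
      # the probe's slope integrated out against its sign-constrained
      # half-normal prior (closed form).  Because slopes are probe-level,
      # the marginal factorises over probes and every probe pays its own
      # Occam factor for a non-Flat coordinate — a null probe's small
      # group-mean fluctuation never pools with other probes' into shared
      # pseudo-evidence for a sign cluster.
      lp <- matrix(lpi - (d$n / 2) * log(2 * pi * sigma2), p, 9L, byrow = TRUE)
      lp <- lp - TSS %o% (0.5 * invs2)
      if (d$nA) for (h in nz1) {
        P <- taus[h] + d$nA * invs2[h]
        B <- S1 * invs2[h]
        lp[, h] <- lp[, h] + 0.5 * (log(taus[h]) - log(P)) + log2c +
          B^2 / (2 * P) + pnorm(sg[h, 1L] * B / sqrt(P), log.p = TRUE)
      }
      if (d$nN) for (h in nz2) {
        P <- taus[h] + d$nN * invs2[h]
        B <- S2 * invs2[h]
        lp[, h] <- lp[, h] + 0.5 * (log(taus[h]) - log(P)) + log2c +
          B^2 / (2 * P) + pnorm(sg[h, 2L] * B / sqrt(P), log.p = TRUE)
      }
      # Gumbel-max categorical draw per probe
      g <- -log(-log(matrix(runif(p * 9L), p, 9L)))
      zs <- max.col(lp + g, ties.method = "first")
      z[, s] <- zs
      # probe-level slopes: truncated-normal full conditionals given the
      # assigned cluster's sign and precision; exact zero on Flat coordinates
      b1 <- numeric(p); b2 <- numeric(p)
      sgn1 <- sg[zs, 1L]; sgn2 <- sg[zs, 2L]
      if (d$nA) {
        jj <- sgn1 != 0L
        if (any(jj)) {
          P <- taus[zs[jj]] + d$nA * invs2[zs[jj]]
          Q <- S1[jj] * invs2[zs[jj]]
          b1[jj] <- .rtrunc_signed(Q / P, 1 / sqrt(P), sgn1[jj])
        }
      }
      if (d$nN) {
        jj <- sgn2 != 0L
        if (any(jj)) {
          P <- taus[zs[jj]] + d$nN * invs2[zs[jj]]
          Q <- S2[jj] * invs2[zs[jj]]
          b2[jj] <- .rtrunc_signed(Q / P, 1 / sqrt(P), sgn2[jj])
        }
      }
      bpro[, s, 1L] <- b1; bpro[, s, 2L] <- b2
      # intercepts
      adj <- d$nA * b1 + d$nN * b2
      prec <- d$n * invs2[zs] + 1 / v_a
      mu <- ((sumy[[s]] - adj) * invs2[zs] + ybar[[s]] / v_a) / prec
      a[, s] <- rnorm(p, mu, 1 / sqrt(prec))
    }
    # slope precisions: tau_sh pools the squared slopes of member probes
    for (s in 1:2) {
      b2sum <- bpro[, s, 1L]^2 + bpro[, s, 2L]^2
      for (h in 1:9) {
        mem <- z[, s] == h
        tau[s, h] <- rgamma(1L, shape = a_tau + m_h[h] * sum(mem) / 2,
                            rate = b_tau + sum(b2sum[mem]) / 2)
      }
    }
    # cluster noise variances, pooled over strata
    SSh <- numeric(9L); Nh <- numeric(9L)
    for (s in 1:2) {
      d <- sd_s[[s]]
      E <- d$Y - a[, s]
      if (d$nA) E[, d$idxA] <- E[, d$idxA, drop = FALSE] - bpro[, s, 1L]
      if (d$nN) E[, d$idxN] <- E[, d$idxN, drop = FALSE] - bpro[, s, 2L]
      rss <- rowSums(E^2)
      for (h in 1:9) {
        mem <- z[, s] == h
        SSh[h] <- SSh[h] + sum(rss[mem])
        Nh[h] <- Nh[h] + sum(mem) * d$n
      }
    }
    sigma2 <- 1 / rgamma(9L, shape = a0 + Nh / 2, rate = b0 + SSh / 2)

    if (it > burn_in) {
      r <- it - burn_in
      idx <- cbind(seq_len(p), (z[, 1L] - 1L) * 9L + z[, 2L])
      counts81[idx] <- counts81[idx] + 1L
      if (keep_draws) {
        zdraw$male[r, ] <- z[, 1L]
        zdraw$female[r, ] <- z[, 2L]
      }
      for (s in 1:2) for (h in 1:9) {
        mem <- z[, s] == h
        if (any(mem)) {
          occ[s, h] <- occ[s, h] + 1
          beta_sum[s, h, 1L] <- beta_sum[s, h, 1L] + mean(bpro[mem, s, 1L])
          beta_sum[s, h, 2L] <- beta_sum[s, h, 2L] + mean(bpro[mem, s, 2L])
        }
      }
      tau_sum <- tau_sum + tau
      sigma2_sum <- sigma2_sum + sigma2; a_sum <- a_sum + a
      bpro_sum <- bpro_sum + bpro
      sign_ok <- sign_ok &&
        all(sign(bpro[, , 1L]) == sg[z, 1L] | bpro[, , 1L] == 0) &&
        all(sign(bpro[, , 2L]) == sg[z, 2L] | bpro[, , 2L] == 0)
    }
    if (verbose && it %% max(1L, n_iter %/% 10L) == 0L)
      message("sweep ", it, "/", n_iter)
  }

  prob <- counts81 / n_keep
  modal_idx <- max.col(prob, ties.method = "first")
  p0 <- unname(prob[, null_pattern()])
  qv <- bayesian_qvalues(p0)
  tab <- data.frame(probe_id = probe_ids,
                    pattern = pattern_labels()[modal_idx],
                    pma = prob[cbind(seq_len(p), modal_idx)],
                    p0 = p0, qvalue = qv,
                    stringsAsFactors = FALSE, row.names = NULL)
  beta_mean <- beta_sum / array(pmax(occ, 1), c(2L, 9L, 2L))
  dimnames(beta_mean) <- list(c("male", "female"), cluster_labels(), c("b1", "b2"))
  dimnames(bpro_sum) <- list(probe_ids, c("male", "female"), c("b1", "b2"))
  out <- list(call = cl,
              table = tab,
              pattern_prob = prob,
              beta_mean = beta_mean,
              beta_probe_mean = bpro_sum / n_keep,
              tau_mean = tau_sum / n_keep,
              sigma2_mean = sigma2_sum / n_keep,
              a_mean = a_sum / n_keep,
              draws = if (keep_draws) zdraw,
              samples = enc,
              data = y,
              sign_constraints_held = sign_ok,
              config = list(n_iter = n_iter, burn_in = burn_in, pb = pb,
                            q_cut = q_cut, a_tau = a_tau, b_tau = b_tau,
                            v_a = v_a, sigma_prior = sigma_prior,
                            seed = as.integer(seed), H = 9L))
  class(out) <- "backpay"
  out
}

#' Select differential probes from a fitted pattern mixture
#'
#' A probe is called differential when its Bayesian q-value is below
#' `q_cut`, its modal pattern is not the null `FlatFlat-FlatFlat` pattern,
#' and the modal pattern's posterior probability exceeds `pb`.
#'
#' @param object a fitted [backpay()] model, or a posterior table with
#'   columns `probe_id`, `pattern`, `pma`, `p0`, `qvalue`.
#' @param pb posterior-probability threshold (default: the fit's setting,
#'   0.5).
#' @param q_cut q-value threshold (default: the fit's setting, 0.05).
#' @return data frame of selected probes: `probe_id`, `pattern`,
#'   `probability`, `q_value`.
#' @export
select_differential <- function(object, pb = NULL, q_cut = NULL) {
  if (inherits(object, "backpay")) {
    pb <- pb %||% object$config$pb
    q_cut <- q_cut %||% object$config$q_cut
    tab <- object$table
  } else {
    pb <- pb %||% 0.5
    q_cut <- q_cut %||% 0.05
    tab <- as.data.frame(object)
    stopifnot(all(c("probe_id", "pattern", "pma", "qvalue") %in% names(tab)))
  }
  sel <- tab$qvalue < q_cut & tab$pattern != null_pattern() & tab$pma > pb
  data.frame(probe_id = tab$probe_id[sel],
             pattern = tab$pattern[sel],
             probability = tab$pma[sel],
             q_value = tab$qvalue[sel],
             stringsAsFactors = FALSE, row.names = NULL)
}
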