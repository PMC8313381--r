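#' Default 9-sample study layout
#'
#' Three tissue types with three samples each and mixed sexes per tissue
#' (two of one sex and one of the other), the design the methylation
#' simulator emulates.
#'
#' @return sample sheet data frame (`sample_id`, `tissue`, `sex`).
#' @export
default_sample_layout <- function() {
  data.frame(
    sample_id = paste0("S", 1:9),
    tissue = rep(c("ATM", "CAM", "NTM"), each = 3L),
    sex = c("male", "male", "female",
            "male", "female", "female",
            "male", "male", "female"),
    stringsAsFactors = FALSE)
}

#' Default pattern frequencies for simulated studies
#'
#' Probability mass on the null pattern plus the eight sex-discordant
#' catalog patterns.
#'
#' @param null_mass mass on `FlatFlat-FlatFlat` (default 0.6); the
#'   remainder is spread evenly over [differential_pattern_catalog()].
#' @return named 81-vector over [pattern_labels()] summing to 1.
#' @export
default_pattern_frequencies <- function(null_mass = 0.6) {
  stopifnot(null_mass >= 0, null_mass <= 1)
  f <- setNames(numeric(81L), pattern_labels())
  f[null_pattern()] <- null_mass
  f[differential_pattern_catalog()] <- (1 - null_mass) / 8
  f
}

#' Simulation configuration
#'
#' Bundles the knobs of the methylation and survival generators.  Defaults
#' describe the emulated study: 9 samples (3 per tissue, mixed sexes),
#' slope magnitudes of about 2 M-value units, within-cluster noise SD 0.3,
#' and a 238-subject survival cohort.
#'
#' @param n_probes number of probes (default 200).
#' @param samples sample sheet (default [default_sample_layout()]).
#' @param pattern_frequencies named 81-vector summing to 1 (default
#'   [default_pattern_frequencies()]).
#' @param effect_size base slope magnitude for non-Flat coordinates
#'   (default 2, M-value units; must be > 0).
#' @param effect_jitter magnitudes are `effect_size + Uniform(0, jitter)`
#'   (default 0.5).
#' @param intercept_mean,intercept_sd probe intercept distribution
#'   (defaults 0 and 1).
#' @param noise_sd residual SD (default 0.3; scalar or per-probe).
#' @param n_subjects survival cohort size (default 238).
#' @param n_genes genes in the survival/expression generator (default 181).
#' @param b1 per-gene log hazard ratios (default all 0; recycled/named).
#' @param baseline_rate exponential baseline hazard (default 0.1).
#' @param censoring_rate target censoring fraction in `[0, 1)` (default 0.2).
#' @param seed integer seed.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(n_probes = 200L,
                       samples = default_sample_layout(),
                       pattern_frequencies = default_pattern_frequencies(),
                       effect_size = 2, effect_jitter = 0.5,
                       intercept_mean = 0, intercept_sd = 1,
                       noise_sd = 0.3,
                       n_subjects = 238L, n_genes = 181L, b1 = 0,
                       baseline_rate = 0.1, censoring_rate = 0.2,
                       seed = 1L) {
  if (n_probes < 1L) stop("'n_probes' must be >= 1")
  if (effect_size <= 0) stop("'effect_size' must be > 0")
  if (effect_jitter < 0) stop("'effect_jitter' must be >= 0")
  if (!(censoring_rate >= 0 && censoring_rate < 1))
    stop("'censoring_rate' must be in [0, 1)")
  pf <- pattern_frequencies
  if (is.null(names(pf)) || !all(names(pf) %in% pattern_labels()))
    stop("'pattern_frequencies' must be named by pattern labels")
  full <- setNames(numeric(81L), pattern_labels())
  full[names(pf)] <- pf
  if (any(full < 0) || abs(sum(full) - 1) > 1e-8)
    stop("'pattern_frequencies' must be nonnegative and sum to 1")
  out <- list(n_probes = as.integer(n_probes), samples = samples,
              pattern_frequencies = full,
              effect_size = effect_size, effect_jitter = effect_jitter,
              intercept_mean = intercept_mean, intercept_sd = intercept_sd,
              noise_sd = noise_sd,
              n_subjects = as.integer(n_subjects),
              n_genes = as.integer(n_genes), b1 = b1,
              baseline_rate = baseline_rate, censoring_rate = censoring_rate,
              seed = as.integer(seed))
  class(out) <- "sim_config"
  out
}

#' Simulate a methylation study with known pattern ground truth
#'
#' Runs the trajectory mixture forward: each probe draws a pattern (a male
#' and a female cluster), each stratum draws slope magnitudes
#' `effect_size + Uniform(0, jitter)` with signs dictated by the cluster
#' (exactly 0 for Flat coordinates), and observations are the trajectory
#' means plus Gaussian noise.  Beta-values are derived from the M-values by
#' the inverse-logit transform.
#'
#' @param config a [sim_config()].
#' @return list of class `"simulated_study"`: `M` (probes x samples),
#'   `beta`, `samples`, and `truth` (probe_id, pattern, male/female
#'   clusters, intercept, the four slopes, sigma).
#' @export
simulate_methylation <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  samples <- validate_sample_sheet(config$samples)
  enc <- encode_design(samples)
  p <- config$n_probes
  sgn <- cluster_signs()
  pat_idx <- sample.int(81L, p, replace = TRUE, prob = config$pattern_frequencies)
  male_cl <- (pat_idx - 1L) %/% 9L + 1L
  female_cl <- (pat_idx - 1L) %% 9L + 1L
  a <- rnorm(p, config$intercept_mean, config$intercept_sd)
  sigma <- rep_len(config$noise_sd, p)
  draw_slopes <- function(cl) {
    mag1 <- config$effect_size + runif(p, 0, config$effect_jitter)
    mag2 <- config$effect_size + runif(p, 0, config$effect_jitter)
    cbind(b1 = sgn[cl, 1L] * mag1, b2 = sgn[cl, 2L] * mag2)
  }
  bm <- draw_slopes(male_cl)
  bf <- draw_slopes(female_cl)
  M <- matrix(0, p, nrow(samples),
              dimnames = list(sprintf("cg%08d", seq_len(p)), samples$sample_id))
  for (i in seq_len(nrow(enc))) {
    b <- if (enc$stratum[i] == 1L) bm else bf
    mu <- a + b[, 1L] * enc$x1[i] + b[, 2L] * enc$x2[i]
    M[, i] <- mu + rnorm(p, 0, sigma)
  }
  truth <- data.frame(probe_id = rownames(M),
                      pattern = pattern_labels()[pat_idx],
                      male_cluster = cluster_labels()[male_cl],
                      female_cluster = cluster_labels()[female_cl],
                      a = a,
                      beta_m1 = bm[, 1L], beta_m2 = bm[, 2L],
                      beta_f1 = bf[, 1L], beta_f2 = bf[, 2L],
                      sigma = sigma, stringsAsFactors = FALSE, row.names = NULL)
  out <- list(M = M, beta = beta_from_m(M), samples = samples, truth = truth,
              config = config)
  class(out) <- "simulated_study"
  out
}

#' Simulate survival outcomes driven by gene expression
#'
#' Expression is standard normal per gene and subject; event times are
#' exponential with hazard `baseline_rate * exp(sum_g b1_g * x_g)`;
#' censoring is independent Uniform(0, u) with `u` calibrated numerically so
#' the expected censoring fraction matches the target.
#'
#' @param config a [sim_config()] (uses `n_subjects`, `n_genes`, `b1`,
#'   `baseline_rate`, `censoring_rate`, `seed`).
#' @return list with `expr` (genes x subjects), `survival` data frame
#'   (`subject_id`, `time`, `event`) and `b1` (true per-gene log hazard
#'   ratios).
#' @export
simulate_survival <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- config$n_subjects
  g <- config$n_genes
  b1 <- rep_len(config$b1, g)
  genes <- if (!is.null(names(config$b1)) && length(config$b1) == g)
    names(config$b1) else sprintf("gene_%03d", seq_len(g))
  expr <- matrix(rnorm(g * n), g, n,
                 dimnames = list(genes, sprintf("subj_%03d", seq_len(n))))
  eta <- as.vector(t(expr) %*% b1)
  lambda <- config$baseline_rate * exp(eta)
  t_event <- rexp(n, rate = lambda)
  if (config$censoring_rate > 0) {
    # expected censoring fraction under C ~ U(0, u): mean over subjects of
    # (1 - exp(-lambda u)) / (lambda u)
    cens_frac <- function(u) mean((1 - exp(-lambda * u)) / (lambda * u)) -
      config$censoring_rate
    u <- uniroot(cens_frac, lower = 1e-8, upper = 1e8, tol = 1e-10)$root
    t_cens <- runif(n, 0, u)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
  } else {
    time <- t_event
    event <- rep(1L, n)
  }
  list(expr = expr,
       survival = data.frame(subject_id = colnames(expr), time = time,
                             event = event, stringsAsFactors = FALSE),
       b1 = setNames(b1, genes))
}

#' Compare assigned patterns with simulation truth
#'
#' @param assigned data frame with `probe_id` and `pattern` columns: the
#'   full posterior table of a [backpay()] fit (modal patterns), optionally
#'   with a logical `selected` column or accompanied by `selected` probe
#'   IDs from [select_differential()].
#' @param truth the `truth` component of a [simulate_methylation()] study.
#' @param selected optional character vector of selected probe IDs.
#' @return list with `modal_accuracy` (all probes: modal pattern equals
#'   truth), `selected_accuracy`, `fdr` (fraction of selected probes whose
#'   truth is the null pattern), `n_selected`, and a sparse `confusion`
#'   table (truth x assigned).
#' @export
evaluate_assignments <- function(assigned, truth, selected = NULL) {
  assigned <- as.data.frame(assigned)
  stopifnot(all(c("probe_id", "pattern") %in% names(assigned)))
  if (!setequal(assigned$probe_id, truth$probe_id))
    stop("probe sets of 'assigned' and 'truth' differ")
  tr <- truth$pattern[match(assigned$probe_id, truth$probe_id)]
  if (is.null(selected)) {
    selected <- if ("selected" %in% names(assigned))
      assigned$probe_id[assigned$selected] else character(0)
  }
  hit <- assigned$pattern == tr
  sel <- assigned$probe_id %in% selected
  list(modal_accuracy = mean(hit),
       selected_accuracy = if (any(sel)) mean(hit[sel]) else NA_real_,
       fdr = if (any(sel)) mean(tr[sel] == null_pattern()) else 0,
       n_selected = sum(sel),
       confusion = table(truth = tr, assigned = assigned$pattern))
}
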