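#' Per-tissue group means with 95% confidence intervals
#'
#' For each requested feature and tissue group: the sample mean and the
#' two-sided 95% t-interval `mean +/- t(0.975, n-1) * sd / sqrt(n)`.
#' Singleton groups return the mean with an undefined-CI flag; zero-variance
#' groups collapse the interval onto the mean.
#'
#' @param x feature-by-sample matrix.
#' @param samples sample sheet.
#' @param feature_ids features to summarise (default: all rows).
#' @return data frame: `feature_id`, `group`, `n`, `mean`, `ci_low`,
#'   `ci_high`, `ci_defined`.
#' @export
group_summary <- function(x, samples, feature_ids = rownames(x)) {
  al <- .align_samples(as.matrix(x), samples)
  x <- al$x
  missing_ids <- setdiff(feature_ids, rownames(x))
  if (length(missing_ids))
    stop("unknown feature(s): ", paste(missing_ids, collapse = ", "))
  out <- list()
  for (g in c("ATM", "CAM", "NTM")) {
    sub <- x[feature_ids, al$samples$tissue == g, drop = FALSE]
    n <- ncol(sub)
    m <- rowMeans(sub)
    if (n > 1L) {
      se <- sqrt(rowSums((sub - m)^2) / (n - 1L)) / sqrt(n)
      half <- qt(0.975, df = n - 1L) * se
      lo <- m - half; hi <- m + half; def <- TRUE
    } else {
      lo <- hi <- rep(NA_real_, length(m)); def <- FALSE
    }
    out[[g]] <- data.frame(feature_id = feature_ids, group = g, n = n,
                           mean = m, ci_low = lo, ci_high = hi,
                           ci_defined = def, stringsAsFactors = FALSE,
                           row.names = NULL)
  }
  res <- do.call(rbind, out)
  res <- res[order(rep(seq_along(feature_ids), 3L)), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Long-format tissue trajectories of selected probes
#'
#' For every selected probe and sex stratum, the three tissue means of the
#' observed M-values in the fixed order ATM, CAM, NTM, with the assigned
#' pattern and its probability.
#'
#' @param assignments a [select_differential()] table (`probe_id`,
#'   `pattern`, `probability`).
#' @param x probe-by-sample M-value matrix.
#' @param samples sample sheet or an [encode_design()] frame.
#' @return data frame: `probe_id`, `stratum`, `tissue`, `mean_mvalue`,
#'   `pattern`, `probability`; `nrow = selected x 2 x 3`.
#' @export
export_pattern_trajectories <- function(assignments, x, samples) {
  x <- as.matrix(x)
  enc <- if (all(c("stratum", "x1", "x2") %in% names(samples))) samples else
    encode_design(validate_sample_sheet(samples))
  assignments <- assignments[order(assignments$probe_id), , drop = FALSE]
  miss <- setdiff(assignments$probe_id, rownames(x))
  if (length(miss)) stop("probes not in matrix: ", paste(miss, collapse = ", "))
  rows <- list()
  for (s in c("male", "female")) {
    for (tis in c("ATM", "CAM", "NTM")) {
      cols <- which(enc$sex == s & enc$tissue == tis)
      mm <- if (length(cols))
        rowMeans(x[assignments$probe_id, cols, drop = FALSE]) else
        rep(NA_real_, nrow(assignments))
      rows[[paste(s, tis)]] <- data.frame(
        probe_id = assignments$probe_id, stratum = s, tissue = tis,
        mean_mvalue = unname(mm), pattern = assignments$pattern,
        probability = assignments$probability,
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$probe_id, match(out$stratum, c("male", "female")),
                   match(out$tissue, c("ATM", "CAM", "NTM"))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full pattern-detection pipeline
#'
#' Orchestrates prefilter -> mixture model and/or moderated statistics ->
#' optional survival screen on either simulated or file-based inputs,
#' writing every stage output as TSV plus a JSON manifest (parameters, seed,
#' file checksums, stage status) into `out_dir`.
#'
#' @param config nested list (or path to a JSON file) with entries:
#'   `seed`; either `simulate` (arguments for [sim_config()]) or `input`
#'   (`matrix`, `samples` file paths); `prefilter` (`enabled`, `alpha`);
#'   `backpay` (`enabled`, `n_iter`, `burn_in`, `pb`, `q_cut`); `limma`
#'   (`enabled`); `survival` (`enabled`, plus either simulated via the
#'   config or `expr`/`surv` file paths).
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- config
  seed <- as.integer(cfg$seed %||% 1L)
  manifest <- list(package = "methpattern",
                   version = as.character(packageVersion("methpattern")),
                   seed = seed, parameters = cfg, stages = list(),
                   outputs = list(), complete = FALSE)
  logfile <- file.path(out_dir, "pipeline.log")
  logmsg <- function(...) cat(format(Sys.time(), "%H:%M:%S"), ..., "\n",
                              file = logfile, append = TRUE)
  emit <- function(name, obj, writer) {
    path <- file.path(out_dir, name)
    writer(obj, path)
    manifest$outputs[[name]] <<- unname(md5sum(path))
    path
  }
  wt <- function(df, path) write.table(df, path, sep = "\t", quote = FALSE,
                                       row.names = FALSE)
  run_stage <- function(name, expr) {
    logmsg("stage", name, "start")
    res <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- "failed"
      manifest$complete <<- FALSE
      .write_manifest(manifest, out_dir)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- "done"
    logmsg("stage", name, "done")
    res
  }

  # --- inputs ---
  if (!is.null(cfg$simulate)) {
    sim <- run_stage("simulate", {
      args <- cfg$simulate[setdiff(names(cfg$simulate), "seed")]
      sc <- do.call(sim_config, c(args, list(seed = seed)))
      simulate_methylation(sc)
    })
    mat <- sim$M; samples <- sim$samples
    emit("truth.tsv", sim$truth, wt)
  } else if (!is.null(cfg$input)) {
    mat <- read_feature_matrix(cfg$input$matrix)
    samples <- read_sample_sheet(cfg$input$samples)
    sim <- NULL
    manifest$input_checksums <- list(
      matrix = unname(md5sum(cfg$input$matrix)),
      samples = unname(md5sum(cfg$input$samples)))
  } else stop("config needs either 'simulate' or 'input'")

  # --- prefilter ---
  pf_cfg <- cfg$prefilter %||% list()
  if (isTRUE(pf_cfg$enabled %||% TRUE)) {
    pf <- run_stage("prefilter", {
      m <- drop_missing_features(mat)
      anova_filter(m, samples, alpha = pf_cfg$alpha %||% 0.05)
    })
    mat_use <- pf$matrix
    emit("anova_table.tsv", pf$table, wt)
    emit("filtered_matrix.tsv", mat_use,
         function(o, p) write_feature_matrix(o, p, id_name = "probe_id"))
  } else {
    mat_use <- drop_missing_features(mat)
    manifest$stages$prefilter <- "skipped"
  }

  # --- mixture model ---
  bp_cfg <- cfg$backpay %||% list()
  if (isTRUE(bp_cfg$enabled %||% TRUE)) {
    fit <- run_stage("backpay", backpay(
      mat_use, samples,
      n_iter = bp_cfg$n_iter %||% 30000L,
      burn_in = bp_cfg$burn_in %||% 10000L,
      pb = bp_cfg$pb %||% 0.5, q_cut = bp_cfg$q_cut %||% 0.05,
      seed = seed, keep_draws = FALSE))
    sel <- select_differential(fit)
    emit("assignments.tsv", fit$table, wt)
    emit("selected.tsv", sel, wt)
    emit("pattern_probabilities.tsv",
         data.frame(probe_id = rownames(fit$pattern_prob), fit$pattern_prob,
                    check.names = FALSE), wt)
    if (nrow(sel))
      emit("pattern_trajectories.tsv",
           export_pattern_trajectories(sel, mat_use, samples), wt)
  } else manifest$stages$backpay <- "skipped"

  # --- moderated statistics ---
  lm_cfg <- cfg$limma %||% list()
  if (isTRUE(lm_cfg$enabled %||% TRUE)) {
    mod <- run_stage("moderated", suppressWarnings(
      moderated_screen(mat_use, samples)))
    emit("moderated_stats.tsv", as.data.frame(mod), wt)
  } else manifest$stages$moderated <- "skipped"

  # --- survival screen ---
  sv_cfg <- cfg$survival %||% list()
  if (isTRUE(sv_cfg$enabled %||% FALSE)) {
    scr <- run_stage("survival", {
      if (!is.null(sv_cfg$expr)) {
        expr <- read_feature_matrix(sv_cfg$expr)
        surv <- read.csv(sv_cfg$surv, stringsAsFactors = FALSE)
      } else {
        args <- cfg$simulate %||% list()
        args <- args[setdiff(names(args), "seed")]
        sc <- do.call(sim_config, c(args, list(seed = seed)))
        ss <- simulate_survival(sc)
        expr <- ss$expr; surv <- ss$survival
      }
      screen_genes(expr, setNames(surv$time, surv$subject_id), surv$event)
    })
    emit("survival_screen.tsv", scr, wt)
  } else manifest$stages$survival <- "skipped"

  manifest$complete <- !any(unlist(manifest$stages) == "failed")
  .write_manifest(manifest, out_dir)
  logmsg("pipeline complete")
  invisible(manifest)
}

.write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
}
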