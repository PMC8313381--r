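test_that("methylation simulator matches its configuration and seed contract", {
  cfg <- sim_config(n_probes = 25, seed = 2)
  sim <- simulate_methylation(cfg)
  expect_equal(dim(sim$M), c(25L, 9L))
  expect_equal(colnames(sim$M), cfg$samples$sample_id)
  expect_equal(nrow(sim$truth), 25L)
  expect_true(all(sim$truth$pattern %in% pattern_labels()))
  # beta matrix is the inverse-logit of M
  expect_equal(sim$beta, beta_from_m(sim$M), tolerance = 1e-12)
  # determinism
  sim2 <- simulate_methylation(cfg)
  expect_identical(sim$M, sim2$M)
  expect_identical(sim$truth, sim2$truth)
})

test_that("noise-free group means equal the trajectory means exactly", {
  cfg <- sim_config(n_probes = 15, noise_sd = 0, seed = 3)
  sim <- simulate_methylation(cfg)
  enc <- encode_design(sim$samples)
  for (s in c("male", "female")) {
    b1 <- if (s == "male") sim$truth$beta_m1 else sim$truth$beta_f1
    b2 <- if (s == "male") sim$truth$beta_m2 else sim$truth$beta_f2
    mu <- trajectory_means(sim$truth$a, b1, b2)
    for (tis in c("ATM", "CAM", "NTM")) {
      cols <- enc$sex == s & enc$tissue == tis
      expect_equal(unname(rowMeans(sim$M[, cols, drop = FALSE])),
                   unname(mu[, tis]), tolerance = 1e-12)
    }
  }
  # slope signs in truth respect the cluster definitions
  sg <- cluster_signs()
  expect_true(all(sign(sim$truth$beta_m1) ==
                    sg[match(sim$truth$male_cluster, cluster_labels()), 1]))
})

test_that("empirical pattern frequencies match the configuration", {
  cfg <- sim_config(n_probes = 4000, seed = 4)
  sim <- simulate_methylation(cfg)
  f <- cfg$pattern_frequencies
  emp <- table(factor(sim$truth$pattern, levels = pattern_labels())) / 4000
  for (pat in names(f)[f > 0]) {
    sd3 <- 3 * sqrt(f[[pat]] * (1 - f[[pat]]) / 4000)
    expect_lt(abs(emp[[pat]] - f[[pat]]), sd3 + 1e-9)
  }
  expect_equal(sum(emp[names(f)[f == 0]]), 0)
})

test_that("survival simulator hits the target censoring rate and is seeded", {
  cfg <- sim_config(n_subjects = 1000, n_genes = 3, b1 = c(0.5, 0, 0),
                    censoring_rate = 0.3, seed = 5)
  ss <- simulate_survival(cfg)
  expect_equal(dim(ss$expr), c(3L, 1000L))
  expect_lt(abs(mean(1 - ss$survival$event) - 0.3), 0.05)
  ss2 <- simulate_survival(cfg)
  expect_identical(ss$survival, ss2$survival)
  expect_identical(ss$expr, ss2$expr)
  # zero censoring: everyone has an event
  ss3 <- simulate_survival(sim_config(n_subjects = 50, n_genes = 1,
                                      censoring_rate = 0, seed = 6))
  expect_true(all(ss3$survival$event == 1))
})

test_that("null expression is uninformative for threshold-split survival", {
  ps <- vapply(1:4, function(s) {
    ss <- simulate_survival(sim_config(n_subjects = 200, n_genes = 1, b1 = 0,
                                       censoring_rate = 0.2, seed = 200 + s))
    grp <- dichotomize(ss$expr[1, ], 0)
    sd <- survival::survdiff(survival::Surv(ss$survival$time,
                                            ss$survival$event) ~ grp)
    1 - pchisq(sd$chisq, 1)
  }, 0)
  # log-rank p-values behave like draws from a null: none systematically tiny
  expect_gt(min(ps), 0.001)
  expect_gt(max(ps), 0.1)
})

test_that("assignment evaluation matches a brute-force comparison loop", {
  sim <- simulate_methylation(sim_config(n_probes = 30, seed = 8))
  truth <- sim$truth
  set.seed(9)
  assigned <- data.frame(probe_id = truth$probe_id,
                         pattern = sample(pattern_labels(), 30, replace = TRUE))
  sel <- sample(truth$probe_id, 10)
  ev <- evaluate_assignments(assigned, truth, selected = sel)
  # oracle loop
  acc <- fdr <- 0; nsel <- 0
  for (i in seq_len(30)) {
    hit <- assigned$pattern[i] == truth$pattern[i]
    acc <- acc + hit
    if (assigned$probe_id[i] %in% sel) {
      nsel <- nsel + 1
      if (truth$pattern[i] == null_pattern()) fdr <- fdr + 1
    }
  }
  expect_equal(ev$modal_accuracy, acc / 30)
  expect_equal(ev$fdr, fdr / nsel)
  expect_equal(ev$n_selected, nsel)
  # identity and degenerate cases
  ev2 <- evaluate_assignments(truth[, c("probe_id", "pattern")], truth,
                              selected = truth$probe_id)
  expect_equal(ev2$modal_accuracy, 1)
  expect_equal(ev2$selected_accuracy, 1)
  flat_truth <- truth
  flat_truth$pattern <- null_pattern()
  ev3 <- evaluate_assignments(assigned, flat_truth, selected = sel)
  expect_equal(ev3$fdr, 1)
  expect_error(evaluate_assignments(assigned[-1, ], truth), "probe sets")
})
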