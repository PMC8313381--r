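test_that("the toy Cox fit matches a grid-search partial-likelihood maximiser", {
  time <- c(1, 2, 3, 4); event <- c(1, 1, 1, 1); x <- c(0, 1, 0, 1)
  fit <- cox_fit_univariate(time, event, x)
  opt <- optimize(function(b) -breslow_loglik(b, time, event, x),
                  interval = c(-10, 10), tol = 1e-9)
  expect_equal(fit$b1, opt$minimum, tolerance = 1e-4)
  expect_true(fit$converged)
  expect_false(fit$degenerate)
  expect_equal(fit$n_events, 4)
  # Wald p is the two-sided normal tail of b1/se
  expect_equal(fit$wald_p, 2 * pnorm(abs(fit$b1 / fit$se), lower.tail = FALSE))
})

test_that("a perfectly separated covariate is flagged non-converged", {
  # every x = 1 subject outlives every x = 0 subject: the partial likelihood
  # is monotone and the estimate runs away
  fit <- cox_fit_univariate(c(1, 2, 3, 4), rep(1, 4), c(0, 0, 1, 1))
  expect_false(fit$converged)
  expect_false(fit$degenerate)
  expect_lt(fit$b1, -5)
})

test_that("degenerate survival inputs are flagged", {
  expect_warning(f <- cox_fit_univariate(1:4, rep(1, 4), rep(2, 4)), "constant")
  expect_true(f$degenerate)
  expect_true(is.na(f$b1))
  expect_warning(f2 <- cox_fit_univariate(1:4, rep(0, 4), rnorm(4)), "events")
  expect_true(f2$degenerate)
  expect_error(cox_fit_univariate(c(-1, 2), c(1, 1), c(0, 1)), "positive")
  expect_error(cox_fit_univariate(c(1, 2), c(1, 2), c(0, 1)), "0/1")
})

test_that("simulation recovery: estimated log hazard ratio near the truth", {
  cfg <- sim_config(n_genes = 1, n_subjects = 500, b1 = 1,
                    censoring_rate = 0.2, seed = 71)
  ss <- simulate_survival(cfg)
  fit <- cox_fit_univariate(ss$survival$time, ss$survival$event, ss$expr[1, ])
  expect_lt(abs(fit$b1 - 1), 3 * fit$se)
  expect_lt(fit$wald_p, 1e-6)
})

test_that("Cox estimates transform correctly under rescaling", {
  set.seed(81)
  n <- 120
  x <- rnorm(n)
  t_ev <- rexp(n, rate = 0.2 * exp(0.8 * x))
  ev <- rbinom(n, 1, 0.8)
  f1 <- cox_fit_univariate(t_ev, ev, x)
  # time rescaling leaves the estimate unchanged
  f2 <- cox_fit_univariate(t_ev * 365, ev, x)
  expect_equal(f2$b1, f1$b1, tolerance = 1e-8)
  # covariate rescaling divides the estimate
  f3 <- cox_fit_univariate(t_ev, ev, x * 2)
  expect_equal(f3$b1, f1$b1 / 2, tolerance = 1e-6)
})

test_that("gene screening adjusts across genes and reports association sign", {
  cfg <- sim_config(n_genes = 40, n_subjects = 238,
                    b1 = c(1, rep(0, 39)), censoring_rate = 0.2, seed = 91)
  ss <- simulate_survival(cfg)
  scr <- screen_genes(ss$expr, setNames(ss$survival$time, ss$survival$subject_id),
                      ss$survival$event)
  expect_equal(nrow(scr), 40L)
  expect_equal(scr$gene[which.min(scr$p)], rownames(ss$expr)[1])
  # higher expression -> higher hazard -> shorter survival: sign "-"
  expect_equal(scr$sign[1], "-")
  expect_equal(scr$p_BH, bh_oracle(scr$p))
  expect_error(screen_genes(ss$expr[, 1:10], ss$survival$time,
                            ss$survival$event), "misaligned")
})

test_that("null gene screens rarely reach BH significance", {
  hits <- vapply(1:3, function(s) {
    ss <- simulate_survival(sim_config(n_genes = 60, n_subjects = 238, b1 = 0,
                                       censoring_rate = 0.2, seed = 100 + s))
    scr <- screen_genes(ss$expr, ss$survival$time, ss$survival$event)
    sum(scr$p_BH < 0.05)
  }, 0)
  expect_true(all(hits == 0))
})

test_that("dichotomization splits at the threshold with documented boundary", {
  g <- dichotomize(c(5.9, 6.1), 6)
  expect_equal(as.character(g), c("low", "high"))
  expect_equal(as.character(dichotomize(c(6, 6.0001), 6)), c("low", "high"))
  expect_warning(g2 <- dichotomize(c(1, 2, 3), 0), "one side")
  expect_true(all(g2 == "high"))
  # invariance to a common shift of data and threshold
  x <- c(1.2, 5.8, 6.3)
  expect_equal(dichotomize(x, 6), dichotomize(x + 10, 16))
})

test_that("Kaplan-Meier curves follow the product-limit construction", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1), rep("a", 3))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$n_risk, c(3, 2, 1))
  # all censored: flat at 1
  km2 <- km_estimate(c(1, 2, 3), c(0, 0, 0), rep("a", 3))
  expect_true(all(km2$survival == 1))
  # no censoring: equals the empirical survival function
  set.seed(111)
  t3 <- sort(rexp(20))
  km3 <- km_estimate(t3, rep(1, 20), rep("a", 20))
  expect_equal(km3$survival, 1 - seq_len(20) / 20)
  # censoring after the last event leaves earlier curve unchanged
  km4 <- km_estimate(c(1, 2, 3, 10), c(1, 1, 1, 0), rep("a", 4))
  expect_equal(km4$survival[1:3], c(3 / 4, 2 / 4, 1 / 4))
  expect_error(km_estimate(c(1, 2), c(1, 1), factor(c("a", "a"),
                                                   levels = c("a", "b"))),
               "group")
})
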