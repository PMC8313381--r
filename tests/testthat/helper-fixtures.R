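# shared fixtures and independent oracles

nine_sample_sheet <- function() default_sample_layout()

# brute-force Benjamini-Hochberg step-up, straight from the definition
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- pmin(1, m * ps / seq_len(m))
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Breslow log partial likelihood for a univariate Cox model (no tied-time
# handling needed beyond Breslow's sum-over-risk-set form)
breslow_loglik <- function(b, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + b * x[i] - log(sum(exp(b * x[risk])))
  }
  ll
}

# tiny deterministic M-value matrix with known group structure
toy_matrix <- function(p = 4, sheet = nine_sample_sheet(), seed = 42) {
  set.seed(seed)
  m <- matrix(rnorm(p * nrow(sheet)), p,
              dimnames = list(paste0("cg", seq_len(p)), sheet$sample_id))
  m
}
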