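# internal random-variate helpers

# one draw per element of (mean, sd), truncated to the half-line with the
# given sign (+1 -> (0, Inf), -1 -> (-Inf, 0)).  Inverse-CDF in the easy
# range; one-sided exponential rejection (Robert 1995) deep in a tail where
# the CDF saturates.
.rtrunc_signed <- function(mean, sd, sign) {
  n <- max(length(mean), length(sd), length(sign))
  mean <- rep_len(mean, n); sd <- rep_len(sd, n); sign <- rep_len(sign, n)
  # standardise to lower truncation at a for +X
  a <- -sign * mean / sd            # draw Z > a, return sign * (mean + sd * Z * sign)... see below
  z <- numeric(n)
  easy <- a < 5
  if (any(easy)) {
    lo <- pnorm(a[easy])
    u <- runif(sum(easy), lo, 1)
    z[easy] <- qnorm(pmin(u, 1 - 1e-16))
  }
  if (any(!easy)) {
    for (i in which(!easy)) {
      ai <- a[i]
      lambda <- (ai + sqrt(ai^2 + 4)) / 2
      repeat {
        x <- ai + rexp(1L, lambda)
        if (runif(1L) <= exp(-(x - lambda)^2 / 2)) { z[i] <- x; break }
      }
    }
  }
  mean + sign * sd * z
}

.rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) <= 0) g <- g + 1e-12
  g / sum(g)
}
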