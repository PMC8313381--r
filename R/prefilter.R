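#' Drop features with any missing value
#'
#' @param x feature-by-sample numeric matrix.
#' @return the submatrix of rows with no missing entries, in the original
#'   order; warns when nothing survives.
#' @export
drop_missing_features <- function(x) {
  stopifnot(is.matrix(x))
  keep <- complete.cases(x) & rowSums(is.infinite(x)) == 0L
  out <- x[keep, , drop = FALSE]
  if (nrow(out) == 0L && nrow(x) > 0L)
    warning("all ", nrow(x), " features contained missing values; empty matrix returned")
  out
}

#' One-way ANOVA F-test for a single feature
#'
#' Classical one-way ANOVA: `F = MS_between / MS_within` on
#' `(k - 1, n - k)` degrees of freedom, with the p-value from the upper tail
#' of the F distribution.  Degenerate inputs are flagged rather than
#' erroring: zero within-group variance with a real between-group difference
#' gives p = 0, and completely constant data gives p = 1.
#'
#' @param values numeric vector of observations.
#' @param groups group labels, same length as `values`; >= 2 groups required.
#' @return list with `F`, `p`, `df` (length 2) and `degenerate` (logical).
#' @examples
#' one_way_anova(c(1, 2, 3, 2, 3, 4, 3, 4, 5), rep(c("a", "b", "c"), each = 3))
#' @export
one_way_anova <- function(values, groups) {
  groups <- as.factor(groups)
  if (length(values) != length(groups)) stop("'values' and 'groups' lengths differ")
  if (anyNA(values)) stop("missing values; apply drop_missing_features() first")
  k <- nlevels(droplevels(groups))
  n <- length(values)
  if (k < 2L) stop("need >= 2 groups")
  if (n - k < 2L) stop("need >= 2 residual degrees of freedom")
  st <- .row_anova(matrix(values, nrow = 1L), droplevels(groups))
  list(F = st$F[1L], p = st$p[1L], df = c(k - 1L, n - k),
       degenerate = st$degenerate[1L])
}

# vectorised one-way ANOVA over matrix rows
.row_anova <- function(x, groups) {
  groups <- droplevels(as.factor(groups))
  k <- nlevels(groups)
  n <- ncol(x)
  cnt <- as.vector(table(groups))
  G <- rowsum(t(x), groups)                  # k x p group sums
  gm <- G / cnt                              # group means
  grand <- colSums(G) / n
  ssb <- colSums(cnt * (gm - rep(grand, each = k))^2)
  sst <- rowSums(x^2) - n * grand^2
  ssw <- pmax(sst - ssb, 0)
  msb <- ssb / (k - 1L)
  msw <- ssw / (n - k)
  tol <- 1e-12 * pmax(rowMeans(x^2), 1)
  Fst <- msb / msw
  p <- pf(Fst, k - 1L, n - k, lower.tail = FALSE)
  degenerate <- msw <= tol
  const <- degenerate & msb <= tol
  sep <- degenerate & msb > tol
  Fst[const] <- NaN; p[const] <- 1
  Fst[sep] <- Inf; p[sep] <- 0
  list(F = unname(Fst), p = unname(p), degenerate = unname(degenerate))
}

#' Filter features by one-way ANOVA across tissue types
#'
#' Per-feature one-way ANOVA with the three tissue types as groups (sexes
#' pooled); features with `p < alpha` (strict) are retained.  This is the
#' pre-screen that reduces an array-scale matrix to the differentially
#' varying features handed to the mixture-model and moderated-statistics
#' stages.
#'
#' @param x feature-by-sample numeric matrix (no missing values).
#' @param samples sample sheet (see [validate_sample_sheet()]).
#' @param alpha retention threshold on the raw p-value (default 0.05).
#' @return list with `matrix` (retained rows, order preserved) and `table`
#'   (data frame: feature_id, F, p, degenerate, kept).
#' @export
anova_filter <- function(x, samples, alpha = 0.05) {
  al <- .align_samples(x, samples)
  x <- al$x
  if (anyNA(x)) stop("missing values; apply drop_missing_features() first")
  st <- .row_anova(x, al$samples$tissue)
  kept <- st$p < alpha
  tab <- data.frame(feature_id = rownames(x) %||% seq_len(nrow(x)),
                    F = st$F, p = st$p, degenerate = st$degenerate,
                    kept = kept, stringsAsFactors = FALSE)
  list(matrix = x[kept, , drop = FALSE], table = tab)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
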