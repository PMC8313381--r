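#' Trajectory cluster and pattern vocabulary
#'
#' A probe's methylation trajectory over the three tissue groups (ordered
#' ATM, CAM, NTM, with CAM the regression reference) is summarised by the
#' signs of the two slope coefficients: `g1` for the ATM indicator and `g2`
#' for the NTM indicator.  Because the fitted group means are
#' `(a + b1, a, a + b2)`, the ATM-to-CAM segment goes *down* when `g1 = +`,
#' *up* when `g1 = -`, and is *flat* when `g1 = 0`; the CAM-to-NTM segment
#' follows the sign of `g2` directly.  Enumerating the signs gives exactly
#' nine trajectory clusters; a *pattern* is the ordered pair
#' (male cluster, female cluster), so there are 81 patterns and the null
#' pattern is `FlatFlat-FlatFlat`.
#'
#' The cluster enumeration order used everywhere in this package (indices
#' 1 to 9) is: DownUp, FlatUp, UpUp, DownFlat, FlatFlat, UpFlat, DownDown,
#' FlatDown, UpDown.  Pattern indices run male-major, female-minor:
#' `pattern_index = (male - 1) * 9 + female`.
#'
#' @return `cluster_labels()` returns the character vector of the 9 cluster
#'   names in enumeration order.  `cluster_signs()` returns a 9 x 2 integer
#'   matrix of slope signs (-1, 0, 1) with rows named by cluster.
#' @examples
#' cluster_labels()
#' cluster_signs()["DownUp", ]   # c(1, 1): both slopes positive
#' @export
cluster_labels <- function() {
  c("DownUp", "FlatUp", "UpUp",
    "DownFlat", "FlatFlat", "UpFlat",
    "DownDown", "FlatDown", "UpDown")
}

#' @rdname cluster_labels
#' @export
cluster_signs <- function() {
  m <- cbind(g1 = rep(c(1L, 0L, -1L), 3L),
             g2 = rep(c(1L, 0L, -1L), each = 3L))
  rownames(m) <- cluster_labels()
  m
}

.sign_token_to_int <- function(g) {
  if (is.character(g)) {
    out <- c("+" = 1L, "0" = 0L, "-" = -1L)[g]
    if (anyNA(out)) stop("invalid sign token: ", paste(g[is.na(out)], collapse = ", "))
    unname(out)
  } else {
    g <- as.integer(g)
    if (!all(g %in% c(-1L, 0L, 1L))) stop("signs must be -1, 0 or +1")
    g
  }
}

#' Map slope signs to a trajectory cluster label and back
#'
#' @param g1,g2 slope signs for the ATM and NTM coefficients; either the
#'   tokens `"+"`, `"0"`, `"-"` or the integers 1, 0, -1.
#' @param label a cluster name, one of [cluster_labels()].
#' @return `cluster_label_from_signs()` returns the cluster name;
#'   `signs_from_label()` returns the length-2 integer sign vector.
#' @examples
#' cluster_label_from_signs("+", "+")  # "DownUp"
#' signs_from_label("FlatUp")          # c(0, 1)
#' @export
cluster_label_from_signs <- function(g1, g2) {
  g1 <- .sign_token_to_int(g1)
  g2 <- .sign_token_to_int(g2)
  sg <- cluster_signs()
  idx <- match(paste(g1, g2), paste(sg[, 1L], sg[, 2L]))
  cluster_labels()[idx]
}

#' @rdname cluster_label_from_signs
#' @export
signs_from_label <- function(label) {
  idx <- match(label, cluster_labels())
  if (anyNA(idx)) stop("unknown cluster label: ", paste(label[is.na(idx)], collapse = ", "))
  sg <- cluster_signs()
  if (length(idx) == 1L) sg[idx, ] else sg[idx, , drop = FALSE]
}

#' Pattern labels, indices and the null pattern
#'
#' @return `pattern_labels()`: the 81 `male-female` pattern names in index
#'   order (male cluster major).  `null_pattern()`: the name of the
#'   no-change pattern.  `pattern_index()`: integer index of a pattern name.
#' @examples
#' pattern_labels()[41]  # "FlatFlat-FlatFlat", the null pattern
#' pattern_index("DownUp-FlatUp")
#' @export
pattern_labels <- function() {
  cl <- cluster_labels()
  as.vector(t(outer(cl, cl, paste, sep = "-")))
}

#' @rdname pattern_labels
#' @export
null_pattern <- function() "FlatFlat-FlatFlat"

#' @rdname pattern_labels
#' @param pattern character vector of pattern names.
#' @export
pattern_index <- function(pattern) {
  idx <- match(pattern, pattern_labels())
  if (anyNA(idx)) stop("unknown pattern: ", paste(pattern[is.na(idx)], collapse = ", "))
  idx
}

#' Split a pattern name into its stratum clusters
#'
#' @param pattern character vector of `male-female` pattern names.
#' @return data frame with columns `pattern`, `male_cluster`, `female_cluster`.
#' @export
pattern_clusters <- function(pattern) {
  pattern_index(pattern)  # validates
  parts <- strsplit(pattern, "-", fixed = TRUE)
  data.frame(pattern = pattern,
             male_cluster = vapply(parts, `[`, "", 1L),
             female_cluster = vapply(parts, `[`, "", 2L))
}

#' Sex-discordant patterns of primary interest
#'
#' The eight patterns in which the male and female trajectory clusters are
#' both non-flat monotone-segment shapes and differ between the sexes; these
#' are the pattern families highlighted by the analysis (four with the sex
#' difference expressed in the NTM group, four in the CAM group).
#'
#' @return character vector of 8 pattern names.
#' @seealso [is_discordant_pattern()] which tags *any* pattern whose male and
#'   female clusters differ.
#' @examples
#' differential_pattern_catalog()
#' @export
differential_pattern_catalog <- function() {
  c("UpUp-UpDown", "UpDown-UpUp", "DownUp-DownDown", "DownDown-DownUp",
    "UpUp-DownUp", "UpDown-DownDown", "DownUp-UpUp", "DownDown-UpDown")
}

#' @rdname differential_pattern_catalog
#' @param pattern character vector of pattern names.
#' @export
is_discordant_pattern <- function(pattern) {
  pc <- pattern_clusters(pattern)
  pc$male_cluster != pc$female_cluster
}

#' Fitted tissue-group means of a trajectory
#'
#' Under the design encoding ATM = (1,0), NTM = (0,1), CAM = (0,0) the model
#' mean for the three tissue groups is `(a + b1, a, a + b2)`.
#'
#' @param intercept intercept `a` (M-value units).
#' @param beta1,beta2 slopes for the ATM and NTM indicators.
#' @return named numeric vector `c(ATM=, CAM=, NTM=)`; vectorised over inputs
#'   (returns a matrix with one row per input when any argument has length > 1).
#' @examples
#' trajectory_means(0, 1, 1)    # (1, 0, 1): a DownUp trajectory
#' trajectory_means(0, -2, 1)   # (-2, 0, 1): an UpUp trajectory
#' @export
trajectory_means <- function(intercept, beta1, beta2) {
  n <- max(length(intercept), length(beta1), length(beta2))
  out <- cbind(ATM = rep_len(intercept, n) + rep_len(beta1, n),
               CAM = rep_len(intercept, n),
               NTM = rep_len(intercept, n) + rep_len(beta2, n))
  if (n == 1L) out[1L, ] else out
}
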