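#' Fisher's exact test on a 2x2 contingency table
#'
#' Computes the classic two-sided Fisher exact p-value (the sum of all
#' hypergeometric outcomes no more probable than the observed table) and
#' the sample cross-product odds ratio. When any cell is zero the
#' Haldane-Anscombe correction (+0.5 to every cell) is applied before the
#' odds ratio is formed, so that log2 odds ratios stay finite and
#' displayable. Note that this is deliberately not the conditional
#' maximum-likelihood odds ratio that [stats::fisher.test()] reports; the
#' p-value, however, is the standard one.
#'
#' Cell layout follows the enrichment convention used throughout the
#' package: `a` = in-class in both margins, `b` = in-class in the first
#' margin only, `c` = in-class in the second margin only, `d` = neither.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return A list with elements `odds_ratio`, `log2_or` and `p`.
#' @examples
#' fisher2x2(10, 5, 2, 20)   # OR = 20, log2 OR ~ 4.32
#' fisher2x2(3, 0, 0, 3)     # Haldane-Anscombe: OR = 49
#' @export
fisher2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("contingency cells must be non-negative integers")
  if (sum(cells) == 0)
    stop("all-zero contingency table")
  tab <- matrix(as.integer(round(cells)), nrow = 2L, byrow = TRUE)
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1L] * cells[4L]) / (cells[2L] * cells[3L])
  list(odds_ratio = or, log2_or = log2(or), p = min(p, 1))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, capped at 1, returned in the
#' input order. Input p-values outside [0, 1] are an error.
#'
#' @param pvals Numeric vector of raw p-values.
#' @return Adjusted p-values, same length and order as the input.
#' @export
bhAdjust <- function(pvals) {
  checkProb(pvals, "pvals")
  stats::p.adjust(pvals, method = "BH")
}

#' Cohen's D standardized mean difference
#'
#' D = (mean(x) - mean(y)) / pooled SD with the usual (n-1)-weighted
#' pooled standard deviation. A zero pooled SD with differing means
#' returns a signed infinity; identical constant samples return 0.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @return A single numeric value.
#' @export
cohensD <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) stop("both samples need at least 2 observations")
  md <- mean(x) - mean(y)
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
               (nx + ny - 2))
  if (sp == 0) {
    if (md == 0) return(0)
    return(sign(md) * Inf)
  }
  md / sp
}

#' Seeded k-means clustering
#'
#' Thin deterministic wrapper around [stats::kmeans()] (the clustering
#' engine used for all grouping analyses in the package): the best
#' within-cluster sum of squares over `nStart` random initializations,
#' reproducible for a fixed `seed`.
#'
#' @param x Numeric matrix (rows are features, columns dimensions).
#' @param k Number of clusters, `1 <= k <= nrow(x)`.
#' @param seed Integer RNG seed.
#' @param nStart Number of random starts (default 25).
#' @return A list with `cluster` (named integer vector), `centers` and
#'   `tot_withinss`.
#' @export
kmeansCluster <- function(x, k, seed, nStart = 25L) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("'x' must not contain missing values")
  if (k < 1L) stop("'k' must be >= 1")
  if (k > nrow(x)) stop("'k' exceeds the number of rows")
  fit <- withSeed(seed,
    stats::kmeans(x, centers = k, nstart = nStart, iter.max = 100L))
  cl <- fit$cluster
  names(cl) <- rownames(x)
  list(cluster = cl, centers = fit$centers, tot_withinss = fit$tot.withinss)
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero variance.
#' @return Correlation coefficient in [-1, 1].
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance in 'x' or 'y'")
  stats::cor(x, y, method = "pearson")
}

#' Two-group location test
#'
#' Two-sided comparison of two samples, either by the equal-variance
#' Student's t-test or by the Wilcoxon rank-sum test. The rank-sum test
#' uses exact enumeration for small tie-free samples (combined n <= 20)
#' and the normal approximation with tie correction otherwise. Fully
#' degenerate inputs (all values identical) return p = 1.
#'
#' @param x,y Numeric samples.
#' @param kind `"student_t"` or `"wilcoxon_rank_sum"`.
#' @return Two-sided p-value.
#' @export
twoGroupTest <- function(x, y, kind = c("student_t", "wilcoxon_rank_sum")) {
  kind <- match.arg(kind)
  if (kind == "student_t") {
    if (length(x) < 2L || length(y) < 2L)
      stop("Student's t needs at least 2 observations per group")
    if (stats::var(x) == 0 && stats::var(y) == 0)
      return(if (mean(x) == mean(y)) 1 else 0)
    return(stats::t.test(x, y, var.equal = TRUE)$p.value)
  }
  if (length(x) < 1L || length(y) < 1L)
    stop("rank-sum test needs at least 1 observation per group")
  vals <- c(x, y)
  if (length(unique(vals)) == 1L) return(1)
  ties <- anyDuplicated(vals) > 0L
  exact <- !ties && length(vals) <= 20L
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value
  )
}
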