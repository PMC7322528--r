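# Per-layer differential records and fold-change matrices. The internal
# differential test is a deliberately simple Welch t on log2 values: the
# pipeline's value lies downstream, and externally computed differential
# tables (DESeq2, limma, ...) are accepted as first-class input through
# loadDifferential().

#' Derive up/down/ns direction labels
#' @noRd
directionLabel <- function(log2fc, adj_p, alpha) {
  ifelse(adj_p < alpha & log2fc > 0, "up",
         ifelse(adj_p < alpha & log2fc < 0, "down", "ns"))
}

#' Simple per-feature differential test between two time points
#'
#' For count data the matrix is library-size normalized to CPM and
#' log2(x + 1)-transformed; intensity data are log2-transformed as is.
#' Each feature is then tested with a Welch t-test between the two days
#' of the contrast, the log2 fold change is the difference of group means
#' (late minus early), and p-values are Benjamini-Hochberg adjusted
#' across features within the contrast. Directions use a strict
#' `adj_p < alpha` cutoff.
#'
#' @param mat Numeric feature x sample matrix.
#' @param design data.frame with columns `sample` (matching `colnames(mat)`),
#'   `day` and `replicate`.
#' @param layer Layer label stored in the records (`"atac"`, `"rna"` or
#'   `"protein"`).
#' @param dayLate,dayEarly The two days of the contrast (`dayLate >
#'   dayEarly`).
#' @param scale `"log_counts"` (CPM + 1, log2) or `"log_intensity"`
#'   (log2).
#' @param alpha FDR threshold for the direction call (default 0.05).
#' @return data.frame of differential records: `feature_id`, `layer`,
#'   `day_late`, `day_early`, `log2fc`, `p`, `adj_p`, `direction`.
#' @export
simpleDifferential <- function(mat, design, layer, dayLate, dayEarly,
                               scale = c("log_counts", "log_intensity"),
                               alpha = 0.05) {
  scale <- match.arg(scale)
  if (dayLate <= dayEarly) stop("'dayLate' must be greater than 'dayEarly'")
  design <- design[match(colnames(mat), design$sample), , drop = FALSE]
  late <- which(design$day == dayLate)
  early <- which(design$day == dayEarly)
  if (length(late) < 2L || length(early) < 2L)
    stop("each condition needs at least 2 replicates")
  lmat <- if (scale == "log_counts") log2(cpmNormalize(mat) + 1) else log2(mat)
  x <- lmat[, late, drop = FALSE]
  y <- lmat[, early, drop = FALSE]
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  tstat <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[se2 == 0] <- 1  # constant in both groups: no evidence either way
  adj <- bhAdjust(p)
  log2fc <- mx - my
  data.frame(
    feature_id = rownames(mat),
    layer = layer,
    day_late = dayLate,
    day_early = dayEarly,
    log2fc = log2fc,
    p = p,
    adj_p = adj,
    direction = directionLabel(log2fc, adj, alpha),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Load an externally computed differential table
#'
#' Accepts a TSV with columns `feature_id`, `layer`, `day_late`,
#' `day_early`, `log2fc`, `p`, `adj_p` (e.g. exported from DESeq2 or
#' limma) and derives direction labels at the configured alpha. A missing
#' column is an error naming it.
#'
#' @param path Path to the TSV.
#' @param alpha FDR threshold (default 0.05, strict inequality).
#' @return data.frame of differential records (see
#'   [simpleDifferential()]).
#' @export
loadDifferential <- function(path, alpha = 0.05) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("feature_id", "layer", "day_late", "day_early",
            "log2fc", "p", "adj_p")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("differential table misses column(s): ",
         paste(miss, collapse = ", "))
  df <- df[need]
  df$direction <- directionLabel(df$log2fc, df$adj_p, alpha)
  df
}

#' Log2 fold changes relative to a baseline day
#'
#' Per feature and day, the mean log2 value minus the baseline-day mean.
#' The baseline column is identically zero by construction and is
#' dropped. Days with a single replicate contribute their own value as
#' the mean.
#'
#' @inheritParams simpleDifferential
#' @param baselineDay Reference day (default 0).
#' @return Numeric matrix, features x non-baseline days (columns named by
#'   day).
#' @export
foldChangeToBaseline <- function(mat, design, baselineDay = 0,
                                 scale = c("log_counts", "log_intensity")) {
  scale <- match.arg(scale)
  design <- design[match(colnames(mat), design$sample), , drop = FALSE]
  days <- sort(unique(design$day))
  if (!baselineDay %in% days) stop("baseline day absent from the design")
  lmat <- if (scale == "log_counts") log2(cpmNormalize(mat) + 1) else log2(mat)
  means <- vapply(days, function(d)
    rowMeans(lmat[, design$day == d, drop = FALSE]),
    numeric(nrow(mat)))
  colnames(means) <- days
  fc <- means - means[, as.character(baselineDay)]
  fc[, colnames(fc) != as.character(baselineDay), drop = FALSE]
}

#' Cluster genes by joint RNA/protein fold-change profiles
#'
#' Inner-joins the two fold-change matrices on gene id, concatenates
#' their columns and k-means-clusters the result (default k = 7, the
#' granularity at which concerted and divergent RNA/protein behavior
#' separates cleanly in differentiation time courses).
#'
#' @param rnaFC,proteinFC Numeric matrices of log2 fold changes with gene
#'   ids as rownames.
#' @param k Number of clusters (default 7).
#' @param seed RNG seed for the k-means initialization.
#' @return List with `cluster` (named integer vector over the joined
#'   genes) and `centers` (per-cluster mean profiles).
#' @export
clusterExpressionProfiles <- function(rnaFC, proteinFC, k = 7L, seed = 1L) {
  genes <- intersect(rownames(rnaFC), rownames(proteinFC))
  if (length(genes) < k)
    stop("'k' exceeds the number of genes present in both matrices")
  joined <- cbind(rnaFC[genes, , drop = FALSE],
                  proteinFC[genes, , drop = FALSE])
  fit <- kmeansCluster(joined, k = k, seed = seed)
  list(cluster = fit$cluster, centers = fit$centers)
}
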