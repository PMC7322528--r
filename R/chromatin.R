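# Chromatin-state machinery around ChIP peak sets: mark-signal matrices,
# regulatory grouping, co-occupancy against other factors, the two-factor
# three-way partition and group-wise comparisons.

#' Length-weighted mean signal of tracks over peaks
#'
#' Each entry is the per-base average of a piecewise-constant signal
#' track (bedGraph semantics) over the peak interval; bases not covered
#' by the track count as 0 signal, not as missing.
#'
#' @param peaks `GRanges` of peaks (with `peak_id` used as rownames when
#'   present).
#' @param tracks Named list of `GRanges` signal tracks with a numeric
#'   `score` column (see [readBedGraph()]).
#' @return Numeric matrix, peaks x tracks.
#' @export
meanSignalMatrix <- function(peaks, tracks) {
  if (is.null(names(tracks)) || any(!nzchar(names(tracks))))
    stop("'tracks' must be a named list")
  n <- length(peaks)
  out <- matrix(0, nrow = n, ncol = length(tracks),
                dimnames = list(peaks$peak_id, names(tracks)))
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  st <- GenomicRanges::start(peaks)
  en <- GenomicRanges::end(peaks)
  for (j in seq_along(tracks)) {
    cvg <- GenomicRanges::coverage(tracks[[j]], weight = "score")
    for (chr in unique(chrom)) {
      sel <- which(chrom == chr)
      if (!chr %in% names(cvg)) next  # uncovered chromosome: signal 0
      rle <- cvg[[chr]]
      need <- max(en[sel])
      if (length(rle) < need)
        rle <- c(rle, S4Vectors::Rle(0, need - length(rle)))
      v <- IRanges::Views(rle, start = st[sel], end = en[sel])
      out[sel, j] <- IRanges::viewSums(v) / (en[sel] - st[sel] + 1)
    }
  }
  out
}

#' Group peaks into regulatory classes by their signal profile
#'
#' Columns (tracks) are z-scored so that marks on different scales
#' contribute equally, then the peaks are k-means-clustered. Constant
#' columns are left at zero. Interpreting and possibly merging visually
#' similar groups is up to the analyst.
#'
#' @param signalMatrix Peaks x tracks matrix (see [meanSignalMatrix()]).
#' @param k Number of regulatory groups.
#' @param seed RNG seed.
#' @return List with `group` (named integer vector per peak) and
#'   `centers` (groups x tracks, in z-score units).
#' @export
regulatoryGroups <- function(signalMatrix, k, seed = 1L) {
  if (k > nrow(signalMatrix)) stop("'k' exceeds the number of peaks")
  z <- scale(signalMatrix)
  z[, attr(z, "scaled:scale") == 0] <- 0
  z <- z[, , drop = FALSE]
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  fit <- kmeansCluster(z, k = k, seed = seed)
  list(group = fit$cluster, centers = fit$centers)
}

#' Co-occupancy fractions of a peak set with other factors
#'
#' For each factor, the fraction of target peaks sharing at least 1 bp
#' with the factor's (merged, non-overlapping) binding regions. Factor
#' sets are reduced internally, which never changes the fraction.
#'
#' @param targetPeaks Non-empty `GRanges` of target peaks.
#' @param factorSets Named list of `GRanges`, one per factor.
#' @return data.frame with `factor`, `n_target`, `n_overlapping`,
#'   `fraction`.
#' @export
cooccupancyFractions <- function(targetPeaks, factorSets) {
  if (length(targetPeaks) == 0L) stop("empty target peak set")
  if (is.null(names(factorSets)) || any(!nzchar(names(factorSets))))
    stop("'factorSets' must be a named list")
  res <- lapply(names(factorSets), function(f) {
    merged <- GenomicRanges::reduce(factorSets[[f]], ignore.strand = TRUE)
    ov <- overlapFlags(targetPeaks, merged, minOverlap = 1L)
    data.frame(factor = f, n_target = length(targetPeaks),
               n_overlapping = sum(ov$flag), fraction = ov$fraction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Three-way partition of two factors' peak sets
#'
#' Splits the union of two binding landscapes into co-bound regions
#' (peaks of factor A overlapping factor B by >= 1 bp, reported at A's
#' coordinates), A-only peaks and B-only peaks. The three groups are
#' disjoint and jointly account for every input peak: every A peak lands
#' in `co_bound` or `a_only`, every B peak either supports a `co_bound`
#' region or lands in `b_only`.
#'
#' @param peaksA `GRanges` of the factor under study (e.g. the TF whose
#'   coordinates define the co-bound regions).
#' @param peaksB `GRanges` of the partner factor.
#' @return List of three `GRanges`: `co_bound`, `a_only`, `b_only`.
#' @export
partitionCobound <- function(peaksA, peaksB) {
  coA <- GenomicRanges::countOverlaps(peaksA, peaksB,
                                      ignore.strand = TRUE) > 0L
  coB <- GenomicRanges::countOverlaps(peaksB, peaksA,
                                      ignore.strand = TRUE) > 0L
  list(co_bound = peaksA[coA], a_only = peaksA[!coA], b_only = peaksB[!coB])
}

#' Pairwise group comparisons of a per-peak quantity
#'
#' Compares a numeric value (mark signal, nearest-gene expression, ...)
#' between all pairs of peak groups with a two-sided location test.
#' Groups with fewer than 2 values are skipped with a warning and yield
#' `NA` entries.
#'
#' @param values Numeric vector of per-peak values.
#' @param groups Factor or character vector of the same length assigning
#'   each value to a group.
#' @param test `"student_t"` or `"wilcoxon_rank_sum"` (see
#'   [twoGroupTest()]).
#' @return Symmetric matrix of two-sided p-values (diagonal `NA`).
#' @export
compareGroups <- function(values, groups,
                          test = c("student_t", "wilcoxon_rank_sum")) {
  test <- match.arg(test)
  stopifnot(length(values) == length(groups))
  groups <- as.character(groups)
  gl <- sort(unique(groups))
  p <- matrix(NA_real_, length(gl), length(gl), dimnames = list(gl, gl))
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2L]
  if (length(small))
    warning("group(s) with fewer than 2 values skipped: ",
            paste(small, collapse = ", "))
  for (i in seq_along(gl)) for (j in seq_along(gl)) {
    if (j <= i) next
    if (gl[i] %in% small || gl[j] %in% small) next
    pv <- twoGroupTest(values[groups == gl[i]], values[groups == gl[j]],
                       kind = test)
    p[i, j] <- pv
    p[j, i] <- pv
  }
  p
}
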