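# Differential TF activity from chromatin accessibility: motif sites
# inside accessible peaks, per-site accessibility fold changes, mean
# activity per TF, and significance as Cohen's D of bootstrap activity
# means against means of size-matched random site draws (the permuted
# null).

#' Scan a genome for PWM matches
#'
#' Log-odds scoring against a uniform 0.25 background (the PWM
#' probabilities already contain the pseudocount, so scores are finite).
#' Both strands are scanned; the minus strand is scored with the
#' reverse-complemented matrix so hit coordinates always refer to the
#' forward strand. A window is a hit when its score reaches
#' `minScoreFrac` times the maximum attainable score of the matrix.
#' Windows containing `N` are skipped.
#'
#' @param genome A [Biostrings::DNAStringSet] (or path to a FASTA file).
#' @param pwm A `"pwm"` object (see [newPWM()], [readJASPAR()]).
#' @param minScoreFrac Fraction of the maximum score required for a hit
#'   (default 0.8; must be in (0, 1]).
#' @return `GRanges` of binding sites with `tf_name`, `match_score`
#'   (bits) and strand.
#' @export
scanPWM <- function(genome, pwm, minScoreFrac = 0.8) {
  if (is.character(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (length(genome) == 0L || sum(Biostrings::width(genome)) == 0L)
    stop("empty genome")
  if (minScoreFrac <= 0 || minScoreFrac > 1)
    stop("'minScoreFrac' must be in (0, 1]")
  names(genome) <- sub("\\s.*$", "", names(genome))
  lo <- log2(pwm$probs / 0.25)
  L <- ncol(lo)
  lo_rc <- lo[4:1, L:1, drop = FALSE]  # reverse complement scoring matrix
  maxScore <- sum(apply(lo, 2L, max))
  threshold <- minScoreFrac * maxScore
  hits <- list()
  for (chrom in names(genome)) {
    s <- as.character(genome[[chrom]])
    n <- nchar(s)
    if (n < L) next
    codes <- match(strsplit(s, "", fixed = TRUE)[[1L]],
                   c("A", "C", "G", "T"))
    nw <- n - L + 1L
    fwd <- numeric(nw)
    rev <- numeric(nw)
    for (l in seq_len(L)) {
      cc <- codes[l:(l + nw - 1L)]
      fwd <- fwd + lo[cbind(cc, l)]
      rev <- rev + lo_rc[cbind(cc, l)]
    }
    for (str in c("+", "-")) {
      sc <- if (str == "+") fwd else rev
      ok <- which(!is.na(sc) & sc >= threshold)
      if (length(ok))
        hits[[length(hits) + 1L]] <- GenomicRanges::GRanges(
          chrom, IRanges::IRanges(start = ok, width = L), strand = str,
          tf_name = pwm$tf_name, match_score = sc[ok])
    }
  }
  if (length(hits) == 0L) {
    out <- GenomicRanges::GRanges()
    out$tf_name <- character(0)
    out$match_score <- numeric(0)
    return(out)
  }
  out <- sort(do.call(c, hits), ignore.strand = TRUE)
  out
}

#' Select (extended) binding sites inside accessible peaks
#'
#' Extends each site by `flank` bp on both sides (clipped at the
#' chromosome start) and keeps it when the extension overlaps an
#' accessibility peak by at least 1 bp. Each kept site is annotated with
#' the id of the overlapped peak; when several peaks overlap, the one
#' with the largest overlap wins, ties broken by lexicographic peak id.
#'
#' @param sites `GRanges` of binding sites (from [scanPWM()]).
#' @param peaks `GRanges` of accessibility peaks with `peak_id`.
#' @param flank Extension in bp (default 50, >= 0).
#' @return `GRanges` of extended in-peak sites with a `peak_id` column.
#' @export
selectSitesInPeaks <- function(sites, peaks, flank = 50L) {
  if (flank < 0) stop("'flank' must be >= 0")
  ext <- sites
  IRanges::ranges(ext) <- IRanges::IRanges(
    start = pmax(1L, GenomicRanges::start(sites) - flank),
    end = GenomicRanges::end(sites) + flank)
  if (length(peaks) == 0L || length(ext) == 0L) return(ext[integer(0)])
  ov <- GenomicRanges::findOverlaps(ext, peaks, ignore.strand = TRUE)
  if (length(ov) == 0L) return(ext[integer(0)])
  q <- S4Vectors::queryHits(ov)
  s <- S4Vectors::subjectHits(ov)
  w <- GenomicRanges::width(IRanges::pintersect(
    IRanges::ranges(ext)[q], IRanges::ranges(peaks)[s]))
  ord <- order(q, -w, peaks$peak_id[s])
  keep <- ord[!duplicated(q[ord])]
  out <- ext[q[keep]]
  out$peak_id <- peaks$peak_id[s[keep]]
  out
}

#' Per-site accessibility log2 fold change between two conditions
#'
#' Counts are CPM-normalized per sample; the fold change is the log2
#' ratio of (pseudocounted) condition means, late over early.
#'
#' @param siteCounts Site x sample count matrix.
#' @param design data.frame with `sample` and `day`.
#' @param dayLate,dayEarly The contrasted days.
#' @return Numeric vector of per-site log2 fold changes.
#' @export
siteLog2FC <- function(siteCounts, design, dayLate, dayEarly) {
  design <- design[match(colnames(siteCounts), design$sample), ,
                   drop = FALSE]
  late <- which(design$day == dayLate)
  early <- which(design$day == dayEarly)
  if (length(late) < 1L || length(early) < 1L)
    stop("both conditions need at least one sample")
  cpm <- cpmNormalize(siteCounts)
  log2((rowMeans(cpm[, late, drop = FALSE]) + 1) /
         (rowMeans(cpm[, early, drop = FALSE]) + 1))
}

#' Mean TF activity over the TF's binding sites
#'
#' The activity statistic: the arithmetic mean of the per-site
#' accessibility log2 fold changes at the TF's in-peak binding sites.
#' TFs with fewer than `minSites` sites are skipped (returned as `NA`)
#' with a warning, since the mean of a handful of sites is unstable.
#'
#' @param siteFCs Numeric vector of the TF's per-site log2 fold changes.
#' @param minSites Minimum number of sites (default 50).
#' @return The mean activity, or `NA` when under-populated.
#' @export
tfActivity <- function(siteFCs, minSites = 50L) {
  if (length(siteFCs) < minSites) {
    warning("fewer than ", minSites, " sites: TF skipped")
    return(NA_real_)
  }
  mean(siteFCs)
}

#' Permutation-null significance of a TF's activity
#'
#' Compares the TF's observed per-site fold-change distribution with a
#' permuted-site null: `nPerm` random draws of the same number of sites
#' from the pooled in-peak sites of all TFs, excluding the TF's own
#' sites (each draw without replacement; if the pool is smaller than the
#' site count, sampling falls back to replacement with a warning).
#' Significance is Cohen's D between the observed site values and the
#' pooled permuted-site values exceeding `dThreshold` in absolute value:
#' a standardized effect size on the scale of per-site variability, so a
#' TF is called only when its sites shift by about one SD of typical
#' accessibility change, not merely when a tiny mean shift is
#' well-measured.
#'
#' @param tfFCs Per-site fold changes of the TF (in-peak sites).
#' @param poolFCs Per-site fold changes of the pooled sites of all other
#'   TFs.
#' @param nPerm Number of permuted site draws (default 1000).
#' @param seed RNG seed.
#' @param dThreshold Cohen's D cutoff (default 1).
#' @return List with `cohens_d`, `significant`, `mean_diff` (the plain
#'   mean activity) and `n_sites`.
#' @export
permutationSignificance <- function(tfFCs, poolFCs, nPerm = 1000L,
                                    seed = 1L, dThreshold = 1) {
  n <- length(tfFCs)
  if (n < 2L) stop("need at least 2 sites")
  if (length(poolFCs) < 1L) stop("empty site pool")
  withSeed(seed, {
    if (length(poolFCs) >= n) {
      nullVals <- unlist(lapply(seq_len(nPerm), function(i)
        poolFCs[sample.int(length(poolFCs), n)]), use.names = FALSE)
    } else {
      warning("site pool smaller than the TF's site count; ",
              "null draws use replacement")
      nullVals <- poolFCs[sample.int(length(poolFCs), n * nPerm,
                                     replace = TRUE)]
    }
    d <- cohensD(tfFCs, nullVals)
    list(cohens_d = d, significant = abs(d) > dThreshold,
         mean_diff = mean(tfFCs), n_sites = n)
  })
}

#' Differential TF activity scan over all TFs
#'
#' Convenience driver: given per-site fold changes labeled by TF, computes
#' each TF's mean activity and permutation-null Cohen's D (pool = all
#' sites of the other TFs).
#'
#' @param siteFCs Numeric vector of per-site log2 fold changes for all
#'   in-peak sites.
#' @param siteTF Character vector, same length, naming each site's TF.
#' @param nPerm,seed,dThreshold,minSites See
#'   [permutationSignificance()] and [tfActivity()].
#' @return data.frame with `tf_name`, `n_sites`, `mean_diff`,
#'   `cohens_d`, `significant`; TFs under `minSites` are dropped with a
#'   warning.
#' @export
tfActivityScan <- function(siteFCs, siteTF, nPerm = 1000L, seed = 1L,
                           dThreshold = 1, minSites = 50L) {
  stopifnot(length(siteFCs) == length(siteTF))
  tfs <- sort(unique(siteTF))
  res <- list()
  for (k in seq_along(tfs)) {
    own <- siteFCs[siteTF == tfs[k]]
    if (length(own) < minSites) {
      warning("TF '", tfs[k], "' has fewer than ", minSites,
              " in-peak sites and was skipped")
      next
    }
    pool <- siteFCs[siteTF != tfs[k]]
    sig <- permutationSignificance(own, pool, nPerm = nPerm,
                                   seed = seed + k, dThreshold = dThreshold)
    res[[length(res) + 1L]] <- data.frame(
      tf_name = tfs[k], n_sites = sig$n_sites, mean_diff = sig$mean_diff,
      cohens_d = sig$cohens_d, significant = sig$significant,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Cluster TFs into groups by joint activity and expression
#'
#' Inner-joins the activity and expression matrices on TF name,
#' concatenates the columns and k-means-clusters them (default k = 8).
#' For each group the Pearson correlation between its mean activity and
#' mean expression profile is reported; anticorrelated groups (r < 0)
#' are flagged as candidate repressors, whose binding compacts chromatin
#' while their expression rises.
#'
#' @param activity TF x contrast matrix of activity values.
#' @param expression TF x contrast matrix of expression log2 fold
#'   changes.
#' @param k Number of groups (default 8).
#' @param seed RNG seed.
#' @return List with `group` (named integer vector) and `summary`
#'   (data.frame: `group`, `n`, `activity_expression_r`,
#'   `candidate_repressor`).
#' @export
clusterTFGroups <- function(activity, expression, k = 8L, seed = 1L) {
  tfs <- intersect(rownames(activity), rownames(expression))
  if (length(tfs) < k) stop("'k' exceeds the number of shared TFs")
  act <- activity[tfs, , drop = FALSE]
  expr <- expression[tfs, , drop = FALSE]
  fit <- kmeansCluster(cbind(act, expr), k = k, seed = seed)
  summ <- lapply(sort(unique(fit$cluster)), function(g) {
    rows <- names(fit$cluster)[fit$cluster == g]
    a <- colMeans(act[rows, , drop = FALSE])
    e <- colMeans(expr[rows, , drop = FALSE])
    r <- if (length(a) >= 3L && stats::var(a) > 0 && stats::var(e) > 0)
      pearsonR(a, e) else NA_real_
    data.frame(group = g, n = length(rows), activity_expression_r = r,
               candidate_repressor = !is.na(r) && r < 0)
  })
  summ <- do.call(rbind, summ)
  rownames(summ) <- NULL
  list(group = fit$cluster, summary = summ)
}
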