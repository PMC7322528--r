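# Independent brute-force oracles and small fixture builders. Oracles
# deliberately use the dumbest correct algorithm (per-basepair counting,
# exhaustive enumeration, all-pairs scans) and share no code with the
# package implementations they check.

# GRanges from BED-style 0-based half-open coordinates
grBed <- function(chrom, start0, end0, strand = "*", peak_id = NULL) {
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start0 + 1, end0),
                               strand = strand)
  if (is.null(peak_id) && length(gr))
    peak_id <- sprintf("p%03d", seq_along(gr))
  gr$peak_id <- peak_id
  gr
}

bedStart <- function(gr) GenomicRanges::start(gr) - 1
bedEnd <- function(gr) GenomicRanges::end(gr)

# exhaustive two-sided Fisher p: sum of hypergeometric outcomes no more
# probable than the observed table, at fixed margins
oracleFisherP <- function(a, b, c, d) {
  m <- a + b        # row 1 total (in-class source)
  n <- c + d        # row 2 total
  k <- a + c        # column 1 total (in-class target)
  xs <- max(0, k - n):min(m, k)
  probs <- stats::dhyper(xs, m, n, k)
  pobs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# per-basepair coverage-count consensus on a toy chromosome
oracleConsensus <- function(sets, minSets, chromLen = 10000) {
  chroms <- unique(unlist(lapply(sets, function(s)
    as.character(GenomicRanges::seqnames(s)))))
  out <- list()
  for (ch in chroms) {
    cnt <- integer(chromLen)
    for (s in sets) {
      sel <- as.character(GenomicRanges::seqnames(s)) == ch
      covered <- logical(chromLen)
      for (i in which(sel)) {
        covered[(bedStart(s)[i] + 1):bedEnd(s)[i]] <- TRUE
      }
      cnt <- cnt + covered
    }
    run <- rle(cnt >= minSets)
    ends <- cumsum(run$lengths)
    starts <- ends - run$lengths + 1
    for (j in which(run$values))
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start0 = starts[j] - 1, end0 = ends[j])
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start0 = numeric(0),
                      end0 = numeric(0)))
  df <- do.call(rbind, out)
  df[order(df$chrom, df$start0), , drop = FALSE]
}

# all-pairs nearest-TSS assignment under the package's distance rule
oracleNearestGene <- function(peaks, tss, promoterWindow = 1500) {
  res <- list()
  for (i in seq_along(peaks)) {
    ch <- as.character(GenomicRanges::seqnames(peaks))[i]
    cand <- tss[tss$chrom == ch, , drop = FALSE]
    if (nrow(cand) == 0) next
    s0 <- bedStart(peaks)[i]; e0 <- bedEnd(peaks)[i]
    d <- ifelse(cand$tss >= s0 & cand$tss < e0, 0,
                pmin(abs(cand$tss - s0), abs(cand$tss - (e0 - 1))))
    best <- min(d)
    gene <- sort(cand$gene_id[d == best])[1]
    res[[length(res) + 1L]] <- data.frame(
      peak_id = peaks$peak_id[i], gene_id = gene, distance = best,
      link_type = if (best <= promoterWindow) "promoter" else "distal",
      stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}

# per-basepair mean signal of a piecewise-constant track over a peak
oracleMeanSignal <- function(peak, track) {
  s0 <- bedStart(peak); e0 <- bedEnd(peak)
  vals <- numeric(e0 - s0)
  tch <- as.character(GenomicRanges::seqnames(track))
  pch <- as.character(GenomicRanges::seqnames(peak))
  for (j in seq_along(track)) {
    if (tch[j] != pch) next
    lo <- max(s0, bedStart(track)[j]); hi <- min(e0, bedEnd(track)[j])
    if (lo < hi) vals[(lo - s0 + 1):(hi - s0)] <- track$score[j]
  }
  mean(vals)
}

# filter-and-count contingency oracle
oracleContingency <- function(pairs, sdir, tdir, ds, dt) {
  s <- sdir[pairs$source_feature] == ds
  t <- tdir[pairs$target_feature] == dt
  c(a = sum(s & t), b = sum(s & !t), c = sum(!s & t), d = sum(!s & !t))
}

# exhaustive per-window PWM scoring on both strands
oraclePWMScan <- function(seqchar, pwm, minScoreFrac) {
  lo <- log2(pwm$probs / 0.25)
  L <- ncol(lo)
  maxS <- sum(apply(lo, 2, max))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  chars <- strsplit(seqchar, "")[[1]]
  hits <- list()
  for (i in seq_len(nchar(seqchar) - L + 1)) {
    win <- chars[i:(i + L - 1)]
    if (any(!win %in% c("A", "C", "G", "T"))) next
    sc_f <- sum(vapply(seq_len(L), function(l) lo[win[l], l], numeric(1)))
    rcwin <- rev(unname(comp[win]))
    sc_r <- sum(vapply(seq_len(L), function(l) lo[rcwin[l], l], numeric(1)))
    if (sc_f >= minScoreFrac * maxS)
      hits[[length(hits) + 1L]] <- data.frame(start0 = i - 1, strand = "+",
                                              score = sc_f)
    if (sc_r >= minScoreFrac * maxS)
      hits[[length(hits) + 1L]] <- data.frame(start0 = i - 1, strand = "-",
                                              score = sc_r)
  }
  if (!length(hits))
    return(data.frame(start0 = numeric(0), strand = character(0),
                      score = numeric(0)))
  do.call(rbind, hits)
}

# brute-force interactor-call oracle on one cell type's target/igg matrix
oracleCallStatus <- function(tg, ig, minFold = 4) {
  vapply(seq_len(nrow(tg)), function(i) {
    t <- tg[i, ]; g <- ig[i, ]
    if (!all(t > 0)) return("rejected")
    if (all(g == 0)) return("exclusive")
    if (all(g > 0) && all(t / g >= minFold)) return("enriched")
    "rejected"
  }, character(1))
}

randomPeaks <- function(n, chromLen = 10000, chrom = "chr1",
                        maxWidth = 500) {
  s0 <- sample.int(chromLen - maxWidth, n, replace = TRUE)
  w <- sample.int(maxWidth - 1, n, replace = TRUE) + 1
  grBed(chrom, s0, pmin(s0 + w, chromLen))
}

adjustedRandIndex <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- b * cc / choose(n, 2)
  maxidx <- (b + cc) / 2
  (a - expected) / (maxidx - expected)
}

# The study-style experimental design used in several tests: adjacent
# contrasts on the RNA/ATAC day grid 0/4/8/12 and on the denser protein
# grid sampled every two days up to day 10.
paperContrasts <- function() {
  rbind(
    data.frame(layer = "rna", day_late = c(4, 8, 12),
               day_early = c(0, 4, 8)),
    data.frame(layer = "atac", day_late = c(4, 8, 12),
               day_early = c(0, 4, 8)),
    data.frame(layer = "protein", day_late = c(4, 8, 10),
               day_early = c(0, 4, 8))
  )
}
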