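# Peak manipulation and peak-to-gene assignment. All functions take and
# return GRanges; coordinate arithmetic is stated in BED (0-based
# half-open) terms in the docs because that is how the conventions are
# defined, and converted internally.

#' Extend peaks symmetrically around their midpoint
#'
#' Each peak is replaced by the fixed-width window `[mid - flank,
#' mid + flank)` (BED coordinates) where `mid = floor((start + end) / 2)`.
#' With the default `flank = 250` every output peak is 500 bp wide, the
#' standard width used for ChIP peak harmonization. Windows running past
#' the chromosome start are clipped at 0 and may be narrower.
#'
#' @param peaks `GRanges` of peaks.
#' @param flank Extension in bp on each side of the midpoint (> 0).
#' @return `GRanges` with the same metadata columns and new coordinates.
#' @export
extendAroundMidpoint <- function(peaks, flank = 250L) {
  if (flank <= 0) stop("'flank' must be > 0")
  start0 <- GenomicRanges::start(peaks) - 1
  end0 <- GenomicRanges::end(peaks)
  mid0 <- floor((start0 + end0) / 2)
  new_start0 <- pmax(0, mid0 - flank)
  new_end0 <- mid0 + flank
  out <- peaks
  IRanges::ranges(out) <- IRanges::IRanges(start = new_start0 + 1,
                                           end = new_end0)
  out
}

#' Consensus regions supported by a minimum number of peak sets
#'
#' Counts, at every base, how many distinct input sets have coverage
#' (overlapping peaks within one set count once) and returns the maximal
#' intervals where that count is at least `minSets`. This is the
#' "present in at least two samples" consensus rule.
#'
#' @param peakSets A list of `GRanges`.
#' @param minSets Minimum number of supporting sets (default 2).
#' @return `GRanges` of consensus intervals (no metadata).
#' @export
mergeConsensus <- function(peakSets, minSets = 2L) {
  if (minSets > length(peakSets))
    stop("'minSets' exceeds the number of peak sets")
  lev <- unique(unlist(lapply(peakSets, function(s)
    as.character(GenomicRanges::seqnames(s)))))
  if (length(lev) == 0L) return(GenomicRanges::GRanges())
  # common seqlengths so that per-set coverage vectors align exactly
  lens <- vapply(lev, function(ch) max(unlist(lapply(peakSets, function(s) {
    sel <- as.character(GenomicRanges::seqnames(s)) == ch
    if (any(sel)) max(GenomicRanges::end(s)[sel]) else 0L
  }))), numeric(1))
  covs <- lapply(peakSets, function(s) {
    s <- GenomicRanges::reduce(s, ignore.strand = TRUE)
    GenomeInfoDb::seqlevels(s) <- lev
    GenomeInfoDb::seqlengths(s) <- lens
    GenomicRanges::coverage(s)
  })
  total <- Reduce(`+`, covs)
  hits <- IRanges::slice(total, lower = minSets, rangesOnly = TRUE)
  GenomicRanges::GRanges(hits)
}

#' Flag peaks overlapping a reference interval set
#'
#' @param peaks `GRanges` to test (must be non-empty).
#' @param reference `GRanges` of reference intervals.
#' @param minOverlap Minimum shared bases to count as overlap (>= 1).
#' @return List with `flag` (logical per peak) and `fraction`
#'   (flagged / total).
#' @export
overlapFlags <- function(peaks, reference, minOverlap = 1L) {
  if (length(peaks) == 0L)
    stop("'peaks' is empty: overlap fraction undefined")
  if (minOverlap < 1L) stop("'minOverlap' must be >= 1")
  flag <- GenomicRanges::countOverlaps(
    peaks, reference, minoverlap = minOverlap, ignore.strand = TRUE) > 0L
  list(flag = flag, fraction = mean(flag))
}

#' Distance from peaks to a point position
#'
#' Distance convention used throughout: 0 when the point falls inside the
#' peak, otherwise the distance to the nearest *included* base, i.e.
#' `min(|pos - start|, |pos - (end - 1)|)` in BED coordinates.
#' @noRd
pointPeakDistance <- function(start0, end0, pos0) {
  ifelse(pos0 >= start0 & pos0 < end0, 0,
         pmin(abs(pos0 - start0), abs(pos0 - (end0 - 1))))
}

#' Assign peaks to their nearest gene TSS
#'
#' Every peak is linked to the gene with the nearest TSS on the same
#' chromosome. Links at a distance of at most `promoterWindow` are typed
#' `promoter`, all others `distal`. Ties (equidistant TSS) are broken by
#' the lexicographically smaller `gene_id`. Additionally, for every gene
#' the single closest promoter-type peak (if any) is reported: this is
#' the "one promoter peak per gene, no further than 1.5 kb" selection
#' used when pairing accessibility with expression.
#'
#' Peaks on chromosomes absent from the TSS table get no link and raise a
#' warning.
#'
#' @param peaks `GRanges` with `peak_id`.
#' @param tss data.frame with `gene_id`, `chrom`, `tss` (0-based),
#'   `strand` (see [readTSS()]).
#' @param promoterWindow Promoter distance cutoff in bp (default 1500).
#' @return List with `links` (data.frame `peak_id`, `gene_id`,
#'   `link_type`, `distance`) and `promoterPeaks` (data.frame `gene_id`,
#'   `peak_id`, `distance`, one row per gene that has a promoter peak).
#' @export
assignPeaksToGenes <- function(peaks, tss, promoterWindow = 1500L) {
  if (nrow(tss) == 0L) stop("TSS table is empty")
  chroms <- as.character(GenomicRanges::seqnames(peaks))
  missing_chrom <- !chroms %in% tss$chrom
  if (any(missing_chrom))
    warning(sum(missing_chrom),
            " peak(s) on chromosomes absent from the TSS table were not linked")
  links <- vector("list", length(peaks))
  start0 <- GenomicRanges::start(peaks) - 1
  end0 <- GenomicRanges::end(peaks)
  bychrom <- split(seq_len(nrow(tss)), tss$chrom)
  for (i in which(!missing_chrom)) {
    idx <- bychrom[[chroms[i]]]
    d <- pointPeakDistance(start0[i], end0[i], tss$tss[idx])
    dmin <- min(d)
    cand <- tss$gene_id[idx[d == dmin]]
    links[[i]] <- data.frame(
      peak_id = peaks$peak_id[i],
      gene_id = min(cand),
      link_type = if (dmin <= promoterWindow) "promoter" else "distal",
      distance = dmin,
      stringsAsFactors = FALSE
    )
  }
  links <- do.call(rbind, links)
  if (is.null(links))
    links <- data.frame(peak_id = character(0), gene_id = character(0),
                        link_type = character(0), distance = numeric(0))
  prom <- links[links$link_type == "promoter", , drop = FALSE]
  if (nrow(prom)) {
    prom <- prom[order(prom$gene_id, prom$distance, prom$peak_id), ]
    prom <- prom[!duplicated(prom$gene_id),
                 c("gene_id", "peak_id", "distance")]
    rownames(prom) <- NULL
  } else {
    prom <- data.frame(gene_id = character(0), peak_id = character(0),
                       distance = numeric(0))
  }
  rownames(links) <- NULL
  list(links = links, promoterPeaks = prom)
}

#' Annotate peaks by genomic category
#'
#' Classifies each peak as `promoter`, `exon`, `intron` or
#' `distal_intergenic` with that precedence: a peak within
#' `promoterWindow` bp of any TSS is a promoter peak no matter what else
#' it overlaps; otherwise exon overlap wins over gene-span (intron)
#' overlap; peaks outside all gene spans are distal intergenic.
#'
#' @param peaks `GRanges` of peaks.
#' @param geneModel List with `genes`, `exons` (`GRanges`) and `tss`
#'   (data.frame), as from [readGeneModel()].
#' @param promoterWindow Half-width of the promoter window around the TSS
#'   in bp (default 1000).
#' @return Character vector of categories, one per peak.
#' @export
annotatePeakCategory <- function(peaks, geneModel, promoterWindow = 1000L) {
  tss <- geneModel$tss
  p1 <- tss$tss + 1  # 1-based point
  promoters <- GenomicRanges::GRanges(
    tss$chrom,
    IRanges::IRanges(start = pmax(1, p1 - promoterWindow),
                     end = p1 + promoterWindow))
  inProm <- GenomicRanges::countOverlaps(peaks, promoters,
                                         ignore.strand = TRUE) > 0L
  inExon <- GenomicRanges::countOverlaps(peaks, geneModel$exons,
                                         ignore.strand = TRUE) > 0L
  inGene <- GenomicRanges::countOverlaps(peaks, geneModel$genes,
                                         ignore.strand = TRUE) > 0L
  out <- rep("distal_intergenic", length(peaks))
  out[inGene] <- "intron"
  out[inExon] <- "exon"
  out[inProm] <- "promoter"
  out
}
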