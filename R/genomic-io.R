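# Readers and writers for the plain-text genomic formats the pipeline
# consumes. Coordinates are BED-style 0-based half-open on disk and
# standard Bioconductor 1-based closed GRanges in memory; the conversion
# happens here and nowhere else.

#' Read a peak file (BED6 or ENCODE narrowPeak)
#'
#' Parses peaks into a [GenomicRanges::GRanges] with metadata columns
#' `peak_id`, `score` and `summit` (absolute 0-based summit position for
#' narrowPeak, `NA` otherwise). Malformed lines raise an error naming the
#' offending line number; negative coordinates and empty intervals are
#' rejected. A missing strand field is stored as `"*"`.
#'
#' @param path Path to the file.
#' @param format `"bed6"` or `"narrowPeak"`.
#' @return A `GRanges` of peaks.
#' @export
readPeaks <- function(path, format = c("bed6", "narrowPeak")) {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(emptyPeaks())
  ncol_needed <- if (format == "bed6") 6L else 10L
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < ncol_needed)
  if (length(bad))
    stop("malformed ", format, " line ", bad[1L], " in '", path,
         "': expected ", ncol_needed, " fields, found ", nf[bad[1L]])
  m <- do.call(rbind, lapply(fields, `[`, seq_len(ncol_needed)))
  start0 <- suppressWarnings(as.numeric(m[, 2L]))
  end0 <- suppressWarnings(as.numeric(m[, 3L]))
  badnum <- which(is.na(start0) | is.na(end0))
  if (length(badnum))
    stop("malformed ", format, " line ", badnum[1L], " in '", path,
         "': non-numeric coordinates")
  if (any(start0 < 0))
    stop("negative coordinate on line ", which(start0 < 0)[1L],
         " in '", path, "'")
  if (any(end0 <= start0))
    stop("empty or inverted interval on line ",
         which(end0 <= start0)[1L], " in '", path, "'")
  strand <- m[, 6L]
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = m[, 1L],
    ranges = IRanges::IRanges(start = start0 + 1, end = end0),
    strand = strand
  )
  gr$peak_id <- m[, 4L]
  gr$score <- suppressWarnings(as.numeric(m[, 5L]))
  if (format == "narrowPeak") {
    offset <- suppressWarnings(as.numeric(m[, 10L]))
    gr$score <- suppressWarnings(as.numeric(m[, 7L]))  # signalValue
    gr$summit <- ifelse(offset < 0, NA_real_, start0 + offset)
    if (any(!is.na(gr$summit) &
            (gr$summit < start0 | gr$summit >= end0)))
      stop("summit outside its peak in '", path, "'")
  } else {
    gr$summit <- NA_real_
  }
  if (anyDuplicated(gr$peak_id))
    stop("duplicate peak_id in '", path, "'")
  gr
}

#' @noRd
emptyPeaks <- function() {
  gr <- GenomicRanges::GRanges()
  gr$peak_id <- character(0)
  gr$score <- numeric(0)
  gr$summit <- numeric(0)
  gr
}

#' Write peaks as BED6 or narrowPeak
#'
#' Inverse of [readPeaks()]: coordinates are emitted 0-based half-open.
#' For narrowPeak output the summit is written as a relative offset
#' (column 10, `-1` when absent) and the score goes to the signalValue
#' column.
#'
#' @param peaks `GRanges` with `peak_id`, `score` and optionally `summit`.
#' @param path Output path.
#' @param format `"bed6"` or `"narrowPeak"`.
#' @return Invisibly, `path`.
#' @export
writePeaks <- function(peaks, path, format = c("bed6", "narrowPeak")) {
  format <- match.arg(format)
  start0 <- GenomicRanges::start(peaks) - 1
  end0 <- GenomicRanges::end(peaks)
  strand <- as.character(GenomicRanges::strand(peaks))
  strand[strand == "*"] <- "."
  score <- if (is.null(peaks$score)) rep(0, length(peaks)) else peaks$score
  if (format == "bed6") {
    out <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                   as.character(GenomicRanges::seqnames(peaks)),
                   as.integer(start0), as.integer(end0),
                   peaks$peak_id, format(score, trim = TRUE), strand)
  } else {
    summit <- if (is.null(peaks$summit)) rep(NA_real_, length(peaks)) else peaks$summit
    offset <- ifelse(is.na(summit), -1, summit - start0)
    out <- sprintf("%s\t%d\t%d\t%s\t0\t%s\t%s\t-1\t-1\t%d",
                   as.character(GenomicRanges::seqnames(peaks)),
                   as.integer(start0), as.integer(end0),
                   peaks$peak_id, strand, format(score, trim = TRUE),
                   as.integer(offset))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a TSS table
#'
#' Tab-separated file with header `gene_id  chrom  tss  strand`; `tss` is
#' a 0-based position. Returns a data.frame with those columns.
#'
#' @param path Path to the TSV.
#' @return data.frame with columns `gene_id`, `chrom`, `tss`, `strand`.
#' @export
readTSS <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "tss", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("TSS table misses column(s): ", paste(miss, collapse = ", "))
  if (any(df$tss < 0)) stop("negative TSS coordinate")
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in TSS table")
  df[need]
}

#' Write a TSS table
#' @param tss data.frame as returned by [readTSS()].
#' @param path Output path.
#' @export
writeTSS <- function(tss, path) {
  utils::write.table(tss, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a minimal gene/exon model
#'
#' Tab-separated file with header
#' `chrom  start  end  strand  gene_id  feature` (0-based half-open
#' coordinates; `feature` is `gene` or `exon`). TSS positions are derived
#' from the gene spans: `start` for `+` strand genes and `end - 1` for
#' `-` strand genes.
#'
#' @param path Path to the TSV.
#' @return A list with `genes` and `exons` (`GRanges` with `gene_id`) and
#'   `tss` (data.frame as from [readTSS()]).
#' @export
readGeneModel <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "strand", "gene_id", "feature")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("gene model misses column(s): ", paste(miss, collapse = ", "))
  toGR <- function(d) {
    gr <- GenomicRanges::GRanges(
      d$chrom, IRanges::IRanges(d$start + 1, d$end), strand = d$strand)
    gr$gene_id <- d$gene_id
    gr
  }
  genes <- toGR(df[df$feature == "gene", ])
  exons <- toGR(df[df$feature == "exon", ])
  gd <- df[df$feature == "gene", ]
  tss <- data.frame(
    gene_id = gd$gene_id,
    chrom = gd$chrom,
    tss = ifelse(gd$strand == "-", gd$end - 1, gd$start),
    strand = gd$strand,
    stringsAsFactors = FALSE
  )
  list(genes = genes, exons = exons, tss = tss)
}

#' Write a minimal gene/exon model
#' @param model List with `genes` and `exons` `GRanges` (see
#'   [readGeneModel()]).
#' @param path Output path.
#' @export
writeGeneModel <- function(model, path) {
  row <- function(gr, feature) {
    if (length(gr) == 0L) return(NULL)
    data.frame(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      gene_id = gr$gene_id,
      feature = feature,
      stringsAsFactors = FALSE
    )
  }
  df <- rbind(row(model$genes, "gene"), row(model$exons, "exon"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a bedGraph signal track
#'
#' Four-column bedGraph (chrom, 0-based start, exclusive end, value) into
#' a `GRanges` with a `score` column. Source intervals must not overlap
#' (piecewise-constant semantics); overlapping inputs are an error.
#'
#' @param path Path to the bedGraph file.
#' @return `GRanges` with numeric `score`.
#' @export
readBedGraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track")]
  if (length(lines) == 0L) {
    gr <- GenomicRanges::GRanges()
    gr$score <- numeric(0)
    return(gr)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4L))
    stop("malformed bedGraph line ", which(nf < 4L)[1L], " in '", path, "'")
  m <- do.call(rbind, lapply(fields, `[`, 1:4))
  start0 <- as.numeric(m[, 2L]); end0 <- as.numeric(m[, 3L])
  val <- as.numeric(m[, 4L])
  if (anyNA(start0) || anyNA(end0) || anyNA(val))
    stop("non-numeric field in bedGraph '", path, "'")
  if (any(start0 < 0)) stop("negative coordinate in bedGraph '", path, "'")
  gr <- GenomicRanges::GRanges(m[, 1L], IRanges::IRanges(start0 + 1, end0))
  gr$score <- val
  if (sum(GenomicRanges::width(GenomicRanges::reduce(gr))) <
      sum(GenomicRanges::width(gr)))
    stop("overlapping intervals in bedGraph '", path, "'")
  gr
}

#' Write a bedGraph signal track
#' @param track `GRanges` with a `score` column.
#' @param path Output path.
#' @export
writeBedGraph <- function(track, path) {
  out <- sprintf("%s\t%d\t%d\t%s",
                 as.character(GenomicRanges::seqnames(track)),
                 as.integer(GenomicRanges::start(track) - 1),
                 as.integer(GenomicRanges::end(track)),
                 format(track$score, trim = TRUE))
  writeLines(out, path)
  invisible(path)
}

#' Read JASPAR-style position frequency matrices
#'
#' Parses the JASPAR PFM text dialects (`>ID NAME` header followed by
#' four rows of counts for A, C, G, T, with or without the
#' `A [ ... ]` bracket decoration). Counts are converted to column-wise
#' base probabilities with a pseudocount spread over the four bases.
#'
#' @param path Path to the PFM file.
#' @param pseudocount Total pseudocount added per column (default 1).
#' @return A named list of PWM objects; each is a list with `tf_name`,
#'   `probs` (4 x L matrix, rows A/C/G/T, columns summing to 1) and
#'   `pseudocount`.
#' @export
readJASPAR <- function(path, pseudocount = 1) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  heads <- which(startsWith(lines, ">"))
  if (length(heads) == 0L) stop("no PFM records in '", path, "'")
  out <- list()
  for (i in seq_along(heads)) {
    h <- heads[i]
    end <- if (i < length(heads)) heads[i + 1L] - 1L else length(lines)
    body <- lines[(h + 1L):end]
    if (length(body) < 4L)
      stop("PFM record '", lines[h], "' has fewer than 4 matrix rows")
    hdr <- sub("^>", "", lines[h])
    toks <- strsplit(hdr, "[ \t]+")[[1L]]
    name <- if (length(toks) >= 2L) toks[2L] else toks[1L]
    rows <- lapply(body[1:4], function(l) {
      l <- gsub("^[ACGTacgt][ \t:|]*", "", l)
      l <- gsub("[][]", " ", l)
      as.numeric(strsplit(trimws(l), "[ \t]+")[[1L]])
    })
    L <- unique(lengths(rows))
    if (length(L) != 1L)
      stop("ragged PFM matrix for '", name, "'")
    counts <- do.call(rbind, rows)
    rownames(counts) <- c("A", "C", "G", "T")
    probs <- sweep(counts + pseudocount / 4, 2L,
                   colSums(counts) + pseudocount, "/")
    out[[name]] <- newPWM(name, probs, pseudocount)
  }
  out
}

#' Construct a position weight matrix object
#'
#' @param tf_name Factor name.
#' @param probs 4 x L matrix of base probabilities (rows A, C, G, T;
#'   every column must sum to 1 within 1e-6) with L >= 4.
#' @param pseudocount Pseudocount that was used to regularize the counts.
#' @return An object of class `"pwm"`.
#' @export
newPWM <- function(tf_name, probs, pseudocount = 1) {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4L) stop("'probs' must have 4 rows (A, C, G, T)")
  if (ncol(probs) < 4L) stop("motif length must be >= 4")
  if (any(abs(colSums(probs) - 1) > 1e-6))
    stop("PWM columns must sum to 1")
  rownames(probs) <- c("A", "C", "G", "T")
  structure(list(tf_name = tf_name, probs = probs,
                 pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM", x$tf_name, "length", ncol(x$probs), "\n")
  invisible(x)
}

#' Write PWMs in JASPAR bracket format (probabilities scaled to counts)
#' @param pwms Named list of `"pwm"` objects.
#' @param path Output path.
#' @param nsites Scale factor turning probabilities into pseudo-counts.
#' @export
writeJASPAR <- function(pwms, path, nsites = 100) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$tf_name, " ", p$tf_name), con)
    cnt <- round(p$probs * nsites, 3)
    for (b in c("A", "C", "G", "T")) {
      writeLines(sprintf("%s [ %s ]", b,
                         paste(format(cnt[b, ], trim = TRUE),
                               collapse = " ")), con)
    }
  }
  invisible(path)
}
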