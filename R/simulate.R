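# Seeded synthetic-data generators. They emulate, at toy scale, every
# input the pipeline consumes -- a random genome with genes and
# promoter/distal peaks, negative-binomial ATAC/RNA counts and log-normal
# protein intensities with planted, lagged cross-layer coupling, ChIP
# peak sets with planted regulatory archetypes and co-binding effects,
# and iBAQ-like pull-down tables -- together with the planted truth, so
# every stage is testable without external downloads. Each generator is a
# pure function of its config: a fixed seed gives byte-identical output.

#' Simulation configuration
#'
#' Bundles and validates all generator parameters. Defaults describe a
#' toy differentiation time course that runs in seconds: 2 chromosomes of
#' 200 kb, 100 genes, 400 accessibility peaks, RNA/ATAC sampled at days
#' 0/4/8/12 and protein every 2 days to day 10, negative-binomial
#' dispersion 0.1 and log-normal library sizes with CV 0.2 (effects of
#' |log2FC| 1.5 are then reliably detectable at the default replicate
#' numbers, mirroring the replicate scale of a typical differentiation
#' study: 4 ATAC, 5 RNA, 2 proteomics replicates).
#'
#' @param seed Integer master seed.
#' @param nChroms,chromLength Toy genome shape.
#' @param nGenes,nPeaks,promoterFraction Gene count, peak count, and the
#'   fraction of peaks planted within 1.5 kb of a TSS.
#' @param days Named list of time grids per layer (`atac`, `rna`,
#'   `protein`).
#' @param replicates Named list of replicate counts per layer.
#' @param dispersion Negative-binomial dispersion (1/size).
#' @param libSizeCV Coefficient of variation of library-size factors.
#' @param coupling List: `p_couple` (conditional probability that a
#'   source-layer change propagates), `lag` (days), `frac_changing`
#'   (fraction of genes with a planted RNA change), `effect` (planted
#'   |log2FC|, >= 1).
#' @param chip List: `n_peaks`, `noise_sd` (per-mark signal SD around the
#'   archetype means), `frac_cobound`, `mark_shift`, `expression_shift`,
#'   `jitter` (bp edge jitter of replicate peak sets), `n_replicates`.
#' @param pulldown List: `n_exclusive`, `n_enriched`, `n_background`,
#'   `min_fold`, `rho` (planted association-rate/expression correlation),
#'   `noise` (per-replicate IgG contamination probability).
#' @return A list of class `"SimConfig"`.
#' @export
simConfig <- function(seed = 1L,
                      nChroms = 2L, chromLength = 200000L,
                      nGenes = 100L, nPeaks = 400L,
                      promoterFraction = 0.5,
                      days = list(atac = c(0, 4, 8, 12),
                                  rna = c(0, 4, 8, 12),
                                  protein = seq(0, 10, by = 2)),
                      replicates = list(atac = 4L, rna = 5L, protein = 2L),
                      dispersion = 0.1, libSizeCV = 0.2,
                      coupling = list(p_couple = 0.8, lag = 4,
                                      frac_changing = 0.5, effect = 1.5),
                      chip = list(n_peaks = 200L, noise_sd = 0.1,
                                  frac_cobound = 0.3, mark_shift = 2,
                                  expression_shift = 2, jitter = 20L,
                                  n_replicates = 3L),
                      pulldown = list(n_exclusive = 30L, n_enriched = 30L,
                                      n_background = 140L, min_fold = 4,
                                      rho = 0.7, noise = 0)) {
  stopifnot(chromLength >= 10000, nChroms >= 1, nGenes >= 1,
            promoterFraction >= 0, promoterFraction <= 1)
  checkProb(coupling$p_couple, "p_couple")
  checkProb(coupling$frac_changing, "frac_changing")
  checkProb(chip$frac_cobound, "frac_cobound")
  checkProb(pulldown$noise, "pulldown noise")
  if (coupling$lag < 0) stop("'lag' must be >= 0")
  if (coupling$effect < 1) stop("planted effect must be >= 1 log2 unit")
  if (is.unsorted(days$rna) || is.unsorted(days$atac) ||
      is.unsorted(days$protein))
    stop("time grids must be sorted")
  structure(list(seed = seed, nChroms = nChroms,
                 chromLength = chromLength, nGenes = nGenes,
                 nPeaks = nPeaks, promoterFraction = promoterFraction,
                 days = days, replicates = replicates,
                 dispersion = dispersion, libSizeCV = libSizeCV,
                 coupling = coupling, chip = chip, pulldown = pulldown),
            class = "SimConfig")
}

#' @export
print.SimConfig <- function(x, ...) {
  cat("SimConfig: seed", x$seed, "|", x$nChroms, "chrom x",
      x$chromLength, "bp |", x$nGenes, "genes |", x$nPeaks, "peaks\n")
  invisible(x)
}

#' Generate the toy genome
#'
#' Uniform-random ACGT sequence; genes tiled with regular spacing and a
#' small jitter (error when the chromosomes cannot fit the requested gene
#' count at a minimum 4 kb spacing); a promoter peak within 1.5 kb of the
#' TSS for `promoterFraction` of the genes; distal peaks placed at least
#' 2.5 kb away from every TSS. Deterministic for a fixed seed.
#'
#' @param config A [simConfig()].
#' @return List with `genome` (`DNAStringSet`), `tss` (data.frame),
#'   `genes`, `exons`, `peaks` (`GRanges`; peaks carry `peak_id`, `type`
#'   and, for promoter peaks, the planted `gene_id`).
#' @export
generateGenome <- function(config) {
  withSeed(config$seed, {
    gpc <- ceiling(config$nGenes / config$nChroms)
    # genes occupy the first half of each chromosome; the remainder is a
    # gene desert where distal peaks can live far from any TSS
    spacing <- floor(0.5 * config$chromLength / (gpc + 1))
    if (spacing < 1900)
      stop("infeasible gene tiling: need >= 1.9 kb spacing, have ",
           spacing)
    chroms <- paste0("chr", seq_len(config$nChroms))
    seqs <- Biostrings::DNAStringSet(vapply(chroms, function(ch)
      paste(sample(c("A", "C", "G", "T"), config$chromLength,
                   replace = TRUE), collapse = ""), character(1)))
    names(seqs) <- chroms

    genes <- list(); tssrows <- list()
    gi <- 0L
    for (ch in chroms) {
      for (g in seq_len(gpc)) {
        gi <- gi + 1L
        if (gi > config$nGenes) break
        tss0 <- g * spacing + sample(-300:300, 1L)
        len <- sample(1500:2800, 1L)
        strand <- sample(c("+", "-"), 1L)
        if (strand == "+") {
          s0 <- tss0; e0 <- min(tss0 + len, config$chromLength)
        } else {
          s0 <- max(0, tss0 - len + 1); e0 <- tss0 + 1
        }
        gene_id <- sprintf("g%03d", gi)
        genes[[gi]] <- data.frame(chrom = ch, start = s0, end = e0,
                                  strand = strand, gene_id = gene_id,
                                  stringsAsFactors = FALSE)
        tssrows[[gi]] <- data.frame(gene_id = gene_id, chrom = ch,
                                    tss = tss0, strand = strand,
                                    stringsAsFactors = FALSE)
      }
    }
    gdf <- do.call(rbind, genes)
    tss <- do.call(rbind, tssrows)
    geneGR <- GenomicRanges::GRanges(
      gdf$chrom, IRanges::IRanges(gdf$start + 1, gdf$end),
      strand = gdf$strand, gene_id = gdf$gene_id)
    # two exons per gene: one at each end of the span
    ex1 <- GenomicRanges::resize(geneGR, width = 200, fix = "start")
    ex2 <- GenomicRanges::resize(geneGR, width = 300, fix = "end")
    exons <- c(ex1, ex2)

    nProm <- min(round(config$nPeaks * config$promoterFraction),
                 config$nGenes)
    promGenes <- sort(sample(seq_len(nrow(tss)), nProm))
    width <- 300L
    promRows <- lapply(promGenes, function(i) {
      center <- tss$tss[i] + sample(-500:500, 1L)
      s0 <- max(0, center - width %/% 2)
      data.frame(chrom = tss$chrom[i], start = s0, end = s0 + width,
                 gene_id = tss$gene_id[i], type = "promoter",
                 stringsAsFactors = FALSE)
    })
    nDist <- config$nPeaks - nProm
    tssByChrom <- split(tss$tss, tss$chrom)
    placed <- lapply(stats::setNames(chroms, chroms), function(ch) {
      i <- which(vapply(promRows, function(r) r$chrom, character(1)) == ch)
      vapply(promRows[i], function(r) r$start, numeric(1))
    })
    distRows <- list()
    tries <- 0L
    while (length(distRows) < nDist) {
      tries <- tries + 1L
      if (tries > 200L * nDist) stop("infeasible distal peak placement")
      ch <- sample(chroms, 1L)
      s0 <- sample.int(config$chromLength - width, 1L)
      center <- s0 + width %/% 2
      if (min(abs(tssByChrom[[ch]] - center)) < 1700) next
      # keep peaks separated so they never touch each other
      if (length(placed[[ch]]) &&
          min(abs(placed[[ch]] - s0)) < 400) next
      placed[[ch]] <- c(placed[[ch]], s0)
      distRows[[length(distRows) + 1L]] <-
        data.frame(chrom = ch, start = s0, end = s0 + width,
                   gene_id = NA_character_, type = "distal",
                   stringsAsFactors = FALSE)
    }
    pdf <- rbind(do.call(rbind, promRows), do.call(rbind, distRows))
    peaks <- GenomicRanges::GRanges(
      pdf$chrom, IRanges::IRanges(pdf$start + 1, pdf$end))
    peaks$peak_id <- sprintf("peak%04d", seq_len(nrow(pdf)))
    peaks$score <- 0
    peaks$summit <- NA_real_
    peaks$type <- pdf$type
    peaks$gene_id <- pdf$gene_id
    list(genome = seqs, tss = tss, genes = geneGR, exons = exons,
         peaks = peaks)
  })
}

#' @noRd
libFactors <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate the multi-omics count and intensity matrices
#'
#' RNA and ATAC counts are negative-binomial around log-normal baselines;
#' protein intensities are log-normal. Planted structure: a fraction of
#' genes changes on the RNA level (direction random, |log2FC| =
#' `coupling$effect`) at a random change day; with probability
#' `p_couple` the gene's promoter peak loses/gains accessibility `lag`
#' days *before* the RNA change, and with probability `p_couple` the
#' protein follows `lag` days *after* it -- the chromatin -> RNA ->
#' protein cascade. All planted labels are returned as the truth set.
#'
#' @param config A [simConfig()].
#' @param genome Result of [generateGenome()].
#' @return List of three [SummarizedExperiment::SummarizedExperiment]s
#'   (`atac`, `rna`, `protein`; assay `counts` or `intensities`, colData
#'   with `sample`, `day`, `replicate`) and `truth` (per-gene data.frame:
#'   change day, direction, coupling flags, promoter `peak_id`).
#' @export
generateMultiomics <- function(config, genome) {
  withSeed(config$seed + 1L, {
    genesv <- genome$tss$gene_id
    nG <- length(genesv)
    cp <- config$coupling
    changing <- stats::runif(nG) < cp$frac_changing
    changeDay <- ifelse(changing,
                        sample(config$days$rna[-1], nG, replace = TRUE),
                        NA)
    dir <- ifelse(changing, sample(c(1, -1), nG, replace = TRUE), 0)
    promPeak <- genome$peaks$peak_id[match(genesv, genome$peaks$gene_id)]
    atacCoupled <- changing & !is.na(promPeak) &
      stats::runif(nG) < cp$p_couple
    protCoupled <- changing & stats::runif(nG) < cp$p_couple
    atacDay <- ifelse(atacCoupled & changeDay - cp$lag >= 0,
                      changeDay - cp$lag, NA)
    protDay <- ifelse(protCoupled &
                        changeDay + cp$lag <= max(config$days$protein),
                      changeDay + cp$lag, NA)

    makeDesign <- function(days, reps, prefix) {
      d <- expand.grid(replicate = seq_len(reps), day = days)
      d$sample <- sprintf("%s_d%02d_r%d", prefix, d$day, d$replicate)
      d[c("sample", "day", "replicate")]
    }
    nbCounts <- function(base, fcmat, design) {
      m <- matrix(0L, nrow = length(base), ncol = nrow(design))
      lf <- libFactors(nrow(design), config$libSizeCV)
      for (j in seq_len(nrow(design))) {
        mu <- base * 2^fcmat[, as.character(design$day[j])] * lf[j]
        m[, j] <- stats::rnbinom(length(base), mu = mu,
                                 size = 1 / config$dispersion)
      }
      colnames(m) <- design$sample
      m
    }
    stepFC <- function(n, days, changeAt, dir, effect) {
      fc <- matrix(0, n, length(days), dimnames = list(NULL, days))
      for (j in seq_along(days)) {
        on <- !is.na(changeAt) & days[j] >= changeAt
        fc[on, j] <- dir[on] * effect
      }
      fc
    }

    rnaDesign <- makeDesign(config$days$rna, config$replicates$rna, "rna")
    rnaFC <- stepFC(nG, config$days$rna, changeDay, dir, cp$effect)
    rnaBase <- stats::rlnorm(nG, meanlog = log(500), sdlog = 1)
    rnaCounts <- nbCounts(rnaBase, rnaFC, rnaDesign)
    rownames(rnaCounts) <- genesv

    atacDesign <- makeDesign(config$days$atac, config$replicates$atac,
                             "atac")
    peakGene <- match(genome$peaks$gene_id, genesv)
    nP <- length(genome$peaks)
    peakChangeDay <- rep(NA_real_, nP)
    peakDir <- rep(0, nP)
    hasGene <- !is.na(peakGene)
    peakChangeDay[hasGene] <- atacDay[peakGene[hasGene]]
    peakDir[hasGene] <- dir[peakGene[hasGene]]
    atacFC <- stepFC(nP, config$days$atac, peakChangeDay, peakDir,
                     cp$effect)
    atacBase <- stats::rlnorm(nP, meanlog = log(200), sdlog = 0.8)
    atacCounts <- nbCounts(atacBase, atacFC, atacDesign)
    rownames(atacCounts) <- genome$peaks$peak_id

    protDesign <- makeDesign(config$days$protein,
                             config$replicates$protein, "prot")
    protFC <- stepFC(nG, config$days$protein, protDay, dir, cp$effect)
    protBase <- stats::rnorm(nG, mean = 20, sd = 2)  # log2 scale
    protInt <- matrix(0, nG, nrow(protDesign),
                      dimnames = list(genesv, protDesign$sample))
    for (j in seq_len(nrow(protDesign))) {
      lg <- protBase + protFC[, as.character(protDesign$day[j])] +
        stats::rnorm(nG, sd = 0.25)
      protInt[, j] <- 2^lg
    }

    se <- function(m, design, assayName) {
      SummarizedExperiment::SummarizedExperiment(
        assays = stats::setNames(list(m), assayName),
        colData = S4Vectors::DataFrame(design, row.names = design$sample))
    }
    truth <- data.frame(
      gene_id = genesv, changing = changing, change_day = changeDay,
      direction = ifelse(dir > 0, "up", ifelse(dir < 0, "down", "ns")),
      promoter_peak = promPeak, atac_coupled = atacCoupled,
      atac_change_day = atacDay, protein_coupled = protCoupled,
      protein_change_day = protDay, stringsAsFactors = FALSE)
    list(atac = se(atacCounts, atacDesign, "counts"),
         rna = se(rnaCounts, rnaDesign, "counts"),
         protein = se(protInt, protDesign, "intensities"),
         truth = truth)
  })
}

#' Generate ChIP peak sets, mark tracks and planted regulatory structure
#'
#' Takes a subset of the genome's peaks as the binding landscape of a
#' study factor (A), assigns each peak one of two planted regulatory
#' archetypes (promoter-like: high H3K4me3/accessibility;
#' enhancer-like: high H3K4me1/H3K27ac), and emits per-mark signal
#' tracks over the peaks (archetype mean + Gaussian noise). A partner
#' factor (B) co-binds a planted fraction of A's peaks; co-bound peaks
#' receive an additive shift on the active enhancer marks and on the
#' nearest gene's expression value. Replicate peak sets are jittered
#' copies of A (edges moved by up to `jitter` bp) so consensus building
#' is exercised; at `jitter = 0` they are identical to A.
#'
#' @param config A [simConfig()].
#' @param genome Result of [generateGenome()].
#' @return List: `peaks_a`, `peaks_b` (`GRanges`), `tracks` (named list
#'   of signal `GRanges`), `replicate_sets` (list of `GRanges`),
#'   `expression` (named per-A-peak expression of the nearest gene),
#'   `truth` (data.frame with planted `group` and `cobound` per A peak).
#' @export
generateChip <- function(config, genome) {
  withSeed(config$seed + 2L, {
    ch <- config$chip
    nPk <- min(ch$n_peaks, length(genome$peaks))
    A <- genome$peaks[sort(sample.int(length(genome$peaks), nPk))]
    A$peak_id <- sprintf("A%04d", seq_len(nPk))
    marks <- c("factorA", "ATAC", "H3K4me3", "H3K4me1", "H3K27ac",
               "H3K27me3")
    archetypes <- rbind(
      promoter_like = c(5, 6, 8, 1, 4, 0.5),
      enhancer_like = c(5, 5, 1, 8, 6, 0.5))
    colnames(archetypes) <- marks
    group <- sample(rownames(archetypes), nPk, replace = TRUE)
    cobound <- stats::runif(nPk) < ch$frac_cobound
    signal <- archetypes[group, , drop = FALSE] +
      matrix(stats::rnorm(nPk * length(marks), sd = ch$noise_sd),
             nPk, length(marks))
    signal[cobound, c("H3K4me1", "H3K27ac")] <-
      signal[cobound, c("H3K4me1", "H3K27ac")] + ch$mark_shift
    signal[signal < 0] <- 0
    tracks <- lapply(marks, function(mk) {
      tr <- GenomicRanges::granges(A)
      tr$score <- unname(signal[, mk])
      tr
    })
    names(tracks) <- marks

    # partner factor: co-bound peaks (small shift keeps >= 1 bp overlap
    # with the 300 bp A peaks) plus B-only peaks kept clear of A
    B <- GenomicRanges::shift(
      GenomicRanges::granges(A[cobound]),
      sample(-50:50, sum(cobound), replace = TRUE))
    nBonly <- max(5L, round(nPk * 0.2))
    apad <- GenomicRanges::resize(GenomicRanges::granges(A),
                                  GenomicRanges::width(A) + 400,
                                  fix = "center")
    bOnly <- GenomicRanges::granges(A)[0]  # empty, same seqinfo
    tries <- 0L
    chromsA <- unique(as.character(GenomicRanges::seqnames(A)))
    while (length(bOnly) < nBonly && tries < 50L * nBonly) {
      tries <- tries + 1L
      cand <- GenomicRanges::GRanges(
        sample(chromsA, 1L),
        IRanges::IRanges(sample.int(config$chromLength - 300L, 1L),
                         width = 300L))
      if (GenomicRanges::countOverlaps(cand, apad) > 0L) next
      if (length(bOnly) &&
          GenomicRanges::countOverlaps(cand, bOnly) > 0L) next
      bOnly <- c(bOnly, cand)
    }
    B <- c(B, bOnly)
    B$peak_id <- sprintf("B%04d", seq_along(B))

    reps <- lapply(seq_len(ch$n_replicates), function(r) {
      if (ch$jitter == 0) return(GenomicRanges::granges(A))
      d1 <- sample(seq(-ch$jitter, ch$jitter), nPk, replace = TRUE)
      d2 <- sample(seq(-ch$jitter, ch$jitter), nPk, replace = TRUE)
      GenomicRanges::GRanges(
        GenomicRanges::seqnames(A),
        IRanges::IRanges(pmax(1, GenomicRanges::start(A) + d1),
                         pmax(GenomicRanges::start(A) + d1 + 50,
                              GenomicRanges::end(A) + d2)))
    })

    expression <- stats::rnorm(nPk, mean = 5, sd = 1) +
      ifelse(cobound, ch$expression_shift, 0)
    names(expression) <- A$peak_id
    truth <- data.frame(peak_id = A$peak_id, group = group,
                        cobound = cobound, stringsAsFactors = FALSE)
    list(peaks_a = A, peaks_b = B, tracks = tracks,
         replicate_sets = reps, expression = expression, truth = truth)
  })
}

#' Generate an iBAQ-like pull-down table with planted interactors
#'
#' The bait sits above the interactor intensity distribution in every
#' target run. Planted per protein (same status in both cell types):
#' exclusive interactors have IgG intensity 0 everywhere, enriched ones
#' have per-replicate target/IgG folds drawn in `[min_fold, 4 min_fold]`,
#' background proteins have folds below `min_fold`. Every called protein
#' carries a planted bait-association rate (`log2_rate`, N(0, 1.2)) that
#' fixes its target intensity ratio between neurons and ESCs, and a
#' protein expression log2 fold change correlated with the rate at the
#' configured `rho` -- at zero noise [associationRate()] recovers the
#' planted rates exactly. With `noise > 0`, each IgG measurement is
#' independently suppressed tenfold with that probability (contamination
#' of the control), letting some background folds cross the threshold.
#'
#' @param config A [simConfig()].
#' @return List with `pd` (a [PulldownExperiment]) and `truth`
#'   (data.frame: `protein_id`, `status`, `log2_rate`, `protein_fc`).
#' @export
generatePulldown <- function(config) {
  withSeed(config$seed + 3L, {
    pu <- config$pulldown
    nExc <- pu$n_exclusive; nEnr <- pu$n_enriched; nBg <- pu$n_background
    n <- nExc + nEnr + nBg
    ids <- sprintf("P%03d", seq_len(n))
    status <- c(rep("exclusive", nExc), rep("enriched", nEnr),
                rep("rejected", nBg))
    called <- status != "rejected"
    z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
    log2_rate <- ifelse(called, 1.2 * z1, NA)
    protein_fc <- 1.2 * (pu$rho * z1 + sqrt(1 - pu$rho^2) * z2)

    baitInt <- 1e7
    baseEsc <- stats::rlnorm(n, meanlog = log(1e5), sdlog = 1)
    ratioEsc <- baseEsc / baitInt
    ratioNeu <- ifelse(called, ratioEsc * 2^log2_rate, ratioEsc)
    targetMean <- cbind(escs = ratioEsc * baitInt,
                        neurons = ratioNeu * baitInt)

    runs <- expand.grid(replicate = c("r1", "r2"),
                        bait = c("target", "igg"),
                        cell_type = c("escs", "neurons"),
                        stringsAsFactors = FALSE)
    runs$run <- with(runs, paste(cell_type, bait, replicate, sep = "_"))
    m <- matrix(0, nrow = n + 1L, ncol = nrow(runs),
                dimnames = list(c("BAIT", ids), runs$run))
    for (j in seq_len(nrow(runs))) {
      ct <- runs$cell_type[j]
      if (runs$bait[j] == "target") {
        m[, j] <- c(baitInt, targetMean[, ct])
      } else {
        fold <- ifelse(status == "enriched",
                       stats::runif(n, pu$min_fold, 4 * pu$min_fold),
                       stats::runif(n, 0.5, pu$min_fold * 0.75))
        igg <- targetMean[, ct] / fold
        igg[status == "exclusive"] <- 0
        if (pu$noise > 0) {
          hit <- stats::runif(n) < pu$noise
          igg[hit] <- igg[hit] / 10
        }
        m[, j] <- c(baitInt / 50, igg)
      }
    }
    pd <- PulldownExperiment(m, bait = runs$bait, replicate = runs$replicate,
                             cellType = runs$cell_type)
    truth <- data.frame(protein_id = ids, status = status,
                        log2_rate = log2_rate, protein_fc = protein_fc,
                        stringsAsFactors = FALSE)
    list(pd = pd, truth = truth)
  })
}

#' Simulate direction records with planted lagged coupling
#'
#' Record-level generator for calibrating and validating the association
#' scan: each pair's source feature is up with probability `pSourceUp`
#' (down otherwise), and the target feature is up with probability
#' `pTargetGivenUp` when the source is up and `pTargetOtherwise` when it
#' is not. The analytic odds ratio of the implied 2x2 table is
#' `(pTargetGivenUp / (1 - pTargetGivenUp)) /
#'  (pTargetOtherwise / (1 - pTargetOtherwise))`
#' (16 at the defaults).
#'
#' @param nPairs Number of linked pairs.
#' @param pSourceUp Probability that the source direction is up.
#' @param pTargetGivenUp,pTargetOtherwise Conditional probabilities of an
#'   up target.
#' @param seed RNG seed.
#' @return List with `pairs`, `sourceRecords`, `targetRecords` ready for
#'   [buildContingency()].
#' @export
simulateCoupledDirections <- function(nPairs = 2000L, pSourceUp = 0.5,
                                      pTargetGivenUp = 0.8,
                                      pTargetOtherwise = 0.2,
                                      seed = 1L) {
  checkProb(c(pSourceUp, pTargetGivenUp, pTargetOtherwise))
  withSeed(seed, {
    ids <- sprintf("f%05d", seq_len(nPairs))
    srcUp <- stats::runif(nPairs) < pSourceUp
    pT <- ifelse(srcUp, pTargetGivenUp, pTargetOtherwise)
    tgtUp <- stats::runif(nPairs) < pT
    list(
      pairs = data.frame(source_feature = ids, target_feature = ids,
                         pair_group = "rna_protein",
                         stringsAsFactors = FALSE),
      sourceRecords = data.frame(feature_id = ids,
                                 direction = ifelse(srcUp, "up", "down"),
                                 stringsAsFactors = FALSE),
      targetRecords = data.frame(feature_id = ids,
                                 direction = ifelse(tgtUp, "up", "down"),
                                 stringsAsFactors = FALSE))
  })
}

#' Simulate independent direction records over a full design
#'
#' Null-model generator: directions are drawn i.i.d. per feature,
#' contrast and layer with the given class probabilities, with no
#' coupling anywhere. Used to check the false-positive calibration of
#' the association scan.
#'
#' @param features Named list of feature-id vectors per layer (`atac`,
#'   `rna`, `protein` as needed).
#' @param contrasts data.frame with `layer`, `day_late`, `day_early`.
#' @param probs Named probabilities for `up`, `down`, `ns` (must sum
#'   to 1).
#' @param seed RNG seed.
#' @return data.frame of differential records (`feature_id`, `layer`,
#'   `day_late`, `day_early`, `direction`).
#' @export
simulateIndependentRecords <- function(features, contrasts,
                                       probs = c(up = 0.2, down = 0.2,
                                                 ns = 0.6),
                                       seed = 1L) {
  if (abs(sum(probs) - 1) > 1e-9) stop("'probs' must sum to 1")
  withSeed(seed, {
    res <- list()
    for (i in seq_len(nrow(contrasts))) {
      lay <- contrasts$layer[i]
      ids <- features[[lay]]
      if (is.null(ids) || length(ids) == 0L) next
      res[[i]] <- data.frame(
        feature_id = ids, layer = lay,
        day_late = contrasts$day_late[i],
        day_early = contrasts$day_early[i],
        direction = sample(names(probs), length(ids), replace = TRUE,
                           prob = probs),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, res)
  })
}
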