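cfgSmall <- function(seed = 1) {
  simConfig(seed = seed, nChroms = 1, chromLength = 120000, nGenes = 25,
            nPeaks = 80, chip = list(n_peaks = 60, noise_sd = 0.1,
                                     frac_cobound = 0.3, mark_shift = 2,
                                     expression_shift = 2, jitter = 20L,
                                     n_replicates = 3L))
}

test_that("generators are pure functions of the config seed", {
  cfg <- cfgSmall(5)
  g1 <- generateGenome(cfg)
  g2 <- generateGenome(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$tss, g2$tss)
  expect_identical(bedStart(g1$peaks), bedStart(g2$peaks))
  m1 <- generateMultiomics(cfg, g1)
  m2 <- generateMultiomics(cfg, g2)
  expect_identical(SummarizedExperiment::assay(m1$rna),
                   SummarizedExperiment::assay(m2$rna))
  expect_identical(m1$truth, m2$truth)
  p1 <- generatePulldown(cfg)
  p2 <- generatePulldown(cfg)
  expect_identical(intensities(p1$pd), intensities(p2$pd))
  # different seed gives different data
  g3 <- generateGenome(cfgSmall(6))
  expect_false(identical(as.character(g1$genome),
                         as.character(g3$genome)))
})

test_that("the toy genome honors its structural constraints", {
  cfg <- cfgSmall(3)
  g <- generateGenome(cfg)
  expect_equal(nrow(g$tss), cfg$nGenes)
  expect_equal(length(g$peaks), cfg$nPeaks)
  expect_equal(sum(Biostrings::width(g$genome)),
               cfg$nChroms * cfg$chromLength)
  # every promoter peak lies within 1.5 kb of its gene's TSS
  prom <- g$peaks[g$peaks$type == "promoter"]
  tsspos <- g$tss$tss[match(prom$gene_id, g$tss$gene_id)]
  d <- ifelse(tsspos >= bedStart(prom) & tsspos < bedEnd(prom), 0,
              pmin(abs(tsspos - bedStart(prom)),
                   abs(tsspos - (bedEnd(prom) - 1))))
  expect_true(all(d <= 1500))
  # distal peaks are never within the promoter window of any TSS
  dist <- g$peaks[g$peaks$type == "distal"]
  links <- assignPeaksToGenes(dist, g$tss, promoterWindow = 1500)
  expect_true(all(links$links$link_type == "distal"))
  # minus-strand TSS derivation is consistent with the gene spans
  gm <- list(genes = g$genes, exons = g$exons, tss = g$tss)
  neg <- g$tss$strand == "-"
  spanEnds <- bedEnd(g$genes)[match(g$tss$gene_id, g$genes$gene_id)]
  expect_true(all(g$tss$tss[neg] == spanEnds[neg] - 1))
})

test_that("multi-omics matrices have the configured shape and planted truth labels", {
  cfg <- cfgSmall(7)
  mo <- generateMultiomics(cfg, generateGenome(cfg))
  expect_equal(dim(SummarizedExperiment::assay(mo$rna)),
               c(cfg$nGenes, length(cfg$days$rna) * cfg$replicates$rna))
  expect_equal(dim(SummarizedExperiment::assay(mo$atac)),
               c(cfg$nPeaks, length(cfg$days$atac) * cfg$replicates$atac))
  expect_equal(dim(SummarizedExperiment::assay(mo$protein)),
               c(cfg$nGenes,
                 length(cfg$days$protein) * cfg$replicates$protein))
  tr <- mo$truth
  expect_equal(nrow(tr), cfg$nGenes)
  # coupled changes respect the configured lag
  lagged <- tr[!is.na(tr$protein_change_day), ]
  expect_true(all(lagged$protein_change_day - lagged$change_day ==
                    cfg$coupling$lag))
  early <- tr[!is.na(tr$atac_change_day), ]
  expect_true(all(early$change_day - early$atac_change_day ==
                    cfg$coupling$lag))
})

test_that("planted RNA effects are detectable by the differential test", {
  hits <- 0; total <- 0
  for (s in c(7, 21)) {
    cfg <- simConfig(seed = s)  # full default scale
    mo <- generateMultiomics(cfg, generateGenome(cfg))
    d <- simpleDifferential(
      SummarizedExperiment::assay(mo$rna),
      as.data.frame(SummarizedExperiment::colData(mo$rna)), "rna", 4, 0)
    tr <- mo$truth
    pl <- tr[tr$changing & tr$change_day == 4, ]
    got <- d[match(pl$gene_id, d$feature_id), ]
    hits <- hits + sum(got$direction == pl$direction)
    total <- total + nrow(pl)
    # significant planted genes always carry the planted sign
    sig <- got[got$direction != "ns", ]
    plsig <- pl[got$direction != "ns", ]
    expect_true(all(sig$direction == plsig$direction))
    # no planted change: almost everything stays ns under BH
    null <- d[match(tr$gene_id[!tr$changing], d$feature_id), ]
    expect_lt(mean(null$direction != "ns"), 0.1)
  }
  expect_gt(hits / total, 0.7)
})

test_that("ChIP generator output matches its planted truth at zero jitter", {
  cfg <- cfgSmall(9)
  cfg$chip$jitter <- 0L
  g <- generateGenome(cfg)
  chip <- generateChip(cfg, g)
  # replicate sets identical to the source peaks at zero jitter, so the
  # two-sample consensus is the peak set itself
  cons <- mergeConsensus(chip$replicate_sets, minSets = 2)
  expect_equal(length(cons), length(chip$peaks_a))
  expect_equal(bedStart(cons), sort(bedStart(chip$peaks_a)))
  # co-bound truth equals the three-way partition
  part <- partitionCobound(chip$peaks_a, chip$peaks_b)
  expect_setequal(part$co_bound$peak_id,
                  chip$truth$peak_id[chip$truth$cobound])
  # mark tracks round-trip through the bedGraph writer/reader
  f <- tempfile(fileext = ".bedGraph")
  writeBedGraph(chip$tracks$H3K27ac, f)
  back <- readBedGraph(f)
  expect_equal(back$score, chip$tracks$H3K27ac$score, tolerance = 1e-6)
  expect_equal(bedStart(back), bedStart(chip$tracks$H3K27ac))
  # planted archetypes are recovered from the signal matrix
  sm <- meanSignalMatrix(chip$peaks_a, chip$tracks)
  rg <- regulatoryGroups(sm[, c("H3K4me3", "H3K4me1", "H3K27ac", "ATAC")],
                         k = 2, seed = 2)
  expect_gte(adjustedRandIndex(rg$group, chip$truth$group), 0.9)
})

test_that("jittered replicate peak sets still yield a consensus covering the peaks", {
  cfg <- cfgSmall(11)
  chip <- generateChip(cfg, generateGenome(cfg))
  cons <- mergeConsensus(chip$replicate_sets, minSets = 2)
  ov <- overlapFlags(chip$peaks_a, cons)
  expect_equal(ov$fraction, 1)
})

test_that("pull-down generator plants recoverable interactors and rates", {
  cfg <- cfgSmall(13)
  pl <- generatePulldown(cfg)
  calls <- callInteractors(pl$pd, minFold = cfg$pulldown$min_fold)
  for (ct in c("escs", "neurons")) {
    got <- calls[calls$cell_type == ct, ]
    got <- got[match(pl$truth$protein_id, got$protein_id), ]
    expect_equal(got$status, pl$truth$status)
  }
  # bait ranks first in both cell types
  expect_equal(rankIBAQ(pl$pd, "escs")$protein_id[1], "BAIT")
  expect_equal(rankIBAQ(pl$pd, "neurons")$protein_id[1], "BAIT")
  # planted association rates recovered to numerical precision
  ar <- associationRate(pl$pd, "BAIT")
  tr <- pl$truth[!is.na(pl$truth$log2_rate), ]
  got <- ar$log2_rate[match(tr$protein_id, ar$protein_id)]
  expect_equal(got, tr$log2_rate, tolerance = 1e-9)
})
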