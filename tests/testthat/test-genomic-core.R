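test_that("BED6 and narrowPeak round-trip through read/write unchanged", {
  peaks <- grBed("chr1", c(100, 500, 900), c(200, 650, 1200),
                 strand = c("+", "-", "*"))
  peaks$score <- c(5, 1.5, 0)
  peaks$summit <- NA_real_

  bed <- tempfile(fileext = ".bed")
  writePeaks(peaks, bed, format = "bed6")
  back <- readPeaks(bed, format = "bed6")
  expect_equal(bedStart(back), bedStart(peaks))
  expect_equal(bedEnd(back), bedEnd(peaks))
  expect_equal(back$peak_id, peaks$peak_id)
  expect_equal(back$score, peaks$score)
  expect_equal(as.character(GenomicRanges::strand(back)),
               as.character(GenomicRanges::strand(peaks)))

  peaks$summit <- c(150, 600, NA)
  np <- tempfile(fileext = ".narrowPeak")
  writePeaks(peaks, np, format = "narrowPeak")
  back2 <- readPeaks(np, format = "narrowPeak")
  expect_equal(back2$summit, peaks$summit)
  expect_equal(bedStart(back2), bedStart(peaks))
  expect_equal(back2$score, peaks$score)
})

test_that("peak reader maps fields, derives summits, and names bad lines", {
  f <- tempfile()
  writeLines("chr1\t100\t200\tp1\t5\t+", f)
  p <- readPeaks(f, "bed6")
  expect_equal(as.character(GenomicRanges::seqnames(p)), "chr1")
  expect_equal(bedStart(p), 100)
  expect_equal(bedEnd(p), 200)
  expect_equal(p$peak_id, "p1")
  expect_equal(as.character(GenomicRanges::strand(p)), "+")

  # narrowPeak summit = start + column-10 offset
  writeLines("chr1\t100\t200\tp1\t0\t.\t7.5\t-1\t-1\t50", f)
  np <- readPeaks(f, "narrowPeak")
  expect_equal(np$summit, 150)
  expect_equal(np$score, 7.5)

  writeLines(c("chr1\t100\t200\tp1\t5\t+", "chr1\t300"), f)
  expect_error(readPeaks(f, "bed6"), "line 2")
  writeLines("chr1\t-5\t200\tp1\t5\t+", f)
  expect_error(readPeaks(f, "bed6"), "negative")
})

test_that("extendAroundMidpoint yields fixed-width windows with left clipping", {
  p <- grBed("chr1", c(1000, 0, 100), c(1200, 10, 201))
  e <- extendAroundMidpoint(p, flank = 250)
  # [1000,1200) -> mid 1100 -> [850,1350)
  expect_equal(bedStart(e)[1], 850)
  expect_equal(bedEnd(e)[1], 1350)
  # [0,10) -> mid 5 -> clipped [0,255)
  expect_equal(bedStart(e)[2], 0)
  expect_equal(bedEnd(e)[2], 255)
  # odd width [100,201) -> mid 150 -> clipped [0,400)
  expect_equal(bedStart(e)[3], 0)
  expect_equal(bedEnd(e)[3], 400)
  expect_error(extendAroundMidpoint(p, flank = 0), "> 0")
})

test_that("extension widths equal 2*flank except left-clipped cases", {
  set.seed(21)
  for (flank in c(50, 250)) {
    p <- randomPeaks(100)
    e <- extendAroundMidpoint(p, flank)
    clipped <- bedStart(e) == 0
    expect_true(all(GenomicRanges::width(e)[!clipped] == 2 * flank))
    expect_true(all(GenomicRanges::width(e)[clipped] <= 2 * flank))
  }
})

test_that("mergeConsensus returns maximal >= minSets coverage runs", {
  s1 <- grBed("chr1", 100, 200)
  s2 <- grBed("chr1", 150, 250)
  s3 <- grBed("chr1", 400, 500)
  cons <- mergeConsensus(list(s1, s2, s3), minSets = 2)
  expect_equal(bedStart(cons), 150)
  expect_equal(bedEnd(cons), 200)
  # identical sets: consensus equals the set
  same <- mergeConsensus(list(s1, s1), minSets = 2)
  expect_equal(bedStart(same), 100)
  expect_equal(bedEnd(same), 200)
  # disjoint sets: empty
  expect_length(mergeConsensus(list(s1, s3), minSets = 2), 0)
  expect_error(mergeConsensus(list(s1), minSets = 2), "exceeds")
})

test_that("mergeConsensus matches the per-basepair coverage oracle", {
  set.seed(33)
  for (rep in 1:30) {
    nsets <- sample(2:5, 1)
    sets <- lapply(seq_len(nsets), function(i)
      randomPeaks(sample(5:50, 1)))
    minSets <- sample(2:nsets, 1)
    got <- mergeConsensus(sets, minSets)
    want <- oracleConsensus(sets, minSets)
    expect_equal(length(got), nrow(want))
    if (length(got)) {
      expect_equal(bedStart(got), want$start0)
      expect_equal(bedEnd(got), want$end0)
    }
  }
})

test_that("overlapFlags counts >= minOverlap shared bases under half-open rules", {
  a <- grBed("chr1", c(0, 300, 600, 900), c(100, 400, 700, 1000))
  b <- grBed("chr1", c(50, 350), c(80, 380))
  ov <- overlapFlags(a, b)
  expect_equal(ov$fraction, 0.5)
  expect_equal(ov$flag, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(overlapFlags(a, a)$fraction, 1.0)
  # adjacency in half-open coordinates is not overlap
  x <- grBed("chr1", 100, 200); y <- grBed("chr1", 200, 300)
  expect_false(overlapFlags(x, y)$flag)
  # monotone non-decreasing as minOverlap decreases
  set.seed(13)
  p <- randomPeaks(50); q <- randomPeaks(20)
  fr <- vapply(c(100, 50, 10, 1), function(mo)
    overlapFlags(p, q, minOverlap = mo)$fraction, numeric(1))
  expect_true(all(diff(fr) >= 0))
  expect_error(overlapFlags(p[0], q), "empty")
})

test_that("assignPeaksToGenes links to the nearest TSS with documented rules", {
  tss <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                    tss = c(5000, 20000), strand = "+")
  peaks <- grBed("chr1", c(4900, 3000), c(4950, 3400),
                 peak_id = c("pNear", "pFar"))
  res <- assignPeaksToGenes(peaks, tss, promoterWindow = 1500)
  near <- res$links[res$links$peak_id == "pNear", ]
  expect_equal(near$gene_id, "gA")
  expect_equal(near$link_type, "promoter")
  # distance measured to the nearest included base: 5000 - 3399 = 1601
  far <- res$links[res$links$peak_id == "pFar", ]
  expect_equal(far$distance, 1601)
  expect_equal(far$link_type, "distal")
  # equidistant TSS tie broken by lexicographically smaller gene_id
  tss2 <- data.frame(gene_id = c("gZ", "gA"), chrom = "chr1",
                     tss = c(1100, 900), strand = "+")
  mid <- grBed("chr1", 995, 1006, peak_id = "pMid")  # included bases 995..1005
  res2 <- assignPeaksToGenes(mid, tss2)
  expect_equal(res2$links$gene_id, "gA")
  # peak on unknown chromosome: warning, no link
  off <- grBed("chr9", 100, 200, peak_id = "pOff")
  expect_warning(res3 <- assignPeaksToGenes(off, tss), "absent")
  expect_equal(nrow(res3$links), 0)
})

test_that("per-gene promoter peak is the closest one within the window", {
  tss <- data.frame(gene_id = "gA", chrom = "chr1", tss = 5000,
                    strand = "+")
  peaks <- grBed("chr1", c(4600, 5200, 9000), c(4700, 5400, 9100),
                 peak_id = c("p300", "p200", "pFar"))
  res <- assignPeaksToGenes(peaks, tss, promoterWindow = 1500)
  expect_equal(nrow(res$promoterPeaks), 1)
  expect_equal(res$promoterPeaks$peak_id, "p200")
})

test_that("assignPeaksToGenes matches the all-pairs nearest-TSS oracle", {
  set.seed(55)
  for (rep in 1:5) {
    peaks <- randomPeaks(200, chromLen = 50000)
    tss <- data.frame(gene_id = sprintf("g%02d", 1:50),
                      chrom = "chr1",
                      tss = sample.int(50000, 50),
                      strand = sample(c("+", "-"), 50, TRUE))
    got <- assignPeaksToGenes(peaks, tss)$links
    want <- oracleNearestGene(peaks, tss)
    got <- got[order(got$peak_id), ]
    want <- want[order(want$peak_id), ]
    expect_equal(got$gene_id, want$gene_id)
    expect_equal(got$distance, want$distance)
    expect_equal(got$link_type, want$link_type)
  }
})

test_that("annotatePeakCategory applies promoter > exon > intron precedence", {
  model <- list(
    genes = grBed("chr1", 5000, 15000, strand = "+", peak_id = "gA"),
    exons = grBed("chr1", c(5000, 14000), c(5500, 15000),
                  strand = "+", peak_id = c("e1", "e2")),
    tss = data.frame(gene_id = "gA", chrom = "chr1", tss = 5000,
                     strand = "+")
  )
  model$genes$gene_id <- "gA"; model$exons$gene_id <- "gA"
  peaks <- grBed("chr1", c(5200, 8000, 14200, 30000, 5250),
                 c(5350, 8200, 14400, 30200, 5600))
  cats <- annotatePeakCategory(peaks, model, promoterWindow = 1000)
  expect_equal(cats, c("promoter",          # 300 bp downstream of TSS
                       "intron",            # in gene span, no exon overlap
                       "exon",              # inside exon, outside window
                       "distal_intergenic", # far away
                       "promoter"))         # overlaps window AND exon
})

test_that("TSS table and gene model round-trip, with strand-aware TSS derivation", {
  tss <- data.frame(gene_id = c("g1", "g2"), chrom = c("chr1", "chr2"),
                    tss = c(100, 5000), strand = c("+", "-"))
  f <- tempfile()
  writeTSS(tss, f)
  expect_equal(readTSS(f), tss)

  gm <- list(genes = grBed("chr1", c(100, 2000), c(1000, 3000),
                           strand = c("+", "-"), peak_id = c("x", "y")),
             exons = grBed("chr1", 100, 300, strand = "+", peak_id = "z"))
  gm$genes$gene_id <- c("g1", "g2"); gm$exons$gene_id <- "g1"
  f2 <- tempfile()
  writeGeneModel(gm, f2)
  back <- readGeneModel(f2)
  expect_equal(back$tss$tss, c(100, 2999))  # minus strand: end - 1
  expect_equal(bedStart(back$genes), c(100, 2000))
})
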