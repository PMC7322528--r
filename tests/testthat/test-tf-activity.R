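pointMassPWM <- function(word = "ACGT") {
  bases <- c("A", "C", "G", "T")
  probs <- vapply(strsplit(word, "")[[1]], function(b) {
    p <- rep(0.01 / 3, 4); p[bases == b] <- 0.99; p
  }, numeric(4))
  newPWM("pm", probs)
}

randomPWM <- function(L = 6) {
  m <- matrix(stats::rgamma(4 * L, 1), nrow = 4)
  newPWM("rnd", sweep(m, 2, colSums(m), "/"))
}

test_that("readJASPAR parses bracketed PFMs into probability matrices", {
  f <- tempfile()
  writeLines(c(">MA0001.1 TFA",
               "A [ 10  0  0 10 ]",
               "C [  0 10  0  0 ]",
               "G [  0  0 10  0 ]",
               "T [  0  0  0  0 ]"), f)
  pwms <- readJASPAR(f)
  expect_equal(names(pwms), "TFA")
  p <- pwms$TFA$probs
  expect_equal(colSums(p), rep(1, 4), tolerance = 1e-9)
  expect_gt(p["A", 1], 0.9)
  expect_gt(p["T", 4], 0)  # pseudocount keeps zero counts positive
  # round trip through the writer
  f2 <- tempfile()
  writeJASPAR(pwms, f2)
  back <- readJASPAR(f2)
  expect_equal(back$TFA$probs, p, tolerance = 0.02)
})

test_that("scanPWM finds a point-mass motif at the right place on both strands", {
  genome <- Biostrings::DNAStringSet(c(chrT = "AAACGTAA"))
  hits <- scanPWM(genome, pointMassPWM("ACGT"), minScoreFrac = 0.9)
  # ACGT is its own reverse complement: one hit per strand at [2,6)
  expect_equal(length(hits), 2)
  expect_equal(unique(GenomicRanges::start(hits) - 1), 2)
  expect_equal(unique(GenomicRanges::end(hits)), 6)
  expect_setequal(as.character(GenomicRanges::strand(hits)), c("+", "-"))
  # reverse-complementing the genome preserves the hit count
  rcg <- Biostrings::reverseComplement(genome)
  names(rcg) <- "chrT"
  expect_equal(length(scanPWM(rcg, pointMassPWM("ACGT"), 0.9)), 2)
  # stricter threshold returns a subset
  set.seed(10)
  g2 <- Biostrings::DNAStringSet(c(chr1 = paste(
    sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")))
  pw <- randomPWM()
  loose <- scanPWM(g2, pw, 0.8)
  strict <- scanPWM(g2, pw, 1.0)
  key <- function(h) paste(GenomicRanges::start(h),
                           GenomicRanges::strand(h))
  expect_true(all(key(strict) %in% key(loose)))
  expect_error(scanPWM(Biostrings::DNAStringSet(), pw), "empty")
})

test_that("scanPWM agrees with the exhaustive per-window oracle, skipping N windows", {
  set.seed(17)
  for (rep in 1:5) {
    seqchar <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE),
                     collapse = "")
    # inject a few N bases
    pos <- sample(900, 3)
    substring(seqchar, pos, pos) <- "N"
    pw <- randomPWM(sample(4:8, 1))
    got <- scanPWM(Biostrings::DNAStringSet(c(chr1 = seqchar)), pw, 0.85)
    want <- oraclePWMScan(seqchar, pw, 0.85)
    expect_equal(length(got), nrow(want))
    if (length(got)) {
      ord <- order(want$start0, want$strand)
      gord <- order(GenomicRanges::start(got) - 1,
                    as.character(GenomicRanges::strand(got)))
      expect_equal(GenomicRanges::start(got)[gord] - 1, want$start0[ord])
      expect_equal(got$match_score[gord], want$score[ord],
                   tolerance = 1e-9)
    }
  }
})

test_that("selectSitesInPeaks extends by the flank and keeps >=1 bp overlaps", {
  sites <- grBed("chr1", c(1000, 2000), c(1010, 2010),
                 peak_id = c("s1", "s2"))
  sites$tf_name <- "tf"
  peaks <- grBed("chr1", 900, 970, peak_id = "pkA")
  # 10 bp site -> 110 bp after the default 50 bp extension
  kept <- selectSitesInPeaks(sites, peaks)
  expect_equal(GenomicRanges::width(kept), 110)
  # site 1 starts 30 bp after the peak end: retained via the extension
  expect_equal(kept$peak_id, "pkA")
  expect_length(selectSitesInPeaks(sites, peaks[0]), 0)
  # tie broken by larger overlap
  two <- c(grBed("chr1", 950, 1200, peak_id = "big"),
           grBed("chr1", 940, 960, peak_id = "sml"))
  kept2 <- selectSitesInPeaks(sites[1], two)
  expect_equal(kept2$peak_id, "big")
})

test_that("siteLog2FC is CPM-invariant and tracks count doubling", {
  design <- data.frame(sample = c("a1", "a2", "b1", "b2"),
                       day = c(0, 0, 4, 4))
  m <- matrix(1000, nrow = 500, ncol = 4,
              dimnames = list(sprintf("s%03d", 1:500), design$sample))
  expect_equal(unname(siteLog2FC(m, design, 4, 0)), rep(0, 500))
  m2 <- m
  m2[1, design$day == 4] <- 2000
  fc <- siteLog2FC(m2, design, 4, 0)
  expect_equal(unname(fc[1]), 1, tolerance = 0.02)
  # scaling one sample's library leaves CPMs unchanged
  m3 <- m2
  m3[, 1] <- m3[, 1] * 10
  expect_equal(siteLog2FC(m3, design, 4, 0), fc, tolerance = 1e-12)
  m0 <- m; m0[, 2] <- 0
  expect_error(siteLog2FC(m0, design, 4, 0), "library size")
})

test_that("tfActivity is the plain mean with a minimum-site guard", {
  expect_equal(tfActivity(c(0.5, 1.5), minSites = 2), 1)
  expect_equal(tfActivity(rep(0, 60)), 0)
  set.seed(23)
  x <- rnorm(500)
  expect_equal(tfActivity(x), sum(x) / length(x), tolerance = 1e-12)
  expect_warning(res <- tfActivity(rnorm(10)), "skipped")
  expect_true(is.na(res))
})

test_that("permutationSignificance separates planted activity from the null", {
  set.seed(31)
  pool <- rnorm(5000, 0, 0.5)
  planted <- rnorm(200, 1, 0.5)
  sig <- permutationSignificance(planted, pool, nPerm = 500, seed = 1)
  expect_true(sig$significant)
  expect_gt(sig$cohens_d, 1)
  # reversing the contrast flips the sign
  sigNeg <- permutationSignificance(-planted, -pool, nPerm = 500, seed = 1)
  expect_equal(sigNeg$cohens_d, -sig$cohens_d, tolerance = 1e-9)
  # a TF whose sites are a random pool subset stays non-significant
  nullTF <- sample(pool, 200)
  sig0 <- permutationSignificance(nullTF, setdiff(pool, nullTF),
                                  nPerm = 500, seed = 2)
  expect_lt(abs(sig0$cohens_d), 1)
  # deterministic under a fixed seed
  expect_identical(sig,
                   permutationSignificance(planted, pool, nPerm = 500,
                                           seed = 1))
  expect_warning(
    permutationSignificance(rnorm(50), rnorm(10), nPerm = 10, seed = 1),
    "replacement")
})

test_that("tfActivityScan flags the planted TF and spares the null TF", {
  set.seed(37)
  fcs <- c(rnorm(200, 1, 0.5), rnorm(200, 0, 0.5), rnorm(4600, 0, 0.5))
  tf <- c(rep("TF_planted", 200), rep("TF_null", 200),
          rep("TF_bg", 4600))
  # (the big background TF draws its null from a smaller pool, which
  # falls back to replacement sampling with a warning)
  res <- suppressWarnings(tfActivityScan(fcs, tf, nPerm = 300, seed = 5))
  expect_true(res$significant[res$tf_name == "TF_planted"])
  expect_gt(res$cohens_d[res$tf_name == "TF_planted"], 1)
  expect_false(res$significant[res$tf_name == "TF_null"])
  expect_equal(res$mean_diff[res$tf_name == "TF_planted"],
               mean(fcs[tf == "TF_planted"]))
})

test_that("clusterTFGroups recovers archetypes and flags anticorrelated repressors", {
  set.seed(41)
  tfs <- sprintf("TF%02d", 1:60)
  # activators: activity and expression both rise; repressors: opposed
  act <- rbind(matrix(rep(c(1, 2, 3), each = 30), ncol = 3),
               matrix(rep(c(1, 2, 3), each = 30), ncol = 3) * -1)
  expr <- rbind(matrix(rep(c(1, 2, 3), each = 30), ncol = 3),
                matrix(rep(c(1, 2, 3), each = 30), ncol = 3))
  act <- act + rnorm(180, sd = 0.05)
  expr <- expr + rnorm(180, sd = 0.05)
  rownames(act) <- rownames(expr) <- tfs
  res <- clusterTFGroups(act, expr, k = 2, seed = 7)
  expect_equal(adjustedRandIndex(res$group, rep(1:2, each = 30)), 1)
  rep_groups <- res$summary$candidate_repressor
  expect_equal(sum(rep_groups), 1)
  # the repressor group is the one with negative activity/expression r
  expect_lt(res$summary$activity_expression_r[rep_groups], 0)
  # all-identical TFs with k = 1
  one <- matrix(1, 10, 3, dimnames = list(sprintf("t%d", 1:10), NULL))
  res1 <- clusterTFGroups(one, one, k = 1, seed = 1)
  expect_equal(unname(res1$group), rep(1L, 10))
})
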