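# Chromatin-bound interactome (ChIP-SICAP style) scoring: iBAQ-ranked
# pull-down tables, interactor calling against IgG controls,
# bait-normalized association rates between cell types, correlation with
# expression change, and functional-category enrichment.

#' @import methods
NULL

#' PulldownExperiment: protein x run intensity container
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding one assay
#' `intensities` of iBAQ-like values (0 = not detected) whose column
#' metadata describes each pull-down run: `bait` (`"target"` or
#' `"igg"`), `replicate` (pairing id) and `cell_type` (`"escs"` or
#' `"neurons"`). Validity requires non-negative intensities and at least
#' two target and two IgG runs per cell type.
#'
#' @export
setClass("PulldownExperiment",
         contains = "SummarizedExperiment")

setValidity("PulldownExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  need <- c("bait", "replicate", "cell_type")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    return(paste("colData misses:", paste(miss, collapse = ", ")))
  if (!all(cd$bait %in% c("target", "igg")))
    return("'bait' must be 'target' or 'igg'")
  if (!all(cd$cell_type %in% c("escs", "neurons")))
    return("'cell_type' must be 'escs' or 'neurons'")
  a <- SummarizedExperiment::assay(object, "intensities")
  if (any(a < 0)) return("intensities must be >= 0")
  for (ct in unique(cd$cell_type)) {
    nt <- sum(cd$cell_type == ct & cd$bait == "target")
    ni <- sum(cd$cell_type == ct & cd$bait == "igg")
    if (nt < 2L || ni < 2L)
      return(paste0("cell type '", ct,
                    "' needs >= 2 target and >= 2 igg runs"))
  }
  TRUE
})

#' Construct a PulldownExperiment
#'
#' @param intensities Protein x run numeric matrix (rownames = protein
#'   ids, colnames = run ids).
#' @param bait Character vector per run: `"target"` or `"igg"`.
#' @param replicate Replicate ids pairing target and IgG runs.
#' @param cellType `"escs"` or `"neurons"` per run.
#' @return A `PulldownExperiment`.
#' @export
PulldownExperiment <- function(intensities, bait, replicate, cellType) {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensities = as.matrix(intensities)),
    colData = S4Vectors::DataFrame(bait = bait, replicate = replicate,
                                   cell_type = cellType))
  methods::new("PulldownExperiment", se)
}

#' Intensity matrix of a PulldownExperiment
#' @param x A `PulldownExperiment`.
#' @return The protein x run intensity matrix.
#' @export
intensities <- function(x) SummarizedExperiment::assay(x, "intensities")

#' Run metadata of a PulldownExperiment
#' @param x A `PulldownExperiment`.
#' @return `DataFrame` with `bait`, `replicate`, `cell_type` per run.
#' @export
runInfo <- function(x) SummarizedExperiment::colData(x)

setMethod("show", "PulldownExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("PulldownExperiment:", nrow(object), "proteins,",
      ncol(object), "runs\n")
  for (ct in unique(cd$cell_type))
    cat(" ", ct, ":", sum(cd$cell_type == ct & cd$bait == "target"),
        "target /", sum(cd$cell_type == ct & cd$bait == "igg"),
        "igg runs\n")
})

#' Read a pull-down intensity table
#'
#' Plain TSV with three metadata header lines (`#bait`, `#replicate`,
#' `#cell_type`, tab-aligned with the run columns) followed by a header
#' row `protein_id <run ids...>` and one row per protein.
#'
#' @param path Path to the TSV.
#' @return A [PulldownExperiment].
#' @export
readPulldownTable <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  need <- c("#bait", "#replicate", "#cell_type")
  got <- vapply(strsplit(meta, "\t"), `[`, character(1), 1L)
  if (!all(need %in% got))
    stop("pull-down table misses metadata line(s): ",
         paste(setdiff(need, got), collapse = ", "))
  metaf <- strsplit(meta, "\t", fixed = TRUE)
  names(metaf) <- got
  body <- lines[!startsWith(lines, "#")]
  df <- utils::read.delim(text = paste(body, collapse = "\n"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1L]]
  nrun <- ncol(m)
  getMeta <- function(key) {
    v <- metaf[[key]][-1]
    if (length(v) != nrun)
      stop("metadata line '", key, "' does not match the run columns")
    v
  }
  PulldownExperiment(m, bait = getMeta("#bait"),
                     replicate = getMeta("#replicate"),
                     cellType = getMeta("#cell_type"))
}

#' Write a pull-down intensity table
#' @param pd A [PulldownExperiment].
#' @param path Output path.
#' @export
writePulldownTable <- function(pd, path) {
  cd <- SummarizedExperiment::colData(pd)
  m <- intensities(pd)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("#bait", cd$bait), collapse = "\t"), con)
  writeLines(paste(c("#replicate", cd$replicate), collapse = "\t"), con)
  writeLines(paste(c("#cell_type", cd$cell_type), collapse = "\t"), con)
  writeLines(paste(c("protein_id", colnames(m)), collapse = "\t"), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(c(rownames(m)[i], format(m[i, ], trim = TRUE,
                                              scientific = FALSE)),
                     collapse = "\t"), con)
  invisible(path)
}

#' Rank proteins by mean target-run intensity
#'
#' Proteins are sorted by their mean intensity over the target pull-down
#' runs of one cell type, descending; ties break by protein id. A
#' specific and efficient pull-down puts the bait at or near rank 1
#' (behind only highly abundant chromatin proteins such as histones).
#'
#' @param pd A [PulldownExperiment].
#' @param cellType Cell type to rank within.
#' @return data.frame with `protein_id`, `mean_intensity`, `rank`.
#' @export
rankIBAQ <- function(pd, cellType) {
  cd <- SummarizedExperiment::colData(pd)
  sel <- cd$cell_type == cellType & cd$bait == "target"
  if (!any(sel)) stop("no target runs for cell type '", cellType, "'")
  mi <- rowMeans(intensities(pd)[, sel, drop = FALSE])
  ord <- order(-mi, names(mi))
  data.frame(protein_id = names(mi)[ord], mean_intensity = mi[ord],
             rank = seq_along(mi), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Call interactors against the IgG control
#'
#' Per cell type, target and IgG runs are paired by replicate id and a
#' per-replicate enrichment fold `target / igg` is formed. A protein is
#' \describe{
#'   \item{exclusive}{detected in every target replicate with IgG
#'     intensity 0 in every replicate;}
#'   \item{enriched}{detected in every target replicate, IgG > 0 in every
#'     replicate, and fold >= `minFold` in every replicate;}
#'   \item{rejected}{anything else, including mixed zero/non-zero IgG
#'     patterns (each rule is applied strictly across all replicates) and
#'     proteins missing from any target replicate.}
#' }
#'
#' @param pd A [PulldownExperiment].
#' @param minFold Minimum per-replicate enrichment fold (default 4;
#'   the boundary fold passes, i.e. `>=`).
#' @return data.frame with `protein_id`, `cell_type`, `status` and a
#'   list-column `fold_per_replicate`.
#' @export
callInteractors <- function(pd, minFold = 4) {
  cd <- SummarizedExperiment::colData(pd)
  m <- intensities(pd)
  out <- list()
  for (ct in unique(cd$cell_type)) {
    treps <- sort(cd$replicate[cd$cell_type == ct & cd$bait == "target"])
    ireps <- sort(cd$replicate[cd$cell_type == ct & cd$bait == "igg"])
    if (!identical(treps, ireps))
      stop("unpaired target/igg replicates in cell type '", ct, "'")
    tg <- vapply(treps, function(r)
      m[, cd$cell_type == ct & cd$bait == "target" & cd$replicate == r],
      numeric(nrow(m)))
    ig <- vapply(treps, function(r)
      m[, cd$cell_type == ct & cd$bait == "igg" & cd$replicate == r],
      numeric(nrow(m)))
    folds <- ifelse(tg > 0 & ig == 0, Inf, tg / ig)
    detected <- rowSums(tg > 0) == ncol(tg)
    exclusive <- detected & rowSums(ig == 0) == ncol(ig)
    enriched <- detected & rowSums(ig > 0) == ncol(ig) &
      rowSums(tg / ig >= minFold) == ncol(ig)
    status <- ifelse(exclusive, "exclusive",
                     ifelse(enriched, "enriched", "rejected"))
    out[[ct]] <- data.frame(
      protein_id = rownames(m), cell_type = ct, status = status,
      fold_per_replicate = I(lapply(seq_len(nrow(m)),
                                    function(i) unname(folds[i, ]))),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Bait-normalized association-rate scores between cell types
#'
#' For every protein, the ratio of its mean target-run intensity to the
#' bait's is formed per cell type, and the score is the log2 of the
#' neurons ratio over the ESCs ratio. Positive scores mean the protein
#' associates with the bait more strongly in neurons. Proteins (or the
#' bait) undetected in either cell type yield no score.
#'
#' @param pd A [PulldownExperiment].
#' @param baitId Protein id of the bait.
#' @return data.frame with `protein_id`, `log2_rate`.
#' @export
associationRate <- function(pd, baitId) {
  cd <- SummarizedExperiment::colData(pd)
  m <- intensities(pd)
  if (!baitId %in% rownames(m)) stop("bait '", baitId, "' not in the table")
  ctMean <- function(ct)
    rowMeans(m[, cd$cell_type == ct & cd$bait == "target", drop = FALSE])
  esc <- ctMean("escs"); neu <- ctMean("neurons")
  if (esc[baitId] <= 0 || neu[baitId] <= 0)
    stop("bait undetected in one of the cell types")
  ok <- esc > 0 & neu > 0
  rate <- log2((neu[ok] / neu[baitId]) / (esc[ok] / esc[baitId]))
  data.frame(protein_id = names(rate), log2_rate = unname(rate),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Correlate association-rate change with protein expression change
#'
#' Pearson correlation between the association-rate scores and the
#' proteins' expression log2 fold changes (neurons vs ESCs), plus
#' residuals from the least-squares line. Proteins whose association
#' changes far more than their expression (large |residual|) are
#' candidates for regulated recruitment to chromatin.
#'
#' @param scores data.frame from [associationRate()].
#' @param proteinFC Named numeric vector of protein expression log2 fold
#'   changes.
#' @return List with `r` and `table` (data.frame `protein_id`,
#'   `log2_rate`, `log2fc`, `residual`).
#' @export
scoreExpressionCorrelation <- function(scores, proteinFC) {
  shared <- intersect(scores$protein_id, names(proteinFC))
  if (length(shared) < 3L) stop("fewer than 3 shared proteins")
  s <- scores$log2_rate[match(shared, scores$protein_id)]
  f <- unname(proteinFC[shared])
  r <- pearsonR(s, f)
  fit <- stats::lm(s ~ f)
  list(r = r,
       table = data.frame(protein_id = shared, log2_rate = s, log2fc = f,
                          residual = unname(stats::residuals(fit)),
                          stringsAsFactors = FALSE))
}

#' Functional-category enrichment of called interactors
#'
#' For every category, a 2x2 table (called-and-in-category, called-only,
#' category-only, neither) over the protein universe, tested with
#' [fisher2x2()]. Used e.g. to show that TFs and TF cofactors are
#' over-represented among a bait's interactors relative to all
#' protein-coding genes.
#'
#' @param called Character vector of called interactors (must be a subset
#'   of `background`).
#' @param annotation data.frame with `protein_id` and `category`
#'   (several rows per protein allowed).
#' @param background Character vector: the protein universe.
#' @return data.frame with `category`, `a`, `b`, `c`, `d`, `odds_ratio`,
#'   `log2_or`, `p`.
#' @export
categoryEnrichment <- function(called, annotation, background) {
  if (!all(called %in% background))
    stop("'called' must be a subset of 'background'")
  cats <- sort(unique(annotation$category))
  res <- lapply(cats, function(cat) {
    members <- unique(annotation$protein_id[annotation$category == cat])
    members <- intersect(members, background)
    if (length(members) == 0L)
      stop("category '", cat, "' has no members in the background")
    a <- sum(called %in% members)
    b <- length(called) - a
    c <- length(members) - a
    d <- length(background) - a - b - c
    fish <- fisher2x2(a, b, c, d)
    data.frame(category = cat, a = a, b = b, c = c, d = d,
               odds_ratio = fish$odds_ratio, log2_or = fish$log2_or,
               p = fish$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
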