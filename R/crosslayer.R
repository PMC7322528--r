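# Directional time-lagged cross-layer association testing. The engine
# asks, for every ordered pair of contrasts and every direction combo,
# whether features that move in the source layer are enriched for moving
# in the target layer at the same or a later time point, with information
# flow restricted to chromatin -> RNA -> protein.

PAIR_GROUPS <- c("rna_protein", "atac_tss_rna", "atac_distal_rna")

#' Build linked feature pairs between molecular layers
#'
#' Creates the three pair universes used for association testing:
#' \describe{
#'   \item{rna_protein}{genes measured on both RNA and protein level
#'     (source = target = the gene).}
#'   \item{atac_tss_rna}{per gene, the single closest promoter peak
#'     within the promoter window (from
#'     [assignPeaksToGenes()]`$promoterPeaks`), kept when both the peak
#'     is measured in ATAC and the gene in RNA.}
#'   \item{atac_distal_rna}{distal peak-to-nearest-gene links with both
#'     members measured; several distal peaks may point at one gene.}
#' }
#'
#' @param geneLinks Result of [assignPeaksToGenes()] (list with `links`
#'   and `promoterPeaks`).
#' @param rnaFeatures Character vector of genes measured on RNA level.
#' @param proteinFeatures Character vector of genes detected on protein
#'   level.
#' @param atacFeatures Character vector of measured peak ids.
#' @return data.frame with `source_feature`, `target_feature`,
#'   `pair_group`.
#' @export
linkLayers <- function(geneLinks, rnaFeatures, proteinFeatures,
                       atacFeatures) {
  shared <- intersect(rnaFeatures, proteinFeatures)
  rp <- data.frame(source_feature = shared, target_feature = shared,
                   pair_group = rep("rna_protein", length(shared)),
                   stringsAsFactors = FALSE)
  pp <- geneLinks$promoterPeaks
  pp <- pp[pp$peak_id %in% atacFeatures & pp$gene_id %in% rnaFeatures, ,
           drop = FALSE]
  tssr <- data.frame(source_feature = pp$peak_id,
                     target_feature = pp$gene_id,
                     pair_group = rep("atac_tss_rna", nrow(pp)),
                     stringsAsFactors = FALSE)
  dl <- geneLinks$links
  dl <- dl[dl$link_type == "distal" & dl$peak_id %in% atacFeatures &
             dl$gene_id %in% rnaFeatures, , drop = FALSE]
  dist <- data.frame(source_feature = dl$peak_id,
                     target_feature = dl$gene_id,
                     pair_group = rep("atac_distal_rna", nrow(dl)),
                     stringsAsFactors = FALSE)
  out <- rbind(rp, tssr, dist)
  rownames(out) <- NULL
  out
}

#' Build one directional 2x2 contingency table over a pair universe
#'
#' The universe is all supplied pairs; `a` counts pairs whose source
#' feature carries `dirSource` at the source contrast AND whose target
#' feature carries `dirTarget` at the target contrast, `b` source-only,
#' `c` target-only, `d` neither. The four cells always sum to the number
#' of pairs. Non-significant (`ns`) features remain in the universe and
#' land in `b`/`c`/`d`.
#'
#' @param pairs data.frame with `source_feature` and `target_feature`.
#' @param sourceRecords,targetRecords Differential records (data.frames
#'   with `feature_id` and `direction`) for the source and target
#'   contrast; they must cover every feature in the pair universe.
#' @param dirSource,dirTarget Direction classes tested (`"up"` or
#'   `"down"`).
#' @return List with integer cells `a`, `b`, `c`, `d`.
#' @export
buildContingency <- function(pairs, sourceRecords, targetRecords,
                             dirSource, dirTarget) {
  if (nrow(pairs) == 0L) stop("empty pair universe")
  sdir <- sourceRecords$direction[match(pairs$source_feature,
                                        sourceRecords$feature_id)]
  tdir <- targetRecords$direction[match(pairs$target_feature,
                                        targetRecords$feature_id)]
  if (anyNA(sdir) || anyNA(tdir))
    stop("differential records do not cover the pair universe")
  s <- sdir == dirSource
  t <- tdir == dirTarget
  list(a = sum(s & t), b = sum(s & !t), c = sum(!s & t), d = sum(!s & !t))
}

#' Map a day onto a reference time grid
#'
#' Nearest grid day; exact ties go to the later day. Used to align the
#' (denser) protein sampling grid with the RNA/ATAC grid.
#'
#' @param day Numeric day(s).
#' @param grid Sorted numeric grid.
#' @return Grid day for each input day.
#' @export
mapToGrid <- function(day, grid) {
  grid <- sort(grid)
  vapply(day, function(d) {
    dd <- abs(grid - d)
    cand <- grid[dd == min(dd)]
    max(cand)  # tie -> later day
  }, numeric(1))
}

#' @noRd
groupLayers <- function(pair_group) {
  switch(pair_group,
         rna_protein = c(source = "rna", target = "protein"),
         atac_tss_rna = c(source = "atac", target = "rna"),
         atac_distal_rna = c(source = "atac", target = "rna"),
         stop("unknown pair group: ", pair_group))
}

#' Enumerate the admissible association test grid
#'
#' For each pair group, all (source contrast, target contrast, direction
#' combination) cells that survive the two filters: the central-dogma
#' flow (the source layer precedes the target layer: ATAC -> RNA ->
#' protein, enforced by the group definition) and time order (the target
#' contrast's late day, mapped to the RNA/ATAC grid, is the same as or
#' later than the source contrast's mapped late day).
#'
#' @param contrasts data.frame with `layer`, `day_late`, `day_early`
#'   listing the available contrasts per layer.
#' @param pairGroups Pair groups to enumerate (default all three).
#' @return data.frame with one row per admissible cell: `pair_group`,
#'   source/target contrast days and `dir_source`, `dir_target`.
#' @export
admissibleCells <- function(contrasts,
                            pairGroups = PAIR_GROUPS) {
  grid <- sort(unique(contrasts$day_late[contrasts$layer %in%
                                           c("rna", "atac")]))
  out <- list()
  for (pg in pairGroups) {
    lay <- groupLayers(pg)
    src <- contrasts[contrasts$layer == lay[["source"]], , drop = FALSE]
    tgt <- contrasts[contrasts$layer == lay[["target"]], , drop = FALSE]
    if (nrow(src) == 0L || nrow(tgt) == 0L) next
    for (i in seq_len(nrow(src))) {
      s_late <- mapToGrid(src$day_late[i], grid)
      for (j in seq_len(nrow(tgt))) {
        t_late <- mapToGrid(tgt$day_late[j], grid)
        if (t_late < s_late) next
        for (ds in c("up", "down")) for (dt in c("up", "down")) {
          out[[length(out) + 1L]] <- data.frame(
            pair_group = pg,
            src_day_late = src$day_late[i], src_day_early = src$day_early[i],
            tgt_day_late = tgt$day_late[j], tgt_day_early = tgt$day_early[j],
            dir_source = ds, dir_target = dt,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Directional time-lagged association scan across molecular layers
#'
#' Runs [buildContingency()] + [fisher2x2()] for every admissible cell
#' (see [admissibleCells()]) and Benjamini-Hochberg-adjusts the p-values
#' within each pair group (the comparison-group-wise correction family).
#' Results are flagged significant at `adj_p < alpha`.
#'
#' @param pairs Linked pairs from [linkLayers()].
#' @param records Differential records covering every (layer, contrast)
#'   in `contrasts` (rows as from [simpleDifferential()] /
#'   [loadDifferential()]).
#' @param contrasts data.frame with `layer`, `day_late`, `day_early`.
#' @param alpha Significance threshold on the adjusted p (default 0.05).
#' @return data.frame with one row per tested cell: the admissible-grid
#'   columns plus `a`, `b`, `c`, `d`, `odds_ratio`, `log2_or`, `p`,
#'   `adj_p`, `significant`.
#' @export
associationScan <- function(pairs, records, contrasts, alpha = 0.05) {
  cells <- admissibleCells(contrasts,
                           pairGroups = intersect(PAIR_GROUPS,
                                                  unique(pairs$pair_group)))
  res <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    lay <- groupLayers(cell$pair_group)
    pu <- pairs[pairs$pair_group == cell$pair_group, , drop = FALSE]
    srec <- records[records$layer == lay[["source"]] &
                      records$day_late == cell$src_day_late &
                      records$day_early == cell$src_day_early, , drop = FALSE]
    trec <- records[records$layer == lay[["target"]] &
                      records$day_late == cell$tgt_day_late &
                      records$day_early == cell$tgt_day_early, , drop = FALSE]
    tab <- buildContingency(pu, srec, trec, cell$dir_source, cell$dir_target)
    fish <- fisher2x2(tab$a, tab$b, tab$c, tab$d)
    res[[i]] <- cbind(cell,
                      data.frame(a = tab$a, b = tab$b, c = tab$c, d = tab$d,
                                 odds_ratio = fish$odds_ratio,
                                 log2_or = fish$log2_or, p = fish$p))
  }
  out <- do.call(rbind, res)
  out$adj_p <- NA_real_
  for (pg in unique(out$pair_group)) {
    sel <- out$pair_group == pg
    out$adj_p[sel] <- bhAdjust(out$p[sel])
  }
  out$significant <- out$adj_p < alpha
  rownames(out) <- NULL
  out
}
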