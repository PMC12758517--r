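# Peak-gene linkage with background-matched null correlations, DEG/DAP
# categorization, stage transitions and newly-formed linked-DAP peak sets.

#' Link peaks to genes within a TSS window via background-matched correlation
#'
#' For every (gene, peak) pair whose peak midpoint lies within `distance` bp
#' of the gene's TSS, the Pearson correlation `r` between the peak's
#' depth-scaled accessibility and the gene's normalized expression is computed
#' across all cells (the entire dataset, all cell types pooled). A null
#' distribution is built from `n_background` peaks matched to the focal peak
#' on GC fraction, mean accessibility and width (nearest neighbours in
#' standardized 3-feature space, sampled without replacement under the fixed
#' seed), excluding peaks within the gene's linkage window; the link's
#' `z = (r - mean(null)) / sd(null)` with a two-sided normal p. Links with
#' `p < p_cutoff` are retained, both signs.
#'
#' @param atac [CountMatrix-class] of raw peak counts (rows follow `peaks`).
#' @param rna_normalized normalized expression matrix ([normalizeCounts()]).
#' @param peaks `GRanges` parallel to `atac` rows, named by peak id.
#' @param gene_models gene model data.frame (gene_id, chrom, tss).
#' @param genome `DNAStringSet` for GC computation.
#' @param genes gene ids to link (default: all genes in `rna_normalized`).
#' @param distance TSS window in bp (default 500000).
#' @param n_background background peaks per focal peak (default 200).
#' @param p_cutoff retention threshold (default 0.05).
#' @param seed seed for background sampling.
#' @return data.frame of retained links: peak_id, gene_id, r, z, p_value,
#'   distance_bp, sign; attribute `"skipped"` lists zero-variance skips.
#' @export
linkPeaks <- function(atac, rna_normalized, peaks, gene_models, genome,
                      genes = NULL, distance = 500000, n_background = 200,
                      p_cutoff = 0.05, seed = 1) {
  am <- if (is(atac, "CountMatrix")) counts(atac) else atac
  rm_ <- rna_normalized
  if (!identical(colnames(am), colnames(rm_)))
    stopf("atac and rna matrices must share the identical ordered cell list")
  if (is.null(genes)) genes <- intersect(rownames(rm_), gene_models$gene_id)
  genes <- intersect(genes, gene_models$gene_id)
  nCell <- ncol(am)

  ## depth-scale peak counts to remove library-size-driven correlation
  depth <- Matrix::colSums(am)
  med <- stats::median(depth[depth > 0])
  P <- am %*% Matrix::Diagonal(x = ifelse(depth > 0, med / depth, 0))
  rowMean <- Matrix::rowMeans(P)
  rowSq <- Matrix::rowSums(P^2)
  rowSd <- sqrt(pmax(0, (rowSq - nCell * rowMean^2) / (nCell - 1)))

  ## peak features for background matching
  feat <- cbind(gc = peakGC(peaks, genome), acc = rowMean,
                width = GenomicRanges::width(peaks))
  featZ <- scale(feat)
  featZ[is.nan(featZ)] <- 0

  mids <- GenomicRanges::start(peaks) - 1L +
    floor((GenomicRanges::width(peaks)) / 2)
  peakChrom <- as.character(GenomicRanges::seqnames(peaks))
  peakIds <- names(peaks)

  skipped <- list()
  out <- list()
  withSubstream(seed, "linkpeaks", {
    for (g in genes) {
      gi <- match(g, gene_models$gene_id)
      tss <- gene_models$tss[gi]
      chrom <- gene_models$chrom[gi]
      inWindow <- which(peakChrom == chrom & abs(mids - tss) <= distance)
      if (!length(inWindow)) next
      e <- as.numeric(rm_[g, ])
      if (stats::sd(e) == 0) {
        skipped[[length(skipped) + 1]] <- data.frame(
          peak_id = NA, gene_id = g, reason = "zero-variance gene")
        next
      }
      eC <- e - mean(e)
      eN <- sqrt(sum(eC^2))
      ## correlation of this gene with every peak in one sparse matvec:
      ## num = sum(x * (y - mean(y))) = (n-1) * cov(x, y)
      num <- as.numeric(P %*% eC)
      rAll <- num / (pmax(rowSd, .Machine$double.eps) * eN * sqrt(nCell - 1))
      pool <- which(!(peakChrom == chrom & abs(mids - tss) <= distance))
      for (pi in inWindow) {
        if (rowSd[pi] == 0) {
          skipped[[length(skipped) + 1]] <- data.frame(
            peak_id = peakIds[pi], gene_id = g, reason = "zero-variance peak")
          next
        }
        usable <- pool[rowSd[pool] > 0]
        if (!length(usable)) next
        nb <- min(n_background, length(usable))
        if (nb < n_background)
          warnf("background pool (%d) smaller than n_background (%d); using all",
                length(usable), n_background)
        d2 <- (featZ[usable, 1] - featZ[pi, 1])^2 +
              (featZ[usable, 2] - featZ[pi, 2])^2 +
              (featZ[usable, 3] - featZ[pi, 3])^2
        cand <- usable[order(d2)][seq_len(min(3 * nb, length(usable)))]
        bg <- if (length(cand) > nb) sample(cand, nb) else cand
        rb <- rAll[bg]
        mu <- mean(rb); sdv <- stats::sd(rb)
        if (!is.finite(sdv) || sdv == 0) next
        z <- (rAll[pi] - mu) / sdv
        p <- 2 * stats::pnorm(-abs(z))
        if (p < p_cutoff)
          out[[length(out) + 1]] <- data.frame(
            peak_id = peakIds[pi], gene_id = g, r = rAll[pi], z = z,
            p_value = p, distance_bp = abs(mids[pi] - tss),
            sign = if (rAll[pi] >= 0) "positive" else "negative",
            stringsAsFactors = FALSE)
      }
    }
  })
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(peak_id = character(0), gene_id = character(0), r = numeric(0),
               z = numeric(0), p_value = numeric(0), distance_bp = numeric(0),
               sign = character(0), stringsAsFactors = FALSE)
  attr(res, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else NULL
  res
}

asIds <- function(x, col) {
  if (is.data.frame(x)) as.character(x[[col]]) else as.character(x)
}

#' Categorize DEGs by their significantly linked peaks
#'
#' A DEG is `linked_DAP` when at least one of its significant links is to a
#' DAP of the same contrast; `linked_nonDAP` when it has significant links but
#' none to a DAP; `no_linked_peak` otherwise. `supporting_peaks` lists the
#' linked DAPs (first category) or all linked peaks (second).
#'
#' @param degs DEG ids (character) or a [wilcoxonDEG()] result.
#' @param daps DAP peak ids (character) or an [lrDAP()] result.
#' @param links data.frame from [linkPeaks()].
#' @return data.frame gene_id, category, supporting_peaks (';'-joined).
#' @export
categorizeDegs <- function(degs, daps, links) {
  degIds <- asIds(degs, "feature_id")
  dapIds <- asIds(daps, "feature_id")
  rows <- lapply(degIds, function(g) {
    lp <- links$peak_id[links$gene_id == g]
    if (!length(lp))
      return(data.frame(gene_id = g, category = "no_linked_peak",
                        supporting_peaks = "", stringsAsFactors = FALSE))
    lDap <- intersect(lp, dapIds)
    if (length(lDap))
      data.frame(gene_id = g, category = "linked_DAP",
                 supporting_peaks = paste(lDap, collapse = ";"),
                 stringsAsFactors = FALSE)
    else
      data.frame(gene_id = g, category = "linked_nonDAP",
                 supporting_peaks = paste(unique(lp), collapse = ";"),
                 stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Categorize DAPs by their significantly linked genes (mirror image)
#'
#' @param daps DAP peak ids or [lrDAP()] result.
#' @param degs DEG ids or [wilcoxonDEG()] result.
#' @param links data.frame from [linkPeaks()].
#' @return data.frame peak_id, category in
#'   {linked_DEG, linked_nonDEG, no_linked_gene}, supporting_genes.
#' @export
annotateDaps <- function(daps, degs, links) {
  dapIds <- asIds(daps, "feature_id")
  degIds <- asIds(degs, "feature_id")
  rows <- lapply(dapIds, function(p) {
    lg <- links$gene_id[links$peak_id == p]
    if (!length(lg))
      return(data.frame(peak_id = p, category = "no_linked_gene",
                        supporting_genes = "", stringsAsFactors = FALSE))
    lDeg <- intersect(lg, degIds)
    if (length(lDeg))
      data.frame(peak_id = p, category = "linked_DEG",
                 supporting_genes = paste(lDeg, collapse = ";"),
                 stringsAsFactors = FALSE)
    else
      data.frame(peak_id = p, category = "linked_nonDEG",
                 supporting_genes = paste(unique(lg), collapse = ";"),
                 stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Track DEG category transitions between two stages
#'
#' One record per gene in the union of the two categorizations; genes absent
#' at a stage get category `"absent"`. The flow table counts each
#' (category_t1, category_t2) pair, and the conversion rate reports the
#' fraction of stage-1 `linked_nonDAP` genes that become `linked_DAP`.
#'
#' @param categories_t1,categories_t2 results of [categorizeDegs()].
#' @return list with `records`, `flows` (data.frame with counts) and
#'   `conversion_rate`.
#' @export
trackTransitions <- function(categories_t1, categories_t2) {
  allGenes <- union(categories_t1$gene_id, categories_t2$gene_id)
  c1 <- categories_t1$category[match(allGenes, categories_t1$gene_id)]
  c2 <- categories_t2$category[match(allGenes, categories_t2$gene_id)]
  c1[is.na(c1)] <- "absent"; c2[is.na(c2)] <- "absent"
  records <- data.frame(gene_id = allGenes, category_t1 = c1,
                        category_t2 = c2,
                        flow = paste(c1, c2, sep = "->"),
                        stringsAsFactors = FALSE)
  flows <- as.data.frame(table(category_t1 = c1, category_t2 = c2),
                         stringsAsFactors = FALSE)
  flows <- flows[flows$Freq > 0, ]
  names(flows)[3] <- "count"
  nTeal <- sum(c1 == "linked_nonDAP")
  conv <- if (nTeal > 0)
    sum(c1 == "linked_nonDAP" & c2 == "linked_DAP") / nTeal else NA_real_
  list(records = records, flows = flows, conversion_rate = conv)
}

#' Newly formed linked-DAP peak set at the later stage
#'
#' The unique DAPs linked (at t2) to genes whose t2 category is `linked_DAP`
#' and whose t1 category is anything else (including `absent`): conversions
#' from `linked_nonDAP` plus de novo appearances, excluding genes that were
#' already `linked_DAP` at t1.
#'
#' @param categories_t1,categories_t2 results of [categorizeDegs()].
#' @param links_t2 [linkPeaks()] result at the later stage.
#' @param daps_t2 DAP ids (or [lrDAP()] result) at the later stage.
#' @return list with `peak_ids` (unique), `genes`, and `by_origin` (count of
#'   contributing genes per t1 category).
#' @export
newlyFormedLinkedDaps <- function(categories_t1, categories_t2, links_t2,
                                  daps_t2) {
  dapIds <- asIds(daps_t2, "feature_id")
  tr <- trackTransitions(categories_t1, categories_t2)$records
  newly <- tr[tr$category_t2 == "linked_DAP" & tr$category_t1 != "linked_DAP", ]
  pk <- unique(links_t2$peak_id[links_t2$gene_id %in% newly$gene_id &
                                links_t2$peak_id %in% dapIds])
  list(peak_ids = pk, genes = newly$gene_id,
       by_origin = table(newly$category_t1))
}
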