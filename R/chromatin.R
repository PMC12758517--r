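# Peak annotation to genomic features, region accessibility per cell and
# histone-mark overlap / bivalency of DAP sets.

#' Annotate peaks to genomic features
#'
#' Each peak is assigned exactly one feature based on its midpoint, with
#' precedence promoter (TSS +/- `promoter_window`) > exon > first_intron >
#' other_intron > downstream (<= `downstream_window` past the 3' end) >
#' distal_intergenic. Strand is respected for first-intron ordering and the
#' downstream window.
#'
#' @param peaks `GRanges` of peaks (names = peak ids).
#' @param gene_models data.frame with gene_id, chrom, strand, tss, span_start,
#'   span_end (0-based half-open span).
#' @param exons data.frame with gene_id, exon_rank, start, end (0-based
#'   half-open).
#' @param promoter_window bp around the TSS (default 3000).
#' @param downstream_window bp past the 3' end (default 3000).
#' @return data.frame peak_id, feature, nearest_gene, distance_to_tss
#'   (signed bp, midpoint minus TSS).
#' @export
annotatePeaks <- function(peaks, gene_models, exons = NULL,
                          promoter_window = 3000, downstream_window = 3000) {
  mids <- GenomicRanges::start(peaks) - 1L +
    floor(GenomicRanges::width(peaks) / 2)
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  ids <- if (is.null(names(peaks))) as.character(seq_along(peaks)) else names(peaks)
  if (is.null(gene_models) || !nrow(gene_models)) {
    warnf("empty gene annotation: all peaks assigned distal_intergenic")
    return(data.frame(peak_id = ids, feature = "distal_intergenic",
                      nearest_gene = NA_character_,
                      distance_to_tss = NA_real_, stringsAsFactors = FALSE))
  }
  res <- lapply(seq_along(peaks), function(i) {
    m <- mids[i]
    onChrom <- gene_models[gene_models$chrom == chrom[i], , drop = FALSE]
    if (!nrow(onChrom))
      return(data.frame(peak_id = ids[i], feature = "distal_intergenic",
                        nearest_gene = NA_character_,
                        distance_to_tss = NA_real_, stringsAsFactors = FALSE))
    dTss <- m - onChrom$tss
    nearest <- which.min(abs(dTss))
    feature <- "distal_intergenic"
    gHit <- NA_integer_
    ## promoter: any gene with |mid - tss| <= window
    prom <- which(abs(dTss) <= promoter_window)
    if (length(prom)) {
      feature <- "promoter"; gHit <- prom[which.min(abs(dTss[prom]))]
    } else {
      inside <- which(m >= onChrom$span_start & m < onChrom$span_end)
      if (length(inside)) {
        gHit <- inside[which.min(abs(dTss[inside]))]
        g <- onChrom$gene_id[gHit]
        ex <- if (is.null(exons)) NULL else
          exons[exons$gene_id == g, , drop = FALSE]
        inExon <- !is.null(ex) && nrow(ex) &&
          any(m >= ex$start & m < ex$end)
        if (inExon) feature <- "exon"
        else if (!is.null(ex) && nrow(ex) >= 2) {
          ## first intron sits between exon ranks 1 and 2 (strand-aware)
          ex <- ex[order(ex$exon_rank), , drop = FALSE]
          fi <- if (onChrom$strand[gHit] == "+")
            c(ex$end[1], ex$start[2]) else c(ex$end[nrow(ex) - 1], ex$start[nrow(ex)])
          fi <- sort(fi)
          feature <- if (m >= fi[1] && m < fi[2]) "first_intron" else "other_intron"
        } else feature <- "other_intron"
      } else {
        ## downstream: within window past the 3' end, strand-aware
        down <- which(ifelse(onChrom$strand == "+",
                             m >= onChrom$span_end &
                               m < onChrom$span_end + downstream_window,
                             m < onChrom$span_start &
                               m >= onChrom$span_start - downstream_window))
        if (length(down)) {
          feature <- "downstream"
          gHit <- down[which.min(abs(dTss[down]))]
        }
      }
    }
    gi <- if (!is.na(gHit)) gHit else nearest
    data.frame(peak_id = ids[i], feature = feature,
               nearest_gene = onChrom$gene_id[gi],
               distance_to_tss = dTss[gi], stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Per-cell summed accessibility within a region set
#'
#' Peaks of the count matrix are matched to the region set by >= 1 bp overlap;
#' each cell's value is the sum of counts over matched peaks.
#'
#' @param atac [CountMatrix-class] of peak counts.
#' @param peaks `GRanges` parallel to `atac` rows.
#' @param region_set `GRanges` of target regions.
#' @param cells optional barcode subset.
#' @param group optional named group label per barcode for the per-group mean.
#' @return list with `per_cell` (data.frame barcode, summed_counts, group) and
#'   `group_means` (named numeric or NULL).
#' @export
countsInRegion <- function(atac, peaks, region_set, cells = NULL,
                           group = NULL) {
  m <- counts(atac)
  if (is.null(cells)) cells <- colnames(m)
  hit <- if (length(region_set)) which(IRanges::overlapsAny(peaks, region_set))
         else integer(0)
  vals <- if (length(hit))
    Matrix::colSums(m[hit, cells, drop = FALSE])
  else setNames(numeric(length(cells)), cells)
  df <- data.frame(barcode = cells, summed_counts = as.numeric(vals),
                   stringsAsFactors = FALSE)
  gm <- NULL
  if (!is.null(group)) {
    df$group <- group[cells]
    gm <- tapply(df$summed_counts, df$group, mean)
  }
  list(per_cell = df, group_means = gm)
}

#' Compare per-cell region accessibility between two groups
#'
#' Two-sided Wilcoxon rank-sum (the differential module's core) on the summed
#' counts of two cell groups.
#'
#' @param values_a,values_b numeric per-cell summed counts (>= 2 each).
#' @return list with `p_value`, `median_a`, `median_b`.
#' @export
compareRegionAccessibility <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stopf("each group needs >= 2 cells")
  list(p_value = rankSumTest(values_a, values_b),
       median_a = stats::median(values_a), median_b = stats::median(values_b))
}

#' Histone-mark overlap percentage of a DAP set
#'
#' A DAP is mark-positive iff it overlaps >= 1 ChIP interval by >= 1 bp.
#'
#' @param dap_set `GRanges` of DAPs (non-empty).
#' @param chip_peaks `GRanges` of ChIP intervals for one (mark, cell state).
#' @param dap_set_id,mark,cell_state labels carried into the result.
#' @return data.frame with dap_set_id, mark, cell_state, percent_positive,
#'   n_overlapping, n_total.
#' @export
histoneOverlap <- function(dap_set, chip_peaks, dap_set_id = "dap_set",
                           mark = NA_character_, cell_state = NA_character_) {
  if (!length(dap_set)) stopf("empty DAP set: overlap percentage undefined")
  nOv <- sum(IRanges::overlapsAny(dap_set, chip_peaks))
  data.frame(dap_set_id = dap_set_id, mark = mark, cell_state = cell_state,
             percent_positive = 100 * nOv / length(dap_set),
             n_overlapping = nOv, n_total = length(dap_set),
             stringsAsFactors = FALSE)
}

#' Bivalent peaks: DAPs overlapping both H3K4me3 and H3K27me3
#'
#' @param dap_set `GRanges` of DAPs.
#' @param k4me3_set,k27me3_set `GRanges` ChIP interval sets.
#' @param links optional [linkPeaks()] result to report linked genes.
#' @return list with `peaks` (`GRanges` subset) and `linked_genes`
#'   (data.frame peak_id, gene_id; NULL without `links`).
#' @export
bivalentPeaks <- function(dap_set, k4me3_set, k27me3_set, links = NULL) {
  biv <- dap_set[IRanges::overlapsAny(dap_set, k4me3_set) &
                 IRanges::overlapsAny(dap_set, k27me3_set)]
  lg <- NULL
  if (!is.null(links) && length(biv) && !is.null(names(biv))) {
    lg <- links[links$peak_id %in% names(biv), c("peak_id", "gene_id")]
    rownames(lg) <- NULL
  }
  list(peaks = biv, linked_genes = lg)
}
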