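# Per-cell QC gates, peak filters, rank-based module scoring and the
# computational sex filter.

checkMetrics <- function(cells, cols) {
  for (cl in cols) {
    if (!cl %in% colnames(cells)) stopf("missing per-cell metric '%s'", cl)
    bad <- which(is.na(cells[[cl]]))
    if (length(bad))
      stopf("metric '%s' missing for barcode %s", cl, cells$barcode[bad[1]])
  }
}

#' RNA-side per-cell QC gate
#'
#' Keeps cells with `nCount_RNA > 1000`, `nCount_RNA < 25000` and
#' `percent.mt < 25` (all strict inequalities).
#'
#' @param cells per-cell metadata with columns `barcode`, `n_count_rna`,
#'   `percent_mt`.
#' @param min_count,max_count,max_percent_mt gate thresholds.
#' @return character vector of kept barcodes.
#' @export
applyRnaQC <- function(cells, min_count = 1000, max_count = 25000,
                       max_percent_mt = 25) {
  cells <- as.data.frame(cells)
  checkMetrics(cells, c("n_count_rna", "percent_mt"))
  keep <- cells$n_count_rna > min_count & cells$n_count_rna < max_count &
          cells$percent_mt < max_percent_mt
  cells$barcode[keep]
}

#' ATAC-side per-cell QC gate
#'
#' Keeps cells with `nCount_ATAC > 1000`, `nCount_ATAC < 100000`,
#' `nucleosome_signal < 2` and `TSS.enrichment > 1` (all strict).
#'
#' @param cells per-cell metadata with columns `barcode`, `n_count_atac`,
#'   `nucleosome_signal`, `tss_enrichment`.
#' @param min_count,max_count,max_nucleosome_signal,min_tss_enrichment gates.
#' @return character vector of kept barcodes.
#' @export
applyAtacQC <- function(cells, min_count = 1000, max_count = 100000,
                        max_nucleosome_signal = 2, min_tss_enrichment = 1) {
  cells <- as.data.frame(cells)
  checkMetrics(cells, c("n_count_atac", "nucleosome_signal", "tss_enrichment"))
  keep <- cells$n_count_atac > min_count & cells$n_count_atac < max_count &
          cells$nucleosome_signal < max_nucleosome_signal &
          cells$tss_enrichment > min_tss_enrichment
  cells$barcode[keep]
}

#' Merge, size-filter and blacklist-filter a peak set
#'
#' Overlapping peaks are first union-reduced into a combined set; peaks are
#' then required to have width strictly greater than `min_width` and strictly
#' less than `max_width`; any peak overlapping the blacklist by >= 1 bp is
#' dropped; peaks on chromosomes outside `allowed_chromosomes` (when given)
#' are dropped.
#'
#' @param peaks `GRanges` of called peaks.
#' @param blacklist optional `GRanges` of excluded regions.
#' @param min_width,max_width strict size gates in bp (defaults 20 / 10000).
#' @param allowed_chromosomes optional character vector of standard
#'   chromosome names.
#' @return filtered `GRanges` (names regenerated as chrom-start-end).
#' @export
filterPeaks <- function(peaks, blacklist = NULL, min_width = 20,
                        max_width = 10000, allowed_chromosomes = NULL) {
  merged <- GenomicRanges::reduce(peaks)
  w <- GenomicRanges::width(merged)
  merged <- merged[w > min_width & w < max_width]
  if (!is.null(blacklist) && length(blacklist))
    merged <- merged[!IRanges::overlapsAny(merged, blacklist)]
  if (!is.null(allowed_chromosomes))
    merged <- merged[as.character(GenomicRanges::seqnames(merged)) %in%
                     allowed_chromosomes]
  names(merged) <- sprintf("%s-%d-%d",
                           as.character(GenomicRanges::seqnames(merged)),
                           GenomicRanges::start(merged) - 1L,
                           GenomicRanges::end(merged))
  merged
}

#' Rank-based per-cell module score for a gene signature
#'
#' For each cell, genes are ranked by descending expression (average ranks for
#' ties), ranks are capped at `r_max`, and the score is
#' `1 - U' / (|S| * r_max)` with
#' `U' = sum over signature genes of min(rank, r_max) - |S|(|S|+1)/2`.
#' The score lies in `[0, 1]` and is invariant under any monotone transform of
#' a cell's expression vector.
#'
#' @param rna a [CountMatrix-class] or matrix (genes x cells); raw or
#'   normalized values give identical scores.
#' @param gene_set character vector of signature gene ids.
#' @param r_max rank cap (default 1500).
#' @return data.frame with columns `barcode`, `score`.
#' @export
moduleScore <- function(rna, gene_set, r_max = 1500) {
  m <- if (is(rna, "CountMatrix")) counts(rna) else rna
  if (!length(gene_set)) stopf("gene_set must not be empty")
  missing <- setdiff(gene_set, rownames(m))
  if (length(missing)) {
    warnf("%d signature gene(s) absent from matrix and dropped: %s",
          length(missing), paste(missing, collapse = ", "))
    gene_set <- setdiff(gene_set, missing)
  }
  if (!length(gene_set)) stopf("no signature gene present in the matrix")
  s <- length(gene_set)
  sIdx <- match(gene_set, rownames(m))
  dense <- as.matrix(m)
  scores <- vapply(seq_len(ncol(dense)), function(j) {
    r <- rank(-dense[, j], ties.method = "average")
    u <- sum(pmin(r[sIdx], r_max)) - s * (s + 1) / 2
    1 - u / (s * r_max)
  }, numeric(1))
  data.frame(barcode = colnames(dense), score = scores,
             stringsAsFactors = FALSE)
}

#' Computational sex filter
#'
#' Verifies the chromosomal sex of each cell against its declared label using
#' a Y-linked gene module score and ATAC fragments in the chrY peak region.
#' Cutoffs come from the reference stage: for XY datasets, 1 SD (times
#' `sd_multiplier`) below the mean score of XY reference-stage cells; for XX
#' datasets, 1 SD above the mean score of XX reference-stage cells.
#' Non-reference cells are removed from XY datasets when they have 0 chrY
#' fragments AND score strictly below the XY cutoff; from XX datasets when
#' they have > 0 chrY fragments OR score strictly above the XX cutoff.
#' Reference-stage cells (which define the cutoffs) are kept unfiltered.
#'
#' @param scores data.frame from [moduleScore()] on the Y-linked gene set.
#' @param cells per-cell metadata with `barcode`, `declared_sex`, `stage`,
#'   `chry_fragments`.
#' @param reference_stage stage defining the cutoffs (default `"E13.5"`).
#' @param sd_multiplier positive multiplier on the SD (default 1).
#' @return list with `kept` (barcodes), `removed` (barcodes),
#'   `cutoff_xy`, `cutoff_xx`.
#' @export
sexFilter <- function(scores, cells, reference_stage = "E13.5",
                      sd_multiplier = 1) {
  if (sd_multiplier <= 0) stopf("sd_multiplier must be > 0")
  cells <- as.data.frame(cells)
  checkMetrics(cells, c("declared_sex", "stage", "chry_fragments"))
  sc <- scores$score[match(cells$barcode, scores$barcode)]
  if (anyNA(sc)) stopf("module score missing for some barcodes")
  refXY <- sc[cells$stage == reference_stage & cells$declared_sex == "XY"]
  refXX <- sc[cells$stage == reference_stage & cells$declared_sex == "XX"]
  if (length(refXY) < 2 || length(refXX) < 2)
    stopf("need >= 2 reference-stage cells per sex to define cutoffs")
  cutoffXY <- mean(refXY) - sd_multiplier * stats::sd(refXY)
  cutoffXX <- mean(refXX) + sd_multiplier * stats::sd(refXX)
  isRef <- cells$stage == reference_stage
  removeXY <- cells$declared_sex == "XY" & !isRef &
    cells$chry_fragments == 0 & sc < cutoffXY
  removeXX <- cells$declared_sex == "XX" & !isRef &
    (cells$chry_fragments > 0 | sc > cutoffXX)
  removed <- removeXY | removeXX
  list(kept = cells$barcode[!removed], removed = cells$barcode[removed],
       cutoff_xy = cutoffXY, cutoff_xx = cutoffXX)
}

#' Marker-based cell type annotation
#'
#' Scores every marker set with [moduleScore()] and assigns each cell the
#' arg-max type; exact ties are broken by lexicographic type name and flagged.
#'
#' @param rna a [CountMatrix-class] or matrix (genes x cells).
#' @param marker_sets named list mapping cell-type label to marker gene ids.
#' @param r_max rank cap passed to [moduleScore()].
#' @return data.frame with `barcode`, `cell_type`, `tie` (logical).
#' @export
annotateCellTypes <- function(rna, marker_sets, r_max = 1500) {
  if (!length(marker_sets)) stopf("marker_sets must not be empty")
  if (any(!lengths(marker_sets))) stopf("each marker set must be non-empty")
  types <- sort(names(marker_sets))
  scoreMat <- vapply(types, function(ty)
    moduleScore(rna, marker_sets[[ty]], r_max)$score,
    numeric(ncol(if (is(rna, "CountMatrix")) counts(rna) else rna)))
  scoreMat <- matrix(scoreMat, ncol = length(types),
                     dimnames = list(NULL, types))
  best <- apply(scoreMat, 1, function(v) which(v == max(v)))
  assigned <- vapply(best, function(ix) types[min(ix)], character(1))
  tie <- vapply(best, function(ix) length(ix) > 1, logical(1))
  bcs <- if (is(rna, "CountMatrix")) barcodes(rna) else colnames(rna)
  data.frame(barcode = bcs, cell_type = assigned, tie = tie,
             stringsAsFactors = FALSE)
}
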