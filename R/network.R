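# chromVAR-style per-cell motif activity, TF->target network assembly and the
# motif co-occurrence matrix.

#' Per-cell motif activity deviations (chromVAR-style)
#'
#' For each motif's peak set M, the expected count of cell i is
#' `E_i = (sum of M's peak totals) * depth_i / total`, the raw deviation
#' `(X_iM - E_i) / E_i`, and the z-score corrects against `n_background_sets`
#' size-|M| peak sets matched to M's members on GC and mean accessibility:
#' `z_i = (raw_i - mean(bg raw_i)) / sd(bg raw_i)`. Cells with `E_i = 0` are
#' masked (NA) and flagged.
#'
#' @param atac [CountMatrix-class] of raw peak counts.
#' @param annotation logical peak x motif matrix (rownames = peak ids), e.g.
#'   built from [scanPeaks()] results.
#' @param peaks `GRanges` parallel to `atac` rows.
#' @param genome `DNAStringSet`.
#' @param n_background_sets number of matched background sets (default 50).
#' @param n_neighbors per-peak matched candidate pool size (default 50).
#' @param seed seed for background sampling.
#' @return list with `z` and `raw` (cells x motifs matrices) and
#'   `masked_cells` (barcodes with zero expectation).
#' @export
chromVarDeviations <- function(atac, annotation, peaks, genome,
                               n_background_sets = 50, n_neighbors = 50,
                               seed = 1) {
  m <- counts(atac)
  if (is.null(rownames(annotation)) ||
      !all(rownames(annotation) %in% rownames(m)))
    stopf("annotation rownames must be peak ids present in the atac matrix")
  depth <- Matrix::colSums(m)
  total <- sum(depth)
  rowTot <- Matrix::rowSums(m)
  feat <- scale(cbind(peakGC(peaks, genome),
                      Matrix::rowMeans(m %*% Matrix::Diagonal(
                        x = ifelse(depth > 0, stats::median(depth[depth > 0]) / depth, 0)))))
  feat[is.nan(feat)] <- 0
  nP <- nrow(m)
  rawFor <- function(rows) {
    X <- Matrix::colSums(m[rows, , drop = FALSE])
    E <- sum(rowTot[rows]) * depth / total
    ifelse(E > 0, (X - E) / E, NA_real_)
  }
  motifs <- colnames(annotation)
  zMat <- rawMat <- matrix(NA_real_, ncol(m), length(motifs),
                           dimnames = list(colnames(m), motifs))
  masked <- character(0)
  withSubstream(seed, "chromvar", {
    for (mo in motifs) {
      rows <- match(rownames(annotation)[annotation[, mo]], rownames(m))
      if (!length(rows)) next
      raw <- rawFor(rows)
      ## per-member nearest-neighbour candidate pools (member excluded)
      nbr <- lapply(rows, function(r) {
        d2 <- (feat[, 1] - feat[r, 1])^2 + (feat[, 2] - feat[r, 2])^2
        d2[r] <- Inf
        order(d2)[seq_len(min(n_neighbors, nP - 1))]
      })
      bgRaw <- matrix(0, ncol(m), n_background_sets)
      for (b in seq_len(n_background_sets)) {
        bgRows <- vapply(nbr, function(cand) cand[sample.int(length(cand), 1)],
                         integer(1))
        bgRaw[, b] <- rawFor(bgRows)
      }
      mu <- rowMeans(bgRaw)
      sdv <- apply(bgRaw, 1, stats::sd)
      rawMat[, mo] <- raw
      zMat[, mo] <- ifelse(is.finite(raw) & sdv > 0, (raw - mu) / sdv, NA_real_)
      masked <- union(masked, colnames(m)[!is.finite(raw)])
    }
  })
  list(z = zMat, raw = rawMat, masked_cells = masked)
}

#' Assemble the TF -> target regulatory network
#'
#' For each motif passing enrichment whose TF gene is a DEG in the focal
#' contrast, an edge is drawn to every gene significantly linked to a focal
#' DAP that contains a hit of that motif; the edge sign is the link sign.
#' Enriched motifs whose TF gene is absent from the expression matrix are
#' excluded and logged in the `excluded_tfs` attribute.
#'
#' @param enrichment [motifEnrichment()] result; motif `name` is taken from
#'   `motif_names` (named by motif_id) or from the hits.
#' @param degs DEG ids or [wilcoxonDEG()] result for the focal contrast.
#' @param hits [scanPeaks()] results row-bound over motifs.
#' @param links [linkPeaks()] result.
#' @param daps DAP ids or [lrDAP()] result.
#' @param motif_names named character: TF gene name per motif_id.
#' @param expressed_genes optional gene universe (e.g. rownames of the RNA
#'   matrix); TFs outside it are excluded.
#' @return data.frame tf, target, sign, peak_id, hit_chrom, hit_start,
#'   hit_end, hit_strand; attribute `excluded_tfs`.
#' @export
buildRegulatoryNetwork <- function(enrichment, degs, hits, links, daps,
                                   motif_names, expressed_genes = NULL) {
  degIds <- asIds(degs, "feature_id")
  dapIds <- asIds(daps, "feature_id")
  passing <- enrichment$motif_id[enrichment$passes]
  excluded <- character(0)
  out <- list()
  for (mo in passing) {
    tf <- unname(motif_names[mo])
    if (is.na(tf)) next
    if (!is.null(expressed_genes) && !tf %in% expressed_genes) {
      excluded <- c(excluded, tf)
      next
    }
    if (!tf %in% degIds) next  # enriched motif but TF not a focal DEG
    h <- hits[hits$motif_id == mo & hits$peak_id %in% dapIds, , drop = FALSE]
    if (!nrow(h)) next
    l <- links[links$peak_id %in% h$peak_id, , drop = FALSE]
    if (!nrow(l)) next
    for (r in seq_len(nrow(l))) {
      hp <- h[h$peak_id == l$peak_id[r], , drop = FALSE][1, ]
      out[[length(out) + 1]] <- data.frame(
        tf = tf, target = l$gene_id[r], sign = l$sign[r],
        peak_id = l$peak_id[r], hit_chrom = hp$chrom, hit_start = hp$start,
        hit_end = hp$end, hit_strand = hp$strand, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) unique(do.call(rbind, out)) else
    data.frame(tf = character(0), target = character(0), sign = character(0),
               peak_id = character(0), hit_chrom = character(0),
               hit_start = numeric(0), hit_end = numeric(0),
               hit_strand = character(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "excluded_tfs") <- unique(excluded)
  res
}

#' Motif co-occurrence matrix
#'
#' `value(A, B)` counts the distinct target genes (default scope) or distinct
#' mediating peaks (`scope = "peak"`) supporting both TFs' edges. The matrix
#' is symmetric; the diagonal is the per-TF distinct-target count.
#'
#' @param edges [buildRegulatoryNetwork()] result.
#' @param scope `"gene"` or `"peak"`.
#' @return symmetric integer matrix, TF x TF.
#' @export
motifCooccurrence <- function(edges, scope = c("gene", "peak")) {
  scope <- match.arg(scope)
  key <- if (scope == "gene") "target" else "peak_id"
  tfs <- sort(unique(edges$tf))
  sets <- lapply(tfs, function(tf) unique(edges[[key]][edges$tf == tf]))
  names(sets) <- tfs
  out <- matrix(0L, length(tfs), length(tfs), dimnames = list(tfs, tfs))
  for (a in seq_along(tfs)) for (b in seq_along(tfs))
    out[a, b] <- length(intersect(sets[[a]], sets[[b]]))
  out
}
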