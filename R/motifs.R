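# PWM construction, exact score-distribution thresholds, motif scanning,
# GC-matched background selection and hypergeometric motif enrichment.

#' Convert a PFM to a log-odds PWM
#'
#' Column probabilities are `(count + 4 * pseudocount * background) /
#' (colsum + 4 * pseudocount)` — with a uniform background this adds
#' `pseudocount` to every cell — and the PWM entries are
#' `log2(probability / background)`.
#'
#' @param pfm a PFM as returned by [readJaspar()] (list with `motif_id`,
#'   `name`, `counts`).
#' @param pseudocount per-cell pseudocount under uniform background
#'   (default 0.8).
#' @param background base frequencies (A, C, G, T) summing to 1.
#' @return list with `motif_id`, `name`, `log_odds` (4 x width), `background`,
#'   `pseudocount`, `width`.
#' @export
pfmToPwm <- function(pfm, pseudocount = 0.8,
                     background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  counts <- pfm$counts
  if (any(colSums(counts) <= 0) && pseudocount == 0)
    stopf("zero column with zero pseudocount in motif %s", pfm$motif_id)
  if (abs(sum(background) - 1) > 1e-8) stopf("background must sum to 1")
  colsum <- colSums(counts)
  prob <- sweep(counts + 4 * pseudocount * background, 2,
                colsum + 4 * pseudocount, "/")
  lo <- log2(prob / background)
  rownames(lo) <- c("A", "C", "G", "T")
  list(motif_id = pfm$motif_id, name = pfm$name, log_odds = lo,
       background = background, pseudocount = pseudocount, width = ncol(lo))
}

# Reverse complement of a PWM: columns reversed, A<->T and C<->G rows swapped.
pwmReverseComplement <- function(pwm) {
  lo <- pwm$log_odds[c("T", "G", "C", "A"), rev(seq_len(pwm$width)), drop = FALSE]
  rownames(lo) <- c("A", "C", "G", "T")
  out <- pwm
  out$log_odds <- lo
  out
}

#' Score threshold from the exact null score distribution
#'
#' Computes the exact distribution of PWM scores of random k-mers under the
#' 0-order background by dynamic programming over discretized scores (column
#' scores rounded to multiples of `resolution` and convolved column by
#' column), and returns the smallest discretized score whose upper tail mass
#' is <= `p`.
#'
#' @param pwm from [pfmToPwm()].
#' @param p tail probability in (0, 1]; default 1e-4.
#' @param resolution score bin width (default 0.001).
#' @return the threshold score (numeric scalar).
#' @export
scoreThreshold <- function(pwm, p = 1e-4, resolution = 0.001) {
  if (p <= 0 || p > 1) stopf("p must lie in (0, 1]")
  ## per-column scores are discretized with ceiling so the binned score of
  ## any k-mer is >= its continuous score: the returned threshold is then
  ## conservative against full-precision scanning (true tail mass <= p)
  bins <- ceiling(pwm$log_odds / resolution)  # 4 x width integer bins
  bg <- pwm$background
  ## distribution over discretized scores, shifted so the minimum-so-far maps
  ## to index 1 after each convolved column
  dist <- 1
  minSo <- 0L
  for (j in seq_len(pwm$width)) {
    colMin <- min(bins[, j]); colMax <- max(bins[, j])
    nxt <- numeric(length(dist) + colMax - colMin)
    for (b in 1:4) {
      s <- bins[b, j] - colMin
      nxt[seq_along(dist) + s] <- nxt[seq_along(dist) + s] + dist * bg[b]
    }
    dist <- nxt
    minSo <- minSo + colMin
  }
  tail <- rev(cumsum(rev(dist)))
  idx <- which(tail <= p + 1e-12)
  ## when even the maximal score has tail mass > p (e.g. an uninformative
  ## column set), fall back to the maximal achievable score so that a perfect
  ## consensus match still passes
  bin <- if (length(idx)) (min(idx) - 1L + minSo) else (minSo + length(dist) - 1L)
  bin * resolution
}

encodeSeq <- function(seqChar) {
  code <- match(seqChar, c("A", "C", "G", "T"))
  code[is.na(code)] <- 0L
  code
}

scanOneStrand <- function(code, lo, threshold) {
  w <- ncol(lo)
  n <- length(code) - w + 1
  if (n < 1) return(NULL)
  sc <- numeric(n)
  bad <- logical(n)
  for (j in seq_len(w)) {
    cj <- code[j:(j + n - 1)]
    miss <- cj == 0L
    bad <- bad | miss
    cj[miss] <- 1L
    sc <- sc + lo[cbind(cj, j)]
  }
  sc[bad] <- -Inf
  hits <- which(sc >= threshold)
  if (!length(hits)) return(NULL)
  data.frame(offset = hits - 1L, score = sc[hits])
}

#' Scan peak sequences for motif hits
#'
#' Every window on both strands with score >= `threshold` is reported (the
#' minus strand is scanned with the reverse-complemented PWM; the hit
#' coordinates are always on the forward strand). Windows containing
#' ambiguous bases (N) score `-Inf`.
#'
#' @param pwm from [pfmToPwm()].
#' @param peaks `GRanges` (names = peak ids) within genome bounds.
#' @param genome `DNAStringSet`.
#' @param threshold score threshold, e.g. from [scoreThreshold()].
#' @return data.frame motif_id, peak_id, chrom, start, end (0-based
#'   half-open), strand, score.
#' @export
scanPeaks <- function(pwm, peaks, genome, threshold) {
  rc <- pwmReverseComplement(pwm)
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  ids <- if (is.null(names(peaks))) as.character(seq_along(peaks)) else names(peaks)
  out <- list()
  for (i in seq_along(peaks)) {
    s <- as.character(Biostrings::subseq(genome[[chrom[i]]],
          GenomicRanges::start(peaks)[i], GenomicRanges::end(peaks)[i]))
    code <- encodeSeq(strsplit(s, "")[[1]])
    ps0 <- GenomicRanges::start(peaks)[i] - 1L
    for (st in c("+", "-")) {
      m <- if (st == "+") pwm$log_odds else rc$log_odds
      h <- scanOneStrand(code, m, threshold)
      if (!is.null(h))
        out[[length(out) + 1]] <- data.frame(
          motif_id = pwm$motif_id, peak_id = ids[i], chrom = chrom[i],
          start = ps0 + h$offset, end = ps0 + h$offset + pwm$width,
          strand = st, score = h$score, stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(motif_id = character(0), peak_id = character(0),
               chrom = character(0), start = numeric(0), end = numeric(0),
               strand = character(0), score = numeric(0),
               stringsAsFactors = FALSE)
}

# GC fraction (from the ranges) and mean depth-scaled accessibility (from the
# matrix rows named by accIds) for a set of peaks.
peakMatchFeatures <- function(accIds, gr, atac, genome) {
  m <- counts(atac)
  depth <- Matrix::colSums(m)
  med <- stats::median(depth[depth > 0])
  P <- m %*% Matrix::Diagonal(x = ifelse(depth > 0, med / depth, 0))
  acc <- Matrix::rowMeans(P)
  cbind(gc = peakGC(gr, genome), acc = acc[match(accIds, rownames(m))])
}

#' Select GC- and accessibility-matched background peaks
#'
#' For each target (cycled in seeded random order), the nearest not-yet-used
#' pool peak in standardized (GC fraction, mean accessibility) space is
#' selected, until `n` background peaks are drawn without replacement.
#'
#' @param target_peaks,pool_peaks `GRanges` named by peak id; ids absent from
#'   the `atac` rownames are resolved by coordinate identity
#'   (`chrom-start-end`).
#' @param atac [CountMatrix-class].
#' @param genome `DNAStringSet`.
#' @param n number of background peaks.
#' @param seed seed for the target cycling order.
#' @return `GRanges` subset of `pool_peaks`.
#' @export
matchBackgroundPeaks <- function(target_peaks, pool_peaks, atac, genome, n,
                                 seed = 1) {
  if (n == 0) return(pool_peaks[0])
  if (length(pool_peaks) < n) {
    warnf("pool (%d) smaller than n (%d): using the whole pool",
          length(pool_peaks), n)
    return(pool_peaks)
  }
  m <- counts(atac)
  ## accessibility is looked up by peak id; ids absent from the matrix fall
  ## back to the id of a coordinate-identical matrix peak when one exists
  lookupIds <- function(gr) {
    ids <- names(gr)
    miss <- !ids %in% rownames(m)
    if (any(miss)) {
      coordId <- sprintf("%s-%d-%d", as.character(GenomicRanges::seqnames(gr)),
                         GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr))
      ids[miss] <- coordId[miss]
      if (!all(ids %in% rownames(m)))
        stopf("peak(s) absent from the atac matrix: %s",
              paste(head(ids[!ids %in% rownames(m)], 3), collapse = ", "))
    }
    ids
  }
  allGr <- c(target_peaks, pool_peaks)
  feat <- peakMatchFeatures(lookupIds(allGr), allGr, atac, genome)
  featZ <- scale(feat)
  featZ[is.nan(featZ)] <- 0
  nT <- length(target_peaks)
  tz <- featZ[seq_len(nT), , drop = FALSE]
  pz <- featZ[-seq_len(nT), , drop = FALSE]
  used <- logical(nrow(pz))
  sel <- integer(0)
  withSubstream(seed, "matchbg", {
    ord <- sample(nT)
    k <- 0
    while (length(sel) < n) {
      t <- ord[(k %% nT) + 1]
      k <- k + 1
      d2 <- (pz[, 1] - tz[t, 1])^2 + (pz[, 2] - tz[t, 2])^2
      d2[used] <- Inf
      pick <- which.min(d2)
      used[pick] <- TRUE
      sel <- c(sel, pick)
    }
  })
  pool_peaks[sort(sel)]
}

#' Hypergeometric motif enrichment of target vs background peaks
#'
#' Each peak counts once per motif regardless of hit multiplicity. The p-value
#' is the hypergeometric upper tail for the number of hit-bearing target
#' peaks, drawing `n_target` peaks from the combined target + background set
#' in which the hit-bearing peaks are the successes. BH adjustment across
#' motifs; a motif passes iff `p_adjusted < 0.05` and
#' `fold_enrichment > 1.25`.
#'
#' @param hits data.frame from [scanPeaks()] (computed on the union of both
#'   peak sets), possibly several motifs row-bound.
#' @param target_peaks,background_peaks `GRanges` or character ids.
#' @param p_cutoff,fold_cutoff pass filters (defaults 0.05 / 1.25).
#' @return data.frame per motif: motif_id, n_target_with_hit, n_target,
#'   n_bg_with_hit, n_bg, fold_enrichment, p_value, p_adjusted, passes.
#' @export
motifEnrichment <- function(hits, target_peaks, background_peaks,
                            p_cutoff = 0.05, fold_cutoff = 1.25) {
  tgt <- if (is.character(target_peaks)) target_peaks else names(target_peaks)
  bg <- if (is.character(background_peaks)) background_peaks
        else names(background_peaks)
  if (!length(tgt)) stopf("empty target set")
  motifs <- sort(unique(hits$motif_id))
  rows <- lapply(motifs, function(mo) {
    hp <- unique(hits$peak_id[hits$motif_id == mo])
    k <- sum(tgt %in% hp)
    kb <- sum(bg %in% hp)
    K <- k + kb
    N <- length(tgt) + length(bg)
    p <- stats::phyper(k - 1, K, N - K, length(tgt), lower.tail = FALSE)
    fold <- if (kb > 0) (k / length(tgt)) / (kb / length(bg))
            else if (k > 0) Inf else 1
    data.frame(motif_id = mo, n_target_with_hit = k, n_target = length(tgt),
               n_bg_with_hit = kb, n_bg = length(bg), fold_enrichment = fold,
               p_value = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adjusted <- adjustPvalues(res$p_value, "BH", m = nrow(res))
  res$passes <- res$p_adjusted < p_cutoff & res$fold_enrichment > fold_cutoff
  res
}
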