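mkPfm <- function(consensus, id = "M1", name = "TF1", strong = 97) {
  b <- strsplit(consensus, "")[[1]]
  counts <- matrix(1, 4, length(b), dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(b)) counts[b[j], j] <- strong
  list(motif_id = id, name = name, counts = counts)
}

test_that("PFM to PWM conversion matches hand substitution and symmetries", {
  # uniform PFM, uniform background -> all log-odds zero
  uni <- list(motif_id = "U", name = "U",
              counts = matrix(5, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL)))
  pwm <- pfmToPwm(uni)
  expect_true(all(abs(pwm$log_odds) < 1e-12))
  expect_equal(scoreThreshold(pwm, p = 0.5), 0)

  # 1-column PFM A=1, pseudocount 0.25, uniform bg:
  # p(A) = (1 + 0.25) / (1 + 1) = 0.625; score = log2(0.625/0.25) = log2(2.5)
  one <- list(motif_id = "O", name = "O",
              counts = matrix(c(1, 0, 0, 0), 4, 1,
                              dimnames = list(c("A", "C", "G", "T"), NULL)))
  pwm1 <- pfmToPwm(one, pseudocount = 0.25)
  expect_equal(unname(pwm1$log_odds["A", 1]), log2(2.5), tolerance = 1e-12)

  # reverse complement: column-reversed, row-swapped
  pfm <- mkPfm("ACGGT")
  rcCounts <- pfm$counts[c("T", "G", "C", "A"), 5:1]
  rownames(rcCounts) <- c("A", "C", "G", "T")
  pwmF <- pfmToPwm(pfm)
  pwmR <- pfmToPwm(list(motif_id = "r", name = "r", counts = rcCounts))
  expect_equal(unname(gonadGRN:::pwmReverseComplement(pwmF)$log_odds),
               unname(pwmR$log_odds))

  zero <- list(motif_id = "Z", name = "Z",
               counts = matrix(c(0, 0, 0, 0), 4, 1,
                               dimnames = list(c("A", "C", "G", "T"), NULL)))
  expect_error(pfmToPwm(zero, pseudocount = 0), "zero column")
})

test_that("threshold DP equals exhaustive k-mer enumeration for widths <= 6", {
  set.seed(8)
  res <- 0.001
  for (w in c(2, 4, 6)) {
    counts <- matrix(rpois(4 * w, 10) + 1, 4, w,
                     dimnames = list(c("A", "C", "G", "T"), NULL))
    pwm <- pfmToPwm(list(motif_id = "x", name = "x", counts = counts))
    binned <- ceiling(pwm$log_odds / res)
    # enumerate all 4^w k-mers on the same discretization
    grid <- as.matrix(expand.grid(rep(list(1:4), w)))
    scores <- rowSums(matrix(binned[cbind(as.vector(grid),
                                          rep(seq_len(w), each = nrow(grid)))],
                             nrow(grid)))
    for (p in c(1e-4, 0.01, 0.2)) {
      # smallest (discretized) score whose tail mass is <= p; when that falls
      # between two achieved scores it is one bin above the lower one
      tab <- sort(unique(scores))
      tailMass <- vapply(tab, function(s) mean(scores >= s), numeric(1))
      ix <- which(tailMass <= p + 1e-12)[1]
      thrEnum <- (if (is.na(ix)) max(tab)
                  else if (ix == 1) tab[1]
                  else tab[ix - 1] + 1) * res
      expect_equal(scoreThreshold(pwm, p = p, resolution = res), thrEnum,
                   tolerance = 1e-9, label = sprintf("w=%d p=%g", w, p))
    }
    # p = 1: everything passes, threshold is the minimal possible score
    expect_equal(scoreThreshold(pwm, p = 1, resolution = res),
                 min(scores) * res, tolerance = 1e-9)
  }
})

test_that("scanning finds a planted consensus site once, on the right strand", {
  pfm <- mkPfm("AACAATGG")
  pwm <- pfmToPwm(pfm)
  thr <- scoreThreshold(pwm, p = 1e-4)
  # low-complexity background that cannot contain the consensus by accident
  bgSeq <- paste(rep("C", 300), collapse = "")
  seqChar <- strsplit(bgSeq, "")[[1]]
  seqChar[101:108] <- strsplit("AACAATGG", "")[[1]]
  genome <- Biostrings::DNAStringSet(paste(seqChar, collapse = ""))
  names(genome) <- "chr1"
  pk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 300))
  names(pk) <- "pk1"
  hits <- scanPeaks(pwm, pk, genome, thr)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 100)  # 0-based
  expect_equal(hits$end, 108)
  expect_equal(hits$strand, "+")

  # reverse-complemented genome swaps the strand
  rcSeq <- as.character(Biostrings::reverseComplement(genome[[1]]))
  genome2 <- Biostrings::DNAStringSet(rcSeq); names(genome2) <- "chr1"
  hits2 <- scanPeaks(pwm, pk, genome2, thr)
  expect_equal(nrow(hits2), 1)
  expect_equal(hits2$strand, "-")
  expect_equal(hits2$start, 300 - 108)

  # all-N sequence yields no hits
  genomeN <- Biostrings::DNAStringSet(paste(rep("N", 300), collapse = ""))
  names(genomeN) <- "chr1"
  expect_equal(nrow(scanPeaks(pwm, pk, genomeN, thr)), 0)

  # peak shorter than the motif: no hits, no error
  tiny <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 4))
  names(tiny) <- "t"
  expect_equal(nrow(scanPeaks(pwm, tiny, genome, thr)), 0)
})

test_that("planted sites in the synthetic genome are recovered at their offsets", {
  ds <- smallSim()
  lib <- smallSimConfig()$motif_library
  sites <- truthTables(ds)$true_motif_sites
  m <- lib[[1]]
  pwm <- pfmToPwm(m)
  thr <- scoreThreshold(pwm, p = 1e-4)
  own <- sites[sites$motif_id == m$motif_id, ]
  pk <- peakRanges(ds)[unique(own$peak_id)]
  hits <- scanPeaks(pwm, pk, genomeSeq(ds), thr)
  found <- paste(hits$chrom, hits$start, hits$end)
  planted <- paste(own$chrom, own$start, own$end)
  expect_true(all(planted %in% found))
})

test_that("background matching reproduces target GC composition", {
  ds <- smallSim()
  atac <- atacCounts(ds)
  pk <- peakRanges(ds)
  gc <- gonadGRN:::peakGC(pk, genomeSeq(ds))
  # targets: 30 peaks from the high-GC stratum
  ord <- order(gc)
  tgt <- pk[ord[(length(pk) - 29):length(pk)]]
  pool <- pk[!names(pk) %in% names(tgt)]
  bg <- matchBackgroundPeaks(tgt, pool, atac, genomeSeq(ds), n = 30, seed = 2)
  expect_length(bg, 30)
  gcT <- mean(gc[match(names(tgt), names(pk))])
  gcB <- mean(gc[match(names(bg), names(pk))])
  gcPool <- mean(gc[match(names(pool), names(pk))])
  # matched background is much closer to the target GC than the pool average
  expect_lt(abs(gcB - gcT), abs(gcPool - gcT) / 2)

  # pool identical to targets: exact multiset recovery
  pool2 <- tgt
  names(pool2) <- paste0("copy_", names(tgt))
  bg2 <- matchBackgroundPeaks(tgt, pool2, atac, genomeSeq(ds), n = 30, seed = 2)
  expect_setequal(names(bg2), names(pool2))

  expect_length(matchBackgroundPeaks(tgt, pool, atac, genomeSeq(ds), n = 0), 0)
  expect_warning(
    matchBackgroundPeaks(tgt, pool[1:3], atac, genomeSeq(ds), n = 10),
    "whole pool")
})

test_that("enrichment p equals the exact hypergeometric sum and filters apply", {
  # 8/10 targets hit vs 10/100 background hit
  hits <- data.frame(motif_id = "M1",
                     peak_id = c(sprintf("t%d", 1:8), sprintf("b%d", 1:10)),
                     stringsAsFactors = FALSE)
  res <- motifEnrichment(hits, sprintf("t%d", 1:10), sprintf("b%d", 1:100))
  expect_equal(res$fold_enrichment, (8 / 10) / (10 / 100))
  expect_equal(res$p_value, enumHyperP(8, 18, 110, 10), tolerance = 1e-12)
  expect_true(res$passes)

  # equal hit rates -> fold 1, fails
  hits2 <- data.frame(motif_id = "M1",
                      peak_id = c(sprintf("t%d", 1:5), sprintf("b%d", 1:50)))
  res2 <- motifEnrichment(hits2, sprintf("t%d", 1:10), sprintf("b%d", 1:100))
  expect_equal(res2$fold_enrichment, 1)
  expect_false(res2$passes)

  # strong p but fold below 1.25 -> fails the fold filter
  hits3 <- data.frame(motif_id = "M1",
                      peak_id = c(sprintf("t%d", 1:60), sprintf("b%d", 1:50)))
  res3 <- motifEnrichment(hits3, sprintf("t%d", 1:100), sprintf("b%d", 1:100))
  expect_lt(res3$fold_enrichment, 1.25)
  expect_false(res3$passes)

  expect_error(motifEnrichment(hits, character(0), "b1"), "empty target")
})

test_that("enrichment p-values are super-uniform under equal planting rates", {
  set.seed(99)
  nT <- 60; nB <- 300
  ps <- replicate(150, {
    hitT <- sprintf("t%d", which(runif(nT) < 0.3))
    hitB <- sprintf("b%d", which(runif(nB) < 0.3))
    res <- motifEnrichment(
      data.frame(motif_id = "M", peak_id = c(hitT, hitB)),
      sprintf("t%d", 1:nT), sprintf("b%d", 1:nB))
    res$p_value
  })
  rate <- mean(ps < 0.05)
  expect_lte(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / length(ps)))
})
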