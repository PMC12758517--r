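# Shared fixtures, built in code. smallSim() is memoised so several test
# files can reuse one simulated dataset.

.fixtureCache <- new.env(parent = emptyenv())

smallSimConfig <- function(seed = 7) {
  simConfig(seed = seed, n_cells_per_group = 12, n_genes = 150, n_peaks = 400,
            genome_length_bp = 1e6, n_chromosomes = 4)
}

smallSim <- function() {
  if (is.null(.fixtureCache$small))
    .fixtureCache$small <- simulateMultiome(smallSimConfig())
  .fixtureCache$small
}

# Brute-force two-sided Wilcoxon rank-sum p by full enumeration of all
# C(n1+n2, n1) group assignments (independent oracle, small n only).
enumRankSumP <- function(x1, x2) {
  values <- c(x1, x2)
  n1 <- length(x1)
  r <- rank(values)
  w <- sum(r[seq_len(n1)])
  mu <- n1 * mean(r) * 1  # n1 * (average rank)
  combs <- utils::combn(length(values), n1)
  ws <- apply(combs, 2, function(ix) sum(r[ix]))
  mean(abs(ws - mu) >= abs(w - mu) - 1e-9)
}

# Iteratively refined grid maximization of the 2-parameter logistic
# log-likelihood (independent oracle for the LR statistic).
gridLogisticLR <- function(x, y, rounds = 6, span0 = 10, grid = 41) {
  ll <- function(b0, b1) {
    eta <- b0 + b1 * x
    sum(y * eta - log1p(exp(eta)))
  }
  c0 <- 0; c1 <- 0; span <- span0
  for (r in seq_len(rounds)) {
    b0s <- seq(c0 - span, c0 + span, length.out = grid)
    b1s <- seq(c1 - span, c1 + span, length.out = grid)
    vals <- outer(b0s, b1s, Vectorize(ll))
    ix <- which(vals == max(vals), arr.ind = TRUE)[1, ]
    c0 <- b0s[ix[1]]; c1 <- b1s[ix[2]]
    span <- span * 2.5 / grid * 2
  }
  p1 <- mean(y)
  llNull <- sum(y * log(p1) + (1 - y) * log(1 - p1))
  2 * (ll(c0, c1) - llNull)
}

# Exact hypergeometric upper-tail probability by direct combinatorial sum.
enumHyperP <- function(k, K, N, n) {
  j <- k:min(K, n)
  sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
}

randomPeaks <- function(n, chroms, len, seed = 1) {
  set.seed(seed)
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(len - 2000, n)
  w <- sample(100:800, n, replace = TRUE)
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, start + w - 1))
  names(gr) <- sprintf("pk%04d", seq_len(n))
  gr
}

# Brute-force oracle for midpoint feature assignment, independent of the
# implementation's interval logic.
bruteAnnotate <- function(mid, chrom, gm, exons, pw = 3000, dw = 3000) {
  onC <- gm[gm$chrom == chrom, , drop = FALSE]
  if (!nrow(onC)) return("distal_intergenic")
  if (any(abs(mid - onC$tss) <= pw)) return("promoter")
  inside <- which(mid >= onC$span_start & mid < onC$span_end)
  if (length(inside)) {
    g <- onC$gene_id[inside[which.min(abs(mid - onC$tss[inside]))]]
    ex <- exons[exons$gene_id == g, , drop = FALSE]
    if (any(mid >= ex$start & mid < ex$end)) return("exon")
    ex <- ex[order(ex$exon_rank), ]
    strand <- onC$strand[onC$gene_id == g]
    fi <- if (strand == "+") sort(c(ex$end[1], ex$start[2]))
          else sort(c(ex$end[nrow(ex) - 1], ex$start[nrow(ex)]))
    if (mid >= fi[1] && mid < fi[2]) return("first_intron")
    return("other_intron")
  }
  down <- any(ifelse(onC$strand == "+",
                     mid >= onC$span_end & mid < onC$span_end + dw,
                     mid < onC$span_start & mid >= onC$span_start - dw))
  if (down) return("downstream")
  "distal_intergenic"
}

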