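# Internal helpers shared across modules.

# Deterministic substream seed derived from a master seed and a stream name.
# Keeps component-level randomness isolated while staying reproducible from one
# user-facing seed. Result stays below 2^31 - 1.
substreamSeed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131L)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

withSubstream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(substreamSeed(seed, name))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

#' Log-normalize a count matrix
#'
#' Counts-per-median-library scaling followed by log2(x + 1): each cell's
#' counts are divided by its library size and multiplied by the median library
#' size over all cells, then log2-transformed with a pseudocount of 1. This is
#' the normalization used for all downstream expression work; rank-based module
#' scores are invariant to it by construction.
#'
#' @param x a [CountMatrix-class] or sparse matrix (features x cells).
#' @return a sparse `dgCMatrix` of normalized values.
#' @export
normalizeCounts <- function(x) {
  m <- if (is(x, "CountMatrix")) counts(x) else x
  libs <- Matrix::colSums(m)
  med <- stats::median(libs[libs > 0])
  scal <- ifelse(libs > 0, med / libs, 0)
  out <- m %*% Matrix::Diagonal(x = scal)
  out@x <- log2(out@x + 1)
  dimnames(out) <- dimnames(m)
  methods::as(out, "CsparseMatrix")
}

# GC fraction of each peak's sequence on the dataset genome; NA-free
# (N bases count toward length, not GC).
peakGC <- function(peaks, genome) {
  chr <- as.character(GenomicRanges::seqnames(peaks))
  vapply(seq_along(peaks), function(i) {
    s <- genome[[chr[i]]]
    sub <- Biostrings::subseq(s, GenomicRanges::start(peaks)[i],
                              GenomicRanges::end(peaks)[i])
    f <- Biostrings::letterFrequency(sub, c("G", "C"))
    sum(f) / length(sub)
  }, numeric(1))
}

# 0-based half-open interval -> GRanges (1-based closed internally)
grFromBed0 <- function(chrom, start0, end0, name = NULL, strand = "*") {
  gr <- GenomicRanges::GRanges(chrom,
        IRanges::IRanges(start = start0 + 1L, end = end0), strand = strand)
  if (!is.null(name)) names(gr) <- name
  gr
}

# GRanges -> 0-based half-open data.frame
bed0FromGr <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             name = if (is.null(names(gr))) "." else names(gr),
             stringsAsFactors = FALSE)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
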