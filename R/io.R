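# Readers and writers for the standard on-disk formats the pipeline touches.
# All genomic coordinates are 0-based half-open (BED convention) at the file
# boundary; GRanges objects are 1-based closed internally, converted here.

#' Read a MatrixMarket triplet count matrix with feature/barcode sidecars
#'
#' Reads the 10x-style trio (matrix.mtx, features.tsv, barcodes.tsv) into a
#' [CountMatrix-class]. Duplicate (i, j) entries are summed, matching
#' MatrixMarket coordinate semantics.
#'
#' @param mtx_path path to the MatrixMarket coordinate file.
#' @param features_path path to a TSV whose first column holds feature ids.
#' @param barcodes_path path to a TSV whose first column holds barcodes.
#' @param modality `"rna"` or `"atac"`.
#' @return A [CountMatrix-class].
#' @export
readMtxTriplet <- function(mtx_path, features_path, barcodes_path,
                           modality = c("rna", "atac")) {
  modality <- match.arg(modality)
  lines <- readLines(mtx_path)
  if (!length(lines) || !grepl("^%%MatrixMarket\\s+matrix\\s+coordinate", lines[1]))
    stopf("not a MatrixMarket coordinate file: %s", mtx_path)
  body <- lines[!grepl("^%", lines)]
  body <- body[nzchar(trimws(body))]
  hdr <- as.numeric(strsplit(trimws(body[1]), "\\s+")[[1]])
  if (length(hdr) != 3 || anyNA(hdr))
    stopf("malformed MatrixMarket size line in %s", mtx_path)
  nr <- hdr[1]; nc <- hdr[2]; nnz <- hdr[3]
  ent <- body[-1]
  if (length(ent) != nnz)
    stopf("MatrixMarket header declares %d entries but file contains %d",
          nnz, length(ent))
  trip <- if (nnz > 0) {
    m <- matrix(as.numeric(unlist(strsplit(trimws(ent), "\\s+"))),
                ncol = 3, byrow = TRUE)
    if (anyNA(m)) stopf("non-numeric entry in %s", mtx_path)
    m
  } else matrix(numeric(0), ncol = 3)
  if (nrow(trip) && min(trip[, 3]) < 0)
    stopf("negative count entry in %s", mtx_path)
  if (nrow(trip) && (max(trip[, 1]) > nr || max(trip[, 2]) > nc))
    stopf("entry index outside declared dimensions in %s", mtx_path)
  feats <- read.table(features_path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE)[[1]]
  bcs <- read.table(barcodes_path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)[[1]]
  if (length(feats) != nr)
    stopf("feature file lists %d ids but matrix declares %d rows",
          length(feats), nr)
  if (length(bcs) != nc)
    stopf("barcode file lists %d ids but matrix declares %d columns",
          length(bcs), nc)
  m <- Matrix::sparseMatrix(i = trip[, 1], j = trip[, 2], x = trip[, 3],
                            dims = c(nr, nc), dimnames = list(feats, bcs))
  CountMatrix(m, modality)
}

#' Write a CountMatrix as a MatrixMarket triplet trio
#'
#' @param x a [CountMatrix-class].
#' @param mtx_path,features_path,barcodes_path output paths.
#' @return invisibly, the three paths.
#' @export
writeMtxTriplet <- function(x, mtx_path, features_path, barcodes_path) {
  m <- methods::as(counts(x), "TsparseMatrix")
  con <- file(mtx_path, "w")
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               sprintf("%d %d %d", nrow(m), ncol(m), length(m@x))), con)
  if (length(m@x))
    writeLines(sprintf("%d %d %d", m@i + 1L, m@j + 1L, as.integer(m@x)), con)
  close(con)
  writeLines(rownames(m), features_path)
  writeLines(colnames(m), barcodes_path)
  invisible(c(mtx_path, features_path, barcodes_path))
}

#' Read / write BED intervals
#'
#' BED coordinates are 0-based half-open and preserved exactly; the returned
#' `GRanges` follows Bioconductor's 1-based closed convention (start + 1).
#'
#' @param path BED file path (>= 3 tab-separated columns; optional name in
#'   column 4, strand in column 6).
#' @return `readBed`: a `GRanges`. `writeBed`: invisibly, the path.
#' @export
readBed <- function(path) {
  raw <- readLines(path)
  raw <- raw[nzchar(trimws(raw)) & !grepl("^(track|browser|#)", raw)]
  if (!length(raw))
    return(GenomicRanges::GRanges())
  parts <- strsplit(raw, "\t", fixed = TRUE)
  ncol <- min(lengths(parts))
  if (ncol < 3) stopf("BED requires >= 3 tab-separated columns: %s", path)
  chrom <- vapply(parts, `[[`, "", 1)
  start0 <- as.numeric(vapply(parts, `[[`, "", 2))
  end0 <- as.numeric(vapply(parts, `[[`, "", 3))
  if (anyNA(start0) || anyNA(end0)) stopf("non-numeric BED coordinate in %s", path)
  if (any(start0 >= end0))
    stopf("BED interval with start >= end in %s", path)
  nm <- if (ncol >= 4) vapply(parts, `[[`, "", 4) else NULL
  strand <- if (ncol >= 6) vapply(parts, `[[`, "", 6) else "*"
  strand[strand == "."] <- "*"
  grFromBed0(chrom, start0, end0, name = nm, strand = strand)
}

#' @rdname readBed
#' @param gr a `GRanges` to write.
#' @export
writeBed <- function(gr, path) {
  df <- bed0FromGr(gr)
  st <- as.character(GenomicRanges::strand(gr))
  st[st == "*"] <- "."
  lines <- if (length(gr))
    sprintf("%s\t%d\t%d\t%s\t%d\t%s", df$chrom, df$start, df$end, df$name, 0L, st)
  else character(0)
  writeLines(lines, path)
  invisible(path)
}

#' Read JASPAR-format position frequency matrices
#'
#' Parses the JASPAR 2022 text format: records of a `>ID NAME` header followed
#' by four base rows (`A [ n n ... ]` etc.). Row order is normalized to
#' A, C, G, T regardless of file order.
#'
#' @param path JASPAR text file.
#' @return A named list of PFMs; each element is a list with `motif_id`,
#'   `name`, and `counts` (4 x width numeric matrix, rows A,C,G,T).
#' @export
readJaspar <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- grep("^>", lines)
  if (!length(starts)) stopf("no JASPAR records in %s", path)
  ends <- c(starts[-1] - 1L, length(lines))
  out <- lapply(seq_along(starts), function(k) {
    hdr <- sub("^>", "", lines[starts[k]])
    toks <- strsplit(hdr, "\\s+")[[1]]
    motif_id <- toks[1]
    name <- if (length(toks) > 1) paste(toks[-1], collapse = " ") else toks[1]
    rows <- lines[(starts[k] + 1L):ends[k]]
    base <- toupper(substr(rows, 1, 1))
    if (!setequal(base, c("A", "C", "G", "T")) || length(rows) != 4)
      stopf("JASPAR record %s must have exactly rows A, C, G, T", motif_id)
    counts <- lapply(rows, function(r) {
      nums <- gsub("^[ACGTacgt]\\s*\\[?|\\]\\s*$", "", r)
      v <- suppressWarnings(as.numeric(strsplit(trimws(nums), "\\s+")[[1]]))
      if (anyNA(v)) stopf("non-numeric count in JASPAR record %s", motif_id)
      v
    })
    w <- unique(lengths(counts))
    if (length(w) != 1 || w < 1)
      stopf("ragged count rows in JASPAR record %s", motif_id)
    mat <- do.call(rbind, counts[order(base)])
    rownames(mat) <- c("A", "C", "G", "T")
    if (any(mat < 0)) stopf("negative count in JASPAR record %s", motif_id)
    if (any(colSums(mat) <= 0))
      stopf("all-zero column in JASPAR record %s", motif_id)
    list(motif_id = motif_id, name = name, counts = mat)
  })
  names(out) <- vapply(out, `[[`, "", "motif_id")
  out
}

#' Write a motif list in JASPAR text format
#' @param motifs list of PFMs as returned by [readJaspar()].
#' @param path output path.
#' @export
writeJaspar <- function(motifs, path) {
  con <- file(path, "w")
  for (m in motifs) {
    writeLines(sprintf(">%s %s", m$motif_id, m$name), con)
    for (b in c("A", "C", "G", "T"))
      writeLines(sprintf("%s [ %s ]", b,
                         paste(format(m$counts[b, ], trim = TRUE), collapse = " ")), con)
  }
  close(con)
  invisible(path)
}

#' Read a genome FASTA into a DNAStringSet
#'
#' Sequences are uppercase-normalized; duplicate chromosome names are an error.
#' @param path FASTA path.
#' @return a `DNAStringSet` named by chromosome.
#' @export
readFastaGenome <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[[`, "", 1)
  if (anyDuplicated(names(seqs)))
    stopf("duplicate chromosome names in %s", path)
  Biostrings::DNAStringSet(toupper(as.character(seqs)))
}

#' Read a gene model TSV
#'
#' Expects header columns gene_id, chrom, strand, tss (0-based); optional
#' span_start / span_end (0-based half-open).
#' @param path TSV path.
#' @return a data.frame of gene models.
#' @export
readGeneModels <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "tss")
  if (!all(need %in% names(df)))
    stopf("gene model table must contain columns: %s", paste(need, collapse = ", "))
  if (anyDuplicated(df$gene_id)) stopf("duplicate gene_id in %s", path)
  if (!all(df$strand %in% c("+", "-"))) stopf("strand must be '+' or '-'")
  df
}

#' Write ground-truth tables as TSV files
#'
#' One TSV per truth table, written to `directory`; empty tables produce
#' header-only files. Round-trippable with [readTruth()].
#'
#' @param truth named list of data.frames (as in `truthTables()`).
#' @param directory output directory (created if absent).
#' @return invisibly, the written paths.
#' @export
writeTruth <- function(truth, directory) {
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  paths <- vapply(names(truth), function(nm) {
    p <- file.path(directory, paste0(nm, ".tsv"))
    write.table(truth[[nm]], p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}

#' @rdname writeTruth
#' @export
readTruth <- function(directory) {
  files <- list.files(directory, pattern = "\\.tsv$", full.names = TRUE)
  out <- lapply(files, read.table, sep = "\t", header = TRUE,
                stringsAsFactors = FALSE)
  names(out) <- sub("\\.tsv$", "", basename(files))
  out
}
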