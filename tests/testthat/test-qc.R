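cellRow <- function(barcode = "c1", n_count_rna = 5000, percent_mt = 5,
                    n_count_atac = 50000, nucleosome_signal = 1,
                    tss_enrichment = 3, declared_sex = "XY", stage = "E11.5",
                    chry_fragments = 1) {
  data.frame(barcode = barcode, n_count_rna = n_count_rna,
             percent_mt = percent_mt, n_count_atac = n_count_atac,
             nucleosome_signal = nucleosome_signal,
             tss_enrichment = tss_enrichment, declared_sex = declared_sex,
             stage = stage, chry_fragments = chry_fragments,
             stringsAsFactors = FALSE)
}

test_that("RNA and ATAC QC gates are strict inequalities and idempotent", {
  cells <- rbind(cellRow("a", n_count_rna = 1000, percent_mt = 0),   # boundary: out
                 cellRow("b", n_count_rna = 1001, percent_mt = 24.9),# in
                 cellRow("c", n_count_rna = 5000, percent_mt = 25),  # boundary: out
                 cellRow("d", n_count_rna = 25000),                  # boundary: out
                 cellRow("e"))
  expect_identical(applyRnaQC(cells), c("b", "e"))

  cells2 <- rbind(cellRow("a", n_count_atac = 1000),                  # out
                  cellRow("b", n_count_atac = 50000,
                          nucleosome_signal = 1.5, tss_enrichment = 2),# in
                  cellRow("c", n_count_atac = 50000,
                          nucleosome_signal = 2, tss_enrichment = 2),  # out
                  cellRow("d", n_count_atac = 100000),                 # out
                  cellRow("e", tss_enrichment = 1))                    # out
  expect_identical(applyAtacQC(cells2), "b")

  # idempotence: filtering the kept subset changes nothing
  kept <- applyRnaQC(cells)
  expect_identical(applyRnaQC(cells[cells$barcode %in% kept, ]), kept)

  cells$percent_mt[2] <- NA
  expect_error(applyRnaQC(cells), "barcode b")
})

test_that("filterPeaks reduces, size-gates and blacklists", {
  pk <- GenomicRanges::GRanges(c("chr1", "chr1", "chr2", "chr2", "chrUn"),
          IRanges::IRanges(start = c(1, 11, 100, 5000, 1),
                           end = c(15, 40, 119, 16000, 100)))
  # (chr1,0,15)+(chr1,10,40) merge to width 40; chr2 width 20 removed (strict);
  # chr2 width 11000 removed; chrUn dropped by the allowed list
  out <- filterPeaks(pk, allowed_chromosomes = c("chr1", "chr2"))
  expect_equal(length(out), 1)
  expect_equal(GenomicRanges::width(out), 40)
  expect_equal(as.character(GenomicRanges::seqnames(out)), "chr1")

  # exactly 10,000 bp is removed (strict <)
  pk2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10000))
  expect_length(filterPeaks(pk2), 0)

  # blacklist overlap by >= 1 bp drops the peak
  pk3 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 500), c(100, 600)))
  bl <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 120))
  out3 <- filterPeaks(pk3, blacklist = bl)
  expect_equal(GenomicRanges::start(out3), 500)
})

test_that("moduleScore matches closed forms and is rank-based", {
  # 10 genes, one cell; signature at the top ranks -> score 1
  m <- matrix(10:1, ncol = 1, dimnames = list(sprintf("g%d", 1:10), "c1"))
  expect_equal(moduleScore(m, c("g1", "g2", "g3"), r_max = 5)$score, 1)

  # all signature ranks beyond r_max: score = (|S|+1) / (2 r_max)
  n <- 2000
  m2 <- matrix(n:1, ncol = 1, dimnames = list(sprintf("g%d", 1:n), "c1"))
  sig <- sprintf("g%d", (n - 3):n)  # ranks 1997..2000, all capped at 1500
  s <- moduleScore(m2, sig, r_max = 1500)$score
  expect_equal(s, (4 + 1) / (2 * 1500))

  # constant cell: every gene has rank (N+1)/2; closed-form score equal for
  # any signature of the same size
  m3 <- matrix(1, nrow = 50, ncol = 1,
               dimnames = list(sprintf("g%d", 1:50), "c1"))
  sA <- moduleScore(m3, c("g1", "g2"), r_max = 1500)$score
  sB <- moduleScore(m3, c("g40", "g41"), r_max = 1500)$score
  expected <- 1 - (2 * (50 + 1) / 2 - 2 * 3 / 2) / (2 * 1500)
  expect_equal(sA, expected)
  expect_equal(sB, expected)

  # invariance under a monotone transform of a cell's expression vector
  set.seed(5)
  m4 <- matrix(rpois(300, 4), nrow = 30,
               dimnames = list(sprintf("g%d", 1:30), sprintf("c%d", 1:10)))
  sig4 <- c("g3", "g7", "g20")
  s1 <- moduleScore(m4, sig4)$score
  s2 <- moduleScore(log1p(m4) * 7 + 2, sig4)$score
  expect_equal(s1, s2)

  expect_error(moduleScore(m4, character(0)), "empty")
  expect_warning(moduleScore(m4, c("g3", "nope")), "dropped")
})

test_that("sexFilter applies the quoted removal rules exactly on a 12-cell truth table", {
  # reference stage defines cutoffs; E11.5 cells are filtered
  ref <- rbind(
    cellRow("r1", declared_sex = "XY", stage = "E13.5"),
    cellRow("r2", declared_sex = "XY", stage = "E13.5"),
    cellRow("r3", declared_sex = "XY", stage = "E13.5"),
    cellRow("r4", declared_sex = "XX", stage = "E13.5", chry_fragments = 0),
    cellRow("r5", declared_sex = "XX", stage = "E13.5", chry_fragments = 0),
    cellRow("r6", declared_sex = "XX", stage = "E13.5", chry_fragments = 0))
  test <- rbind(
    cellRow("t1", declared_sex = "XY", stage = "E11.5", chry_fragments = 3),
    cellRow("t2", declared_sex = "XY", stage = "E11.5", chry_fragments = 0),
    cellRow("t3", declared_sex = "XY", stage = "E11.5", chry_fragments = 0),
    cellRow("t4", declared_sex = "XX", stage = "E11.5", chry_fragments = 1),
    cellRow("t5", declared_sex = "XX", stage = "E11.5", chry_fragments = 0),
    cellRow("t6", declared_sex = "XX", stage = "E11.5", chry_fragments = 0))
  cells <- rbind(ref, test)
  # XY ref scores mean 0.8 sd 0.1 -> cutoff_XY = 0.7; XX ref mean 0.1 sd 0.05
  # -> cutoff_XX = 0.15
  scores <- data.frame(
    barcode = cells$barcode,
    score = c(0.7, 0.8, 0.9, 0.05, 0.10, 0.15,
              0.2,   # t1: low score BUT chrY fragments > 0 -> kept (AND rule)
              0.2,   # t2: 0 fragments AND score < cutoff -> removed
              0.7,   # t3: score exactly at cutoff, strict < -> kept
              0.05,  # t4: XX with > 0 fragments -> removed (OR rule)
              0.5,   # t5: XX score > cutoff -> removed
              0.12)) # t6: XX clean -> kept
  res <- sexFilter(scores, cells)
  expect_equal(res$cutoff_xy, 0.8 - sd(c(0.7, 0.8, 0.9)), tolerance = 1e-12)
  expect_setequal(res$removed, c("t2", "t4", "t5"))
  # reference-stage cells are never filtered
  expect_true(all(ref$barcode %in% res$kept))

  expect_error(sexFilter(scores, cells[-(1:2), ]), ">= 2 reference")
})

test_that("sexFilter retains correctly labeled synthetic cells and removes mislabeled ones", {
  ds <- smallSim()
  cells <- as.data.frame(cellData(ds))
  yGenes <- c("Kdm5d", "Eif2s3y", "Uty", "Ddx3y")
  # rank cap well below the tied rank of undetected genes on the 150-gene
  # panel (analogue of 1500 on a ~20k-gene transcriptome) so XX scores are
  # exactly constant
  sc <- moduleScore(rnaCounts(ds), yGenes, r_max = 100)
  res <- sexFilter(sc, cells)
  expect_length(res$removed, 0)

  # deliberately mislabel some cells: swap declared sex
  swap <- cells
  xyIdx <- which(swap$declared_sex == "XY" & swap$stage == "E11.5")[1:5]
  xxIdx <- which(swap$declared_sex == "XX" & swap$stage == "E11.5")[1:5]
  swap$declared_sex[xyIdx] <- "XX"  # true XY declared XX: fragments > 0
  swap$declared_sex[xxIdx] <- "XY"  # true XX declared XY: 0 frags, low score
  res2 <- sexFilter(sc, swap)
  expect_true(all(swap$barcode[c(xyIdx, xxIdx)] %in% res2$removed))
  # all correctly labeled non-reference cells stay
  correct <- swap$barcode[-c(xyIdx, xxIdx)]
  expect_true(all(setdiff(correct, res2$kept) == character(0)))
})

test_that("annotateCellTypes assigns marker arg-max and flags ties", {
  genes <- c("Fst", "Foxl2", "Amh", "Sox9", sprintf("g%d", 1:6))
  m <- matrix(0, 10, 3, dimnames = list(genes, c("cPre", "cSer", "cZero")))
  m[c("Fst", "Foxl2"), "cPre"] <- 50
  m[c("Amh", "Sox9"), "cSer"] <- 50
  m[5:10, ] <- matrix(rep(1:6, 3), 6)  # shared background
  res <- annotateCellTypes(m, list(pregranulosa = c("Fst", "Foxl2"),
                                   Sertoli = c("Amh", "Sox9")))
  expect_equal(res$cell_type[res$barcode == "cPre"], "pregranulosa")
  expect_equal(res$cell_type[res$barcode == "cSer"], "Sertoli")
  # all-zero cell ties across all types, flagged, lexicographic winner
  expect_true(res$tie[res$barcode == "cZero"])
  expect_equal(res$cell_type[res$barcode == "cZero"], "Sertoli")
  expect_error(annotateCellTypes(m, list()), "empty")
})
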