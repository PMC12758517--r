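# Synthetic joint RNA+ATAC generator with full ground truth.
#
# The generator emulates the statistical structure the downstream analyses
# assume: cell populations laid out on a (sex x stage x cell type) grid,
# negative-binomial RNA counts with cell-type programs and planted sex-specific
# DEGs, Poisson ATAC counts with planted sex-specific DAPs, latent-factor
# coupling between linked peaks and their target genes within 500 kb of the
# TSS, Y-linked expression and chrY fragments confined to XY cells, motif
# consensus sites planted into differential peaks, and histone ChIP tracks
# covering configured fractions of each DAP set.

#' Simulation configuration
#'
#' Builds and validates the parameter set for [simulateMultiome()]. Defaults
#' describe the study conditions the package is validated under: four somatic
#' gonadal cell types crossed with two sexes and three developmental stages
#' (~2,000 cells), 500 genes, 2,000 peaks.
#'
#' @param seed master seed; all stage-level randomness derives from named
#'   substreams of it.
#' @param n_cells_per_group cells per (sex, stage, cell type) group.
#' @param cell_types character vector of cell-type labels.
#' @param stages character vector of developmental stages.
#' @param n_genes,n_peaks feature counts (n_peaks includes one chrY peak).
#' @param genome_length_bp length of each synthetic chromosome.
#' @param n_chromosomes number of chromosomes (>= 2; the last is chrY).
#' @param mean_library_rna,mean_library_atac expected counts per cell.
#' @param nb_dispersion negative-binomial dispersion of RNA counts
#'   (variance = mu + dispersion * mu^2).
#' @param deg_log2fc planted log2 fold change for DEGs and DAPs.
#' @param frac_deg fraction of genes sex-differential per cell type.
#' @param frac_dap fraction of peaks sex-differential per cell type.
#' @param link_strength latent-factor loading coupling a peak to its target.
#' @param frac_linked fraction of each DAP set coupled to a target gene within
#'   500 kb of its TSS.
#' @param motif_library list of PFMs (as from [readJaspar()]); default three
#'   built-in synthetic motifs whose names double as TF gene ids.
#' @param plant_rate fraction of linked DAPs receiving a planted motif site.
#' @param histone_overlap_frac named per-mark fractions of each DAP set covered
#'   by the matching synthetic ChIP track.
#' @param y_gene_ids gene ids treated as Y-linked.
#' @return a `SimConfig` (validated list).
#' @export
simConfig <- function(seed = 1L,
                      n_cells_per_group = 85L,
                      cell_types = c("epithelial", "presupporting",
                                     "Sertoli", "pregranulosa"),
                      stages = c("E11.5", "E12.5", "E13.5"),
                      n_genes = 500L,
                      n_peaks = 2000L,
                      genome_length_bp = 2e6,
                      n_chromosomes = 5L,
                      mean_library_rna = 5000,
                      mean_library_atac = 10000,
                      nb_dispersion = 0.3,
                      deg_log2fc = 1,
                      frac_deg = 0.10,
                      frac_dap = 0.15,
                      link_strength = 0.6,
                      frac_linked = 0.5,
                      motif_library = NULL,
                      plant_rate = 0.8,
                      histone_overlap_frac = c(H3K4me3 = 0.40,
                                               H3K27me3 = 0.10,
                                               H3K27ac = 0.50),
                      y_gene_ids = c("Kdm5d", "Eif2s3y", "Uty", "Ddx3y")) {
  if (is.null(motif_library)) motif_library <- builtinMotifs()
  cfg <- list(seed = as.integer(seed),
              n_cells_per_group = as.integer(n_cells_per_group),
              cell_types = cell_types, stages = stages,
              n_genes = as.integer(n_genes), n_peaks = as.integer(n_peaks),
              genome_length_bp = genome_length_bp,
              n_chromosomes = as.integer(n_chromosomes),
              mean_library_rna = mean_library_rna,
              mean_library_atac = mean_library_atac,
              nb_dispersion = nb_dispersion, deg_log2fc = deg_log2fc,
              frac_deg = frac_deg, frac_dap = frac_dap,
              link_strength = link_strength, frac_linked = frac_linked,
              motif_library = motif_library, plant_rate = plant_rate,
              histone_overlap_frac = histone_overlap_frac,
              y_gene_ids = y_gene_ids)
  fracs <- c(cfg$frac_deg, cfg$frac_dap, cfg$frac_linked, cfg$plant_rate,
             cfg$histone_overlap_frac)
  if (any(fracs < 0 | fracs > 1)) stopf("all fractions must lie in [0, 1]")
  if (cfg$n_cells_per_group < 0 || cfg$n_genes < 0 || cfg$n_peaks < 1)
    stopf("counts must be non-negative (and n_peaks >= 1)")
  if (cfg$n_chromosomes < 2)
    stopf("n_chromosomes must be >= 2: a dedicated chrY is required")
  if (cfg$nb_dispersion < 0) stopf("nb_dispersion must be >= 0")
  structure(cfg, class = "SimConfig")
}

#' @export
print.SimConfig <- function(x, ...) {
  cat("SimConfig: ", length(x$cell_types), " cell types x ",
      length(x$stages), " stages x 2 sexes, ",
      x$n_cells_per_group, " cells/group; ",
      x$n_genes, " genes, ", x$n_peaks, " peaks, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# Built-in synthetic motif library: strongly informative 8-mers whose names
# are the ids of the TF genes planted as DEGs (SOX/GATA/nuclear-receptor
# flavoured consensi, non-palindromic).
builtinMotifs <- function() {
  mk <- function(id, name, consensus) {
    b <- strsplit(consensus, "")[[1]]
    counts <- matrix(1, 4, length(b), dimnames = list(c("A", "C", "G", "T"), NULL))
    for (j in seq_along(b)) counts[b[j], j] <- 97
    list(motif_id = id, name = name, counts = counts)
  }
  # GC-balanced consensi keep the spontaneous hit rate of the uniform-
  # background scan threshold honest on GC-heterogeneous sequence
  list(M001 = mk("M001", "Sox9", "CAACAATGGC"),
       M002 = mk("M002", "Gata4", "CAGATAAGCG"),
       M003 = mk("M003", "Nr5a1", "TGACCTTGAC"))
}

motifConsensus <- function(pfm) {
  paste(rownames(pfm$counts)[apply(pfm$counts, 2, which.max)], collapse = "")
}

randomChromosome <- function(len, nblocks = 10) {
  # blockwise GC heterogeneity so peaks span a realistic GC range
  bl <- ceiling(len / nblocks)
  unlist(lapply(seq_len(nblocks), function(b) {
    n <- min(bl, len - (b - 1) * bl)
    if (n <= 0) return(character(0))
    gc <- runif(1, 0.42, 0.58)
    sample(c("A", "T", "G", "C"), n, replace = TRUE,
           prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
  }))
}

#' Simulate a joint single-nucleus multiome dataset with ground truth
#'
#' @param config a `SimConfig` from [simConfig()].
#' @return a [MultiomeDataset-class] whose `truthTables()` hold planted DEGs,
#'   DAPs, peak-gene links, motif sites, regulatory edges, histone membership
#'   and marker genes.
#' @details Identical config (including seed) yields byte-identical output.
#'   RNA counts are negative binomial with lognormal per-cell size factors;
#'   ATAC counts are Poisson with rate = size factor x peak propensity x
#'   planted multipliers. Each true link couples its peak and gene through a
#'   per-cell standard-normal latent factor with loading `link_strength`
#'   (negated on the peak side for negative links). Y-linked genes and the
#'   chrY peak have zero counts in XX cells and are always non-zero in XY
#'   cells. Column rates are rescaled so each cell's expected library equals
#'   its size factor times the configured mean library.
#' @export
simulateMultiome <- function(config) {
  if (!inherits(config, "SimConfig")) stopf("config must come from simConfig()")
  cfg <- config
  autos <- paste0("chr", seq_len(cfg$n_chromosomes - 1L))
  chroms <- c(autos, "chrY")

  ## genome ------------------------------------------------------------------
  genomeChars <- withSubstream(cfg$seed, "genome", {
    lapply(chroms, function(ch) randomChromosome(cfg$genome_length_bp))
  })
  names(genomeChars) <- chroms

  ## gene models -------------------------------------------------------------
  nY <- length(cfg$y_gene_ids)
  mtIds <- c("mt-Nd1", "mt-Co1")
  nAuto <- cfg$n_genes - nY - length(mtIds)
  if (nAuto < 1) stopf("n_genes too small for Y-linked and mitochondrial genes")
  geneIds <- c(sprintf("g%04d", seq_len(nAuto)), mtIds, cfg$y_gene_ids)
  # TF genes: rename the first genes after the motif library's TF names
  tfNames <- vapply(cfg$motif_library, `[[`, "", "name")
  geneIds[seq_along(tfNames)] <- tfNames
  gm <- withSubstream(cfg$seed, "genes", {
    chrom <- c(sample(autos, nAuto + length(mtIds), replace = TRUE),
               rep("chrY", nY))
    strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
    spanLen <- sample(5000:20000, cfg$n_genes, replace = TRUE)
    lo <- 10000; hi <- cfg$genome_length_bp - max(spanLen) - 10000
    anchor <- floor(runif(cfg$n_genes, lo, hi))
    span_start <- anchor
    span_end <- anchor + spanLen
    tss <- ifelse(strand == "+", span_start, span_end - 1L)
    data.frame(gene_id = geneIds, chrom = chrom, strand = strand,
               tss = as.integer(tss), span_start = as.integer(span_start),
               span_end = as.integer(span_end), stringsAsFactors = FALSE)
  })
  exons <- do.call(rbind, lapply(seq_len(nrow(gm)), function(i) {
    L <- gm$span_end[i] - gm$span_start[i]
    rel <- rbind(c(0, 500), c(floor(L * 0.45), floor(L * 0.45) + 300),
                 c(L - 400, L))
    if (gm$strand[i] == "-") rel <- L - rel[3:1, 2:1, drop = FALSE]
    data.frame(gene_id = gm$gene_id[i], exon_rank = 1:3,
               start = as.integer(gm$span_start[i] + rel[, 1]),
               end = as.integer(gm$span_start[i] + rel[, 2]),
               stringsAsFactors = FALSE)
  }))

  ## peaks -------------------------------------------------------------------
  nAutoPeaks <- cfg$n_peaks - 1L
  peakTab <- withSubstream(cfg$seed, "peaks", {
    perChrom <- diff(floor(seq(0, nAutoPeaks, length.out = length(autos) + 1)))
    tabs <- lapply(seq_along(autos), function(ci) {
      k <- perChrom[ci]
      if (k == 0) return(NULL)
      slots <- floor(seq(5000, cfg$genome_length_bp - 5000, length.out = k))
      w <- sample(200:600, k, replace = TRUE)
      start <- slots + sample(-500:500, k, replace = TRUE)
      data.frame(chrom = autos[ci], start = as.integer(start),
                 end = as.integer(start + w), stringsAsFactors = FALSE)
    })
    do.call(rbind, tabs)
  })
  peakTab <- rbind(peakTab,
                   data.frame(chrom = "chrY", start = 1000L, end = 1400L,
                              stringsAsFactors = FALSE))
  peakTab$peak_id <- sprintf("%s-%d-%d", peakTab$chrom, peakTab$start, peakTab$end)
  peaks <- grFromBed0(peakTab$chrom, peakTab$start, peakTab$end,
                      name = peakTab$peak_id)
  chrYPeak <- cfg$n_peaks  # index of the designated chrY peak

  ## cells -------------------------------------------------------------------
  grid <- expand.grid(cell_type = cfg$cell_types, stage = cfg$stages,
                      sex = c("XX", "XY"), stringsAsFactors = FALSE)
  nCells <- nrow(grid) * cfg$n_cells_per_group
  cells <- if (nCells > 0) {
    idx <- rep(seq_len(nrow(grid)), each = cfg$n_cells_per_group)
    data.frame(barcode = sprintf("cell%06d", seq_len(nCells)),
               declared_sex = grid$sex[idx], stage = grid$stage[idx],
               cell_type = grid$cell_type[idx], stringsAsFactors = FALSE)
  } else data.frame(barcode = character(0), declared_sex = character(0),
                    stage = character(0), cell_type = character(0),
                    stringsAsFactors = FALSE)

  ## planted effects ---------------------------------------------------------
  isY <- gm$chrom == "chrY"
  isMt <- grepl("^mt-", gm$gene_id)
  markerTab <- NULL
  degTab <- dapTab <- linkTab <- NULL
  withSubstream(cfg$seed, "effects", {
    eligible <- which(!isY & !isMt)
    # cell-type marker programs (5 genes each, strongly up in their type);
    # canonical gonadal markers get their field names when the type exists
    canon <- list(Sertoli = c("Amh", "Sox9"), pregranulosa = c("Fst", "Foxl2"),
                  presupporting = c("Wnt4", "Runx1"),
                  epithelial = c("Upk3b", "Aldh1a2"))
    used <- integer(0)
    markerTab <- do.call(rbind, lapply(cfg$cell_types, function(ct) {
      pick <- sample(setdiff(eligible, c(used, seq_along(tfNames))), 5)
      used <<- c(used, pick)
      nm <- setdiff(canon[[ct]], geneIds)  # avoid collision with TF gene names
      if (length(nm)) geneIds[pick[seq_along(nm)]] <<- nm
      data.frame(cell_type = ct, gene_id = geneIds[pick],
                 stringsAsFactors = FALSE)
    }))
    gm$gene_id <- geneIds
    exons$gene_id <- rep(geneIds, each = 3)

    nDeg <- round(cfg$frac_deg * cfg$n_genes)
    degTab <- do.call(rbind, lapply(cfg$cell_types, function(ct) {
      if (nDeg == 0) return(NULL)
      tfIdx <- seq_len(min(length(tfNames), nDeg))
      extra <- sample(setdiff(eligible, c(used, seq_along(tfNames))),
                      max(0, nDeg - length(tfIdx)))
      pick <- c(tfIdx, extra)
      sign <- c(rep("up_in_XY", length(tfIdx)),
                sample(c("up_in_XY", "up_in_XX"), length(extra), replace = TRUE))
      data.frame(gene_id = geneIds[pick], contrast = ct, sign = sign,
                 stringsAsFactors = FALSE)
    }))

    nDap <- round(cfg$frac_dap * cfg$n_peaks)
    autoPeakIdx <- setdiff(seq_len(cfg$n_peaks), chrYPeak)
    dapTab <- do.call(rbind, lapply(cfg$cell_types, function(ct) {
      if (nDap == 0) return(NULL)
      pick <- sample(autoPeakIdx, nDap)
      data.frame(peak_id = peakTab$peak_id[pick], peak_index = pick,
                 contrast = ct,
                 sign = sample(c("up_in_XY", "up_in_XX"), nDap, replace = TRUE),
                 stringsAsFactors = FALSE)
    }))

    # peak-gene links: frac_linked of each DAP set coupled to a target gene
    # whose TSS lies within 500 kb of the peak midpoint (DEG targets preferred)
    mids <- peakTab$start + floor((peakTab$end - peakTab$start) / 2)
    linkTab <- do.call(rbind, lapply(cfg$cell_types, function(ct) {
      if (is.null(dapTab)) return(NULL)
      dset <- dapTab[dapTab$contrast == ct, ]
      nLink <- round(cfg$frac_linked * nrow(dset))
      if (nLink == 0) return(NULL)
      pick <- sample(seq_len(nrow(dset)), nLink)
      ctDegs <- degTab$gene_id[degTab$contrast == ct]
      rows <- lapply(pick, function(r) {
        pi <- dset$peak_index[r]
        cand <- which(gm$chrom == peakTab$chrom[pi] &
                      abs(gm$tss - mids[pi]) <= 500000 & !isY & !isMt)
        if (!length(cand)) return(NULL)
        deg <- cand[gm$gene_id[cand] %in% ctDegs]
        pool <- if (length(deg)) deg else cand
        gi <- pool[which.min(abs(gm$tss[pool] - mids[pi]))]
        data.frame(peak_id = dset$peak_id[r], peak_index = pi,
                   gene_id = gm$gene_id[gi], gene_index = gi, cell_type = ct,
                   sign = sample(c("positive", "negative"), 1,
                                 prob = c(0.75, 0.25)),
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    }))
    if (!is.null(linkTab)) {
      linkTab <- linkTab[!duplicated(linkTab[c("peak_id", "gene_id", "cell_type")]), ]
      ## one coupling sign per (peak, gene) pair, whichever cell type drew it
      ## first, so repeated selections cannot cancel each other
      pg <- paste(linkTab$peak_id, linkTab$gene_id)
      linkTab$sign <- linkTab$sign[match(pg, pg)]
    }
  })

  ## motif planting ----------------------------------------------------------
  motifSites <- NULL
  edgeTab <- NULL
  withSubstream(cfg$seed, "motifs", {
    if (!is.null(linkTab) && nrow(linkTab) && length(cfg$motif_library)) {
      rows <- list(); edges <- list()
      for (r in seq_len(nrow(linkTab))) {
        if (runif(1) > cfg$plant_rate) next
        m <- cfg$motif_library[[sample(length(cfg$motif_library), 1)]]
        cons <- motifConsensus(m)
        w <- nchar(cons)
        pi <- linkTab$peak_index[r]
        ps <- peakTab$start[pi]; pe <- peakTab$end[pi]
        if (pe - ps < w) next
        off <- sample(0:(pe - ps - w), 1)
        strand <- sample(c("+", "-"), 1)
        site <- if (strand == "+") cons else
          as.character(Biostrings::reverseComplement(Biostrings::DNAString(cons)))
        pos0 <- ps + off
        genomeChars[[peakTab$chrom[pi]]][(pos0 + 1):(pos0 + w)] <-
          strsplit(site, "")[[1]]
        rows[[length(rows) + 1]] <- data.frame(
          motif_id = m$motif_id, tf = m$name, chrom = peakTab$chrom[pi],
          start = pos0, end = pos0 + w, strand = strand,
          peak_id = peakTab$peak_id[pi], stringsAsFactors = FALSE)
        edges[[length(edges) + 1]] <- data.frame(
          tf = m$name, target = linkTab$gene_id[r], sign = linkTab$sign[r],
          cell_type = linkTab$cell_type[r], peak_id = peakTab$peak_id[pi],
          stringsAsFactors = FALSE)
      }
      motifSites <- do.call(rbind, rows)
      edgeTab <- do.call(rbind, edges)
      if (!is.null(edgeTab))
        edgeTab <- edgeTab[!duplicated(edgeTab[c("tf", "target", "cell_type")]), ]
    }
  })

  ## ChIP tracks -------------------------------------------------------------
  marks <- names(cfg$histone_overlap_frac)
  chip <- list()
  hmTab <- NULL
  withSubstream(cfg$seed, "chip", {
    hmRows <- list()
    for (ct in cfg$cell_types) {
      dset <- if (is.null(dapTab)) NULL else dapTab[dapTab$contrast == ct, ]
      for (mk in marks) {
        frac <- cfg$histone_overlap_frac[[mk]]
        covered <- integer(0)
        if (!is.null(dset) && nrow(dset)) {
          nCov <- round(frac * nrow(dset))
          covered <- sample(dset$peak_index, nCov)
        }
        covIv <- if (length(covered)) {
          jit <- sample(50:150, length(covered), replace = TRUE)
          data.frame(chrom = peakTab$chrom[covered],
                     start = pmax(0L, peakTab$start[covered] - jit),
                     end = peakTab$end[covered] + jit)
        } else NULL
        # background intervals, discarded if they touch any peak
        nBg <- 50
        bgStart <- floor(runif(nBg, cfg$genome_length_bp * 0.96,
                               cfg$genome_length_bp * 0.99))
        bgIv <- data.frame(chrom = sample(autos, nBg, replace = TRUE),
                           start = as.integer(bgStart),
                           end = as.integer(bgStart + 500))
        bgGr <- grFromBed0(bgIv$chrom, bgIv$start, bgIv$end)
        bgIv <- bgIv[!IRanges::overlapsAny(bgGr, peaks), , drop = FALSE]
        iv <- rbind(covIv, bgIv)
        chip[[paste(mk, ct, sep = ".")]] <-
          grFromBed0(iv$chrom, iv$start, iv$end)
        if (!is.null(dset) && nrow(dset))
          hmRows[[length(hmRows) + 1]] <- data.frame(
            peak_id = dset$peak_id, mark = mk, cell_state = ct,
            member = dset$peak_index %in% covered, stringsAsFactors = FALSE)
      }
    }
    hmTab <- do.call(rbind, hmRows)
  })

  ## count matrices ----------------------------------------------------------
  rnaM <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
            dims = c(cfg$n_genes, nCells),
            dimnames = list(gm$gene_id, cells$barcode))
  atacM <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
            dims = c(cfg$n_peaks, nCells),
            dimnames = list(peakTab$peak_id, cells$barcode))
  if (nCells > 0) {
    sfRna <- withSubstream(cfg$seed, "sizefactors",
                           stats::rlnorm(nCells, -0.3^2 / 2, 0.3))
    sfAtac <- withSubstream(cfg$seed, "sizefactors.atac",
                            stats::rlnorm(nCells, -0.3^2 / 2, 0.3))
    isXY <- cells$declared_sex == "XY"
    half <- cfg$deg_log2fc / 2

    ## RNA rates
    baseG <- withSubstream(cfg$seed, "rna.base",
                           stats::rlnorm(cfg$n_genes, 0, 1))
    baseG[isMt] <- stats::median(baseG) * 2  # modest mitochondrial fraction
    ## network TFs are well-expressed genes (their real counterparts are major
    ## lineage regulators), not draws from the genome-wide expression prior
    baseG[seq_along(tfNames)] <- stats::quantile(baseG, 0.9)
    lograte <- matrix(log(baseG), cfg$n_genes, nCells)
    for (i in seq_len(nrow(markerTab))) {
      gi <- match(markerTab$gene_id[i], gm$gene_id)
      sel <- cells$cell_type == markerTab$cell_type[i]
      lograte[gi, sel] <- lograte[gi, sel] + log(8)
    }
    if (!is.null(degTab)) for (i in seq_len(nrow(degTab))) {
      gi <- match(degTab$gene_id[i], gm$gene_id)
      sel <- cells$cell_type == degTab$contrast[i]
      up <- if (degTab$sign[i] == "up_in_XY") isXY else !isXY
      lograte[gi, sel & up] <- lograte[gi, sel & up] + half * log(2)
      lograte[gi, sel & !up] <- lograte[gi, sel & !up] - half * log(2)
    }
    ## ATAC rates
    baseP <- withSubstream(cfg$seed, "atac.base",
                           stats::rlnorm(cfg$n_peaks, 0, 0.8))
    lorate <- matrix(log(baseP), cfg$n_peaks, nCells)
    if (!is.null(dapTab)) for (i in seq_len(nrow(dapTab))) {
      pi <- dapTab$peak_index[i]
      sel <- cells$cell_type == dapTab$contrast[i]
      up <- if (dapTab$sign[i] == "up_in_XY") isXY else !isXY
      lorate[pi, sel & up] <- lorate[pi, sel & up] + half * log(2)
      lorate[pi, sel & !up] <- lorate[pi, sel & !up] - half * log(2)
    }
    ## latent link factors couple peaks and genes: one per-cell activity
    ## factor per target gene (so a gene with several linked peaks does not
    ## accumulate variance), each linked peak coupled with the link's sign
    if (!is.null(linkTab) && nrow(linkTab) && cfg$link_strength != 0) {
      gUnique <- unique(linkTab$gene_index)
      fac <- withSubstream(cfg$seed, "link.factors",
               matrix(stats::rnorm(length(gUnique) * nCells), length(gUnique)))
      for (k in seq_along(gUnique))
        lograte[gUnique[k], ] <- lograte[gUnique[k], ] +
          cfg$link_strength * fac[k, ]
      couple <- linkTab[!duplicated(linkTab[c("peak_id", "gene_id")]), ]
      for (r in seq_len(nrow(couple))) {
        s <- if (couple$sign[r] == "positive") 1 else -1
        k <- match(couple$gene_index[r], gUnique)
        pi <- couple$peak_index[r]
        lorate[pi, ] <- lorate[pi, ] + s * cfg$link_strength * fac[k, ]
      }
    }
    ## Y-linked expression and chrY fragments: XY only
    lograte[isY, !isXY] <- -Inf
    lorate[chrYPeak, ] <- log(2)  # modest chrY peak rate in XY
    lorate[chrYPeak, !isXY] <- -Inf

    rateR <- exp(lograte)
    rateA <- exp(lorate)
    ## calibrate expected library per cell
    colR <- colSums(rateR); colR[colR == 0] <- 1
    colA <- colSums(rateA); colA[colA == 0] <- 1
    rateR <- sweep(rateR, 2, sfRna * cfg$mean_library_rna / colR, "*")
    rateA <- sweep(rateA, 2, sfAtac * cfg$mean_library_atac / colA, "*")

    cnts <- withSubstream(cfg$seed, "rna.counts", {
      v <- as.vector(rateR)
      out <- numeric(length(v))
      pos <- v > 0
      out[pos] <- if (cfg$nb_dispersion > 0)
        stats::rnbinom(sum(pos), mu = v[pos], size = 1 / cfg$nb_dispersion)
      else stats::rpois(sum(pos), v[pos])
      matrix(out, cfg$n_genes)
    })
    acnts <- withSubstream(cfg$seed, "atac.counts", {
      v <- as.vector(rateA)
      out <- numeric(length(v))
      pos <- v > 0
      out[pos] <- stats::rpois(sum(pos), v[pos])
      matrix(out, cfg$n_peaks)
    })
    ## chrY peak: guarantee >= 1 fragment in XY cells
    acnts[chrYPeak, isXY] <- acnts[chrYPeak, isXY] + 1
    dimnames(cnts) <- list(gm$gene_id, cells$barcode)
    dimnames(acnts) <- list(peakTab$peak_id, cells$barcode)
    rnaM <- methods::as(Matrix::Matrix(cnts, sparse = TRUE), "CsparseMatrix")
    atacM <- methods::as(Matrix::Matrix(acnts, sparse = TRUE), "CsparseMatrix")
  }

  ## cell QC metrics ---------------------------------------------------------
  libR <- Matrix::colSums(rnaM)
  mtRows <- which(isMt)
  pctMt <- if (nCells > 0 && length(mtRows))
    100 * Matrix::colSums(rnaM[mtRows, , drop = FALSE]) / pmax(libR, 1)
  else numeric(nCells)
  qcm <- withSubstream(cfg$seed, "qc.metrics", {
    data.frame(nucleosome_signal = stats::runif(nCells, 0.5, 1.5),
               tss_enrichment = stats::runif(nCells, 2, 6))
  })
  cellsDF <- S4Vectors::DataFrame(
    barcode = cells$barcode, declared_sex = cells$declared_sex,
    stage = cells$stage, cell_type = cells$cell_type,
    n_count_rna = as.numeric(libR), percent_mt = as.numeric(pctMt),
    n_count_atac = as.numeric(Matrix::colSums(atacM)),
    nucleosome_signal = if (nCells) qcm$nucleosome_signal else numeric(0),
    tss_enrichment = if (nCells) qcm$tss_enrichment else numeric(0),
    chry_fragments = as.numeric(atacM[chrYPeak, ]))

  genome <- Biostrings::DNAStringSet(vapply(genomeChars, paste,
                                            character(1), collapse = ""))
  names(genome) <- chroms

  emptyDf <- function(cols) as.data.frame(setNames(
    rep(list(character(0)), length(cols)), cols))
  truth <- list(
    true_degs = if (is.null(degTab)) emptyDf(c("gene_id", "contrast", "sign"))
                else degTab,
    true_daps = if (is.null(dapTab)) emptyDf(c("peak_id", "contrast", "sign"))
                else dapTab[c("peak_id", "contrast", "sign")],
    true_links = if (is.null(linkTab))
        emptyDf(c("peak_id", "gene_id", "cell_type", "sign"))
      else linkTab[c("peak_id", "gene_id", "cell_type", "sign")],
    true_motif_sites = if (is.null(motifSites))
        emptyDf(c("motif_id", "tf", "chrom", "start", "end", "strand", "peak_id"))
      else motifSites,
    true_network_edges = if (is.null(edgeTab))
        emptyDf(c("tf", "target", "sign", "cell_type", "peak_id"))
      else edgeTab,
    true_histone_membership = if (is.null(hmTab))
        emptyDf(c("peak_id", "mark", "cell_state", "member"))
      else hmTab,
    marker_genes = if (is.null(markerTab)) emptyDf(c("cell_type", "gene_id"))
                   else markerTab)

  new("MultiomeDataset",
      rna = CountMatrix(rnaM, "rna"), atac = CountMatrix(atacM, "atac"),
      cells = cellsDF, peaks = peaks, geneModels = gm, exons = exons,
      genome = genome, chipTracks = chip, truth = truth)
}

#' Write a full synthetic dataset to disk in standard formats
#'
#' MatrixMarket trio per modality, peaks.bed, genome.fa, genes.tsv, cells.tsv,
#' one BED per ChIP track and TSV truth tables under `truth/`.
#'
#' @param ds a [MultiomeDataset-class].
#' @param directory output directory.
#' @return invisibly, the directory.
#' @export
writeDataset <- function(ds, directory) {
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  writeMtxTriplet(rnaCounts(ds), file.path(directory, "rna_matrix.mtx"),
                  file.path(directory, "rna_features.tsv"),
                  file.path(directory, "rna_barcodes.tsv"))
  writeMtxTriplet(atacCounts(ds), file.path(directory, "atac_matrix.mtx"),
                  file.path(directory, "atac_features.tsv"),
                  file.path(directory, "atac_barcodes.tsv"))
  writeBed(peakRanges(ds), file.path(directory, "peaks.bed"))
  gen <- genomeSeq(ds)
  con <- file(file.path(directory, "genome.fa"), "w")
  for (i in seq_along(gen)) {
    writeLines(paste0(">", names(gen)[i]), con)
    sq <- as.character(gen[[i]])
    writeLines(substring(sq, seq(1, nchar(sq), 80),
                         pmin(seq(1, nchar(sq), 80) + 79, nchar(sq))), con)
  }
  close(con)
  write.table(geneModels(ds), file.path(directory, "genes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(cellData(ds)), file.path(directory, "cells.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(chipTracks(ds)))
    writeBed(chipTracks(ds)[[nm]],
             file.path(directory, paste0("chip_", gsub("\\.", "_", nm), ".bed")))
  writeTruth(truthTables(ds), file.path(directory, "truth"))
  invisible(directory)
}
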