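## Seeded synthetic-data generator: toy genome, LD blocks, ChIP-seq-like
## peak sets with a controllable planted per-block probability over a
## uniform Poisson background, TAD partitions, gene models and DEG tables,
## with every planted item recorded as ground truth. All emitted files are
## byte-identical under a fixed seed.

#' Simulation configuration
#'
#' Defaults emulate the study's operating point: 16 blocks whose length
#' multiset is the published block-length set (mean ~30.6 kb), a peak
#' background of 15 peaks/Mb (the density scale of ENCODE-grade histone
#' peak files), lognormal peak lengths with ~1 kb median, Mb-scale TADs,
#' ~12 genes per TAD, and a 6% DEG fraction per comparison so the union
#' over the two comparisons lands near the ~12% share of TAD transcripts
#' with reported tissue differential expression.
#'
#' @param chrom_lengths Named vector of toy chromosome lengths (bp).
#' @param n_blocks Number of LD blocks.
#' @param block_lengths Block length multiset (recycled/truncated to
#'   `n_blocks`); defaults to the 16 published block lengths.
#' @param lambda_per_mb Background peak density (peaks per Mb).
#' @param peak_meanlog,peak_sdlog Lognormal peak-length parameters.
#' @param planted_prob Default per-block probability that a peak is
#'   planted inside the block (0 = pure null).
#' @param peak_sets Data frame with columns `cell_type`, `mark`,
#'   `planted_prob` describing which peak files to emit; `NULL` gives a
#'   default design of one planted cell type (HUVEC, three activating
#'   marks at `planted_prob`, plus a background-only H3K9me3 set) and one
#'   null cell type (SMC).
#' @param tad_size_range Uniform range of TAD sizes (bp).
#' @param genes_per_tad Mean genes per TAD (Poisson).
#' @param gene_length_range Uniform range of gene lengths (bp).
#' @param deg_fraction Fraction of TAD genes planted as DEGs, per
#'   comparison.
#' @param n_decoy_degs DEG records for symbols absent from the gene
#'   annotation (non-trivial negatives for overlap code).
#' @param boundary_spanning If `TRUE`, TAD boundaries are not moved off
#'   the blocks, so blocks may span domain boundaries (exercises the
#'   partial-containment fallback).
#' @return A `sim_config` list.
#' @export
sim_config <- function(chrom_lengths = c(chrS1 = 25e6, chrS2 = 25e6,
                                         chrS3 = 25e6, chrS4 = 25e6),
                       n_blocks = 16,
                       block_lengths = NULL,
                       lambda_per_mb = 15,
                       peak_meanlog = log(1000), peak_sdlog = 0.5,
                       planted_prob = 0,
                       peak_sets = NULL,
                       tad_size_range = c(5e5, 1.5e6),
                       genes_per_tad = 12,
                       gene_length_range = c(2e3, 8e4),
                       deg_fraction = 0.06,
                       n_decoy_degs = 10,
                       boundary_spanning = FALSE) {
  if (is.null(block_lengths)) {
    block_lengths <- interval_length(ia_ld_blocks())
  }
  block_lengths <- rep_len(block_lengths, n_blocks)
  if (is.null(peak_sets)) {
    peak_sets <- data.frame(
      cell_type = c(rep("HUVEC", 3), rep("SMC", 3), "HUVEC"),
      mark = c(ACTIVATING_MARKS, ACTIVATING_MARKS, "H3K9me3"),
      planted_prob = c(rep(planted_prob, 3), 0, 0, 0, 0),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(chrom_lengths > 0),
            all(peak_sets$planted_prob >= 0 & peak_sets$planted_prob <= 1),
            planted_prob >= 0, planted_prob <= 1,
            lambda_per_mb >= 0, deg_fraction >= 0, deg_fraction <= 1,
            all(block_lengths >= 1))
  structure(list(chrom_lengths = chrom_lengths, n_blocks = n_blocks,
                 block_lengths = block_lengths,
                 lambda_per_mb = lambda_per_mb,
                 peak_meanlog = peak_meanlog, peak_sdlog = peak_sdlog,
                 planted_prob = planted_prob, peak_sets = peak_sets,
                 tad_size_range = tad_size_range,
                 genes_per_tad = genes_per_tad,
                 gene_length_range = gene_length_range,
                 deg_fraction = deg_fraction,
                 n_decoy_degs = n_decoy_degs,
                 boundary_spanning = boundary_spanning),
            class = "sim_config")
}

#' Toy genome chromosome sizes
#' @param config A [sim_config()].
#' @return Named numeric vector of chromosome lengths.
#' @export
gen_genome <- function(config) {
  config$chrom_lengths
}

#' Generate non-overlapping LD blocks with synthetic sentinel SNPs
#'
#' Block lengths follow `config$block_lengths`; placement is uniform with
#' rejection of overlaps. Each block gets a synthetic rsID and a sentinel
#' position drawn uniformly within it.
#'
#' @param config A [sim_config()].
#' @param genome From [gen_genome()].
#' @param seed Integer seed.
#' @return An `ld_blocks` table.
#' @export
gen_blocks <- function(config, genome, seed = NULL) {
  lens <- config$block_lengths
  if (max(lens) > max(genome)) stop("genome too small for block lengths")
  draw <- function() {
    acc <- genomic_intervals(character(), numeric(), numeric())
    for (k in seq_along(lens)) {
      placed <- FALSE
      for (try in 1:1000) {
        cand <- sample_random_regions(genome, 1, lens[k])
        clash <- any(acc$chrom == cand$chrom &
                       acc$start < cand$end & cand$start < acc$end)
        if (!clash) {
          acc <- rbind(acc, cand)
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("genome too small: cannot place non-overlapping blocks")
    }
    acc$name <- sprintf("rs9%06d", seq_along(lens))
    out <- genomic_intervals(acc$chrom, acc$start, acc$end, acc$name)
    out$snp_id <- out$name
    out$snp_pos <- floor(out$start + stats::runif(nrow(out)) *
                           (out$end - out$start))
    out$snp_location <- sample(c("intronic", "exonic", "intergenic"),
                               nrow(out), replace = TRUE,
                               prob = c(0.5, 0.25, 0.25))
    out$nearest_gene <- NA_character_
    ld_blocks(out)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Generate a peak set with planted per-block enrichment
#'
#' Background peaks form a Poisson process of `config$lambda_per_mb` over
#' the genome (they may fall inside blocks by chance, keeping the null
#' exactly uniform); independently, with probability `planted_prob`, one
#' additional peak is planted fully inside each block.
#'
#' @inheritParams gen_blocks
#' @param blocks Blocks from [gen_blocks()] (or the bundled set).
#' @param planted_prob Per-block planting probability.
#' @param cell_type,mark Labels for the emitted [peak_set()].
#' @return List: `peaks` (a `peak_set`) and `planted` (named logical,
#'   ground truth of which blocks carry a planted peak).
#' @export
gen_peaks <- function(config, genome, blocks, planted_prob = NULL,
                      cell_type = "synthetic", mark = "H3K27ac",
                      seed = NULL) {
  if (is.null(planted_prob)) planted_prob <- config$planted_prob
  stopifnot(planted_prob >= 0, planted_prob <= 1)
  blocks <- .as_intervals(blocks)
  draw <- function() {
    n_bg <- stats::rpois(1, config$lambda_per_mb * sum(genome) / 1e6)
    bg <- if (n_bg > 0) {
      len <- pmax(1, round(stats::rlnorm(n_bg, config$peak_meanlog,
                                         config$peak_sdlog)))
      ch <- sample(names(genome), n_bg, replace = TRUE, prob = genome)
      start <- floor(stats::runif(n_bg) * pmax(1, genome[ch] - len + 1))
      genomic_intervals(ch, start, pmin(start + len, genome[ch]))
    } else {
      genomic_intervals(character(), numeric(), numeric())
    }
    planted <- stats::runif(nrow(blocks)) < planted_prob
    pl <- if (any(planted)) {
      b <- blocks[planted, , drop = FALSE]
      len <- pmax(1, pmin(round(stats::rlnorm(nrow(b), config$peak_meanlog,
                                              config$peak_sdlog)),
                          b$end - b$start))
      start <- floor(b$start + stats::runif(nrow(b)) *
                       (b$end - b$start - len + 1))
      genomic_intervals(b$chrom, start, start + len)
    } else {
      genomic_intervals(character(), numeric(), numeric())
    }
    names(planted) <- blocks$name
    list(peaks = peak_set(cell_type, mark, rbind(bg, pl),
                          source = "synthetic"),
         planted = planted)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Generate a TAD partition of the toy genome
#'
#' TADs tile each chromosome with sizes uniform over
#' `config$tad_size_range`. Unless `config$boundary_spanning` is set, any
#' boundary falling inside a block is pushed to the block's end so every
#' block is fully contained in one TAD by construction.
#'
#' @inheritParams gen_peaks
#' @param cell_type Label recorded in TAD names.
#' @return A `genomic_intervals` table of named, abutting TADs.
#' @export
gen_tads <- function(config, genome, blocks, cell_type = "synthetic",
                     seed = NULL) {
  blocks <- .as_intervals(blocks)
  draw <- function() {
    out <- lapply(names(genome), function(ch) {
      len <- genome[[ch]]
      cuts <- 0
      while (cuts[length(cuts)] < len) {
        cuts <- c(cuts, cuts[length(cuts)] +
                    stats::runif(1, config$tad_size_range[1],
                                 config$tad_size_range[2]))
      }
      cuts <- c(floor(cuts[-length(cuts)]), len)
      if (!config$boundary_spanning) {
        b <- blocks[blocks$chrom == ch, , drop = FALSE]
        for (i in seq_along(cuts)) {
          inside <- b$start < cuts[i] & cuts[i] < b$end
          if (any(inside)) cuts[i] <- min(b$end[inside][1], len)
        }
        cuts <- sort(unique(cuts))
      }
      genomic_intervals(ch, cuts[-length(cuts)], cuts[-1])
    })
    out <- do.call(rbind, out)
    out$name <- sprintf("%s_tad_%03d", cell_type, seq_len(nrow(out)))
    out
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Generate gene models scattered within TADs
#'
#' For each TAD of the supplied partition, a Poisson number of genes is
#' placed fully inside it, giving exact per-TAD rosters by construction.
#'
#' @inheritParams gen_peaks
#' @param tads A partition from [gen_tads()].
#' @return List: `genes` (intervals with `symbol`) and `tad_genes` (ground
#'   truth, TAD name -> symbols).
#' @export
gen_genes <- function(config, tads, seed = NULL) {
  draw <- function() {
    counter <- 0
    rows <- list()
    truth <- stats::setNames(vector("list", nrow(tads)), tads$name)
    for (i in seq_len(nrow(tads))) {
      k <- stats::rpois(1, config$genes_per_tad)
      if (k == 0) { truth[[i]] <- character(0); next }
      tlen <- tads$end[i] - tads$start[i]
      len <- pmax(1, pmin(round(stats::runif(k, config$gene_length_range[1],
                                             config$gene_length_range[2])),
                          tlen))
      start <- floor(tads$start[i] + stats::runif(k) * (tlen - len + 1))
      sym <- sprintf("GENE%05d", counter + seq_len(k))
      counter <- counter + k
      g <- genomic_intervals(tads$chrom[i], start, start + len, sym)
      g$symbol <- sym
      rows[[length(rows) + 1]] <- g
      truth[[i]] <- sym
    }
    genes <- if (length(rows)) do.call(rbind, rows) else {
      g <- genomic_intervals(character(), numeric(), numeric())
      g$symbol <- character(0)
      g
    }
    list(genes = genes, tad_genes = truth)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Generate a DEG table from TAD genes plus decoys
#'
#' Each comparison independently plants `config$deg_fraction` of the TAD
#' genes as DEGs (recorded as ground truth); decoy records use symbols
#' absent from the annotation. Directions are random; about a third of
#' fold-changes are withheld (NA), emulating studies that report none.
#'
#' @inheritParams gen_peaks
#' @param gene_symbols Character vector of all TAD gene symbols.
#' @return List: `degs` (a `deg_table`), `planted` (list per comparison of
#'   planted symbols), `decoys` (character).
#' @export
gen_degs <- function(config, gene_symbols, seed = NULL) {
  comparisons <- c("IA_vs_control", "ruptured_vs_unruptured")
  studies <- list(IA_vs_control = c("SimStudyA", "SimStudyB"),
                  ruptured_vs_unruptured = c("SimStudyC", "SimStudyD"))
  draw <- function() {
    planted <- list()
    rows <- list()
    mk_row <- function(sym, cmp) {
      dir <- sample(c("up", "down"), length(sym), replace = TRUE)
      fc <- round(stats::runif(length(sym), 0.5, 4), 2) *
        ifelse(dir == "up", 1, -1)
      fc[stats::runif(length(sym)) < 1 / 3] <- NA
      data.frame(symbol = sym,
                 study = sample(studies[[cmp]], length(sym), replace = TRUE),
                 comparison = cmp, direction = dir, log2fc = fc,
                 stringsAsFactors = FALSE)
    }
    for (cmp in comparisons) {
      hit <- gene_symbols[stats::runif(length(gene_symbols)) <
                            config$deg_fraction]
      planted[[cmp]] <- hit
      if (length(hit)) rows[[length(rows) + 1]] <- mk_row(hit, cmp)
    }
    decoys <- if (config$n_decoy_degs > 0) {
      sprintf("DECOY%03d", seq_len(config$n_decoy_degs))
    } else character(0)
    if (length(decoys)) {
      rows[[length(rows) + 1]] <-
        mk_row(decoys, sample(comparisons, 1))
    }
    degs <- if (length(rows)) do.call(rbind, rows) else {
      data.frame(symbol = character(0), study = character(0),
                 comparison = character(0), direction = character(0),
                 log2fc = numeric(0), stringsAsFactors = FALSE)
    }
    class(degs) <- c("deg_table", "data.frame")
    list(degs = degs, planted = planted, decoys = decoys)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Brute-force per-TAD gene rosters from generator-held tables (independent
# of genes_in_tads): >= 1 bp overlap.
.truth_tad_genes <- function(tads, genes) {
  stats::setNames(lapply(seq_len(nrow(tads)), function(i) {
    hit <- genes$chrom == tads$chrom[i] &
      genes$start < tads$end[i] & tads$start[i] < genes$end
    sort(unique(genes$symbol[hit]))
  }), tads$name)
}

#' Simulate a complete dataset on disk
#'
#' Emits `chrom.sizes`, `blocks.bed`, `blocks_meta.tsv`,
#' `peaks_<cell>_<mark>.bed` per configured peak set, `tads_<cell>.bed`
#' per cell type, `genes.bed`, `degs.tsv`, `ground_truth.json` and
#' `config.yaml` into `dir`. Byte-identical across runs for a fixed seed.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param seed Integer master seed; sub-seeds for each component are
#'   derived from it.
#' @return Invisibly, a list with the in-memory objects (`genome`,
#'   `blocks`, `peak_sets`, `tads`, `genes`, `degs`) and `truth` (planted
#'   blocks per peak set, per-cell-type block-TAD map and TAD gene
#'   rosters, planted DEG symbols, decoys), plus `files`.
#' @export
simulate_dataset <- function(config, dir, seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genome <- gen_genome(config)
  n_sub <- 4 + nrow(config$peak_sets) + 8
  sub <- withr::with_seed(seed, sample.int(2147483646L, n_sub))

  blocks <- gen_blocks(config, genome, seed = sub[1])
  cell_types <- unique(config$peak_sets$cell_type[
    config$peak_sets$mark %in% ACTIVATING_MARKS])
  tads <- stats::setNames(lapply(seq_along(cell_types), function(i) {
    gen_tads(config, genome, blocks, cell_type = cell_types[i],
             seed = sub[4 + nrow(config$peak_sets) + i])
  }), cell_types)
  gg <- gen_genes(config, tads[[1]], seed = sub[2])
  dd <- gen_degs(config, gg$genes$symbol, seed = sub[3])

  peak_sets <- vector("list", nrow(config$peak_sets))
  planted <- list()
  for (i in seq_len(nrow(config$peak_sets))) {
    ps <- config$peak_sets[i, ]
    gp <- gen_peaks(config, genome, blocks,
                    planted_prob = ps$planted_prob,
                    cell_type = ps$cell_type, mark = ps$mark,
                    seed = sub[4 + i])
    peak_sets[[i]] <- gp$peaks
    planted[[paste(ps$cell_type, ps$mark, sep = "_")]] <-
      names(gp$planted)[gp$planted]
  }

  # ground truth: block -> containing TAD, per-TAD rosters, per cell type
  tad_of_block <- lapply(tads, function(td) {
    stats::setNames(vapply(seq_len(nrow(blocks)), function(i) {
      hit <- td$chrom == blocks$chrom[i] & td$start <= blocks$start[i] &
        blocks$end[i] <= td$end
      if (any(hit)) td$name[which(hit)[1]] else NA_character_
    }, ""), blocks$name)
  })
  tad_genes <- lapply(tads, .truth_tad_genes, genes = gg$genes)

  files <- list(
    chrom_sizes = file.path(dir, "chrom.sizes"),
    blocks = file.path(dir, "blocks.bed"),
    blocks_meta = file.path(dir, "blocks_meta.tsv"),
    genes = file.path(dir, "genes.bed"),
    degs = file.path(dir, "degs.tsv"),
    ground_truth = file.path(dir, "ground_truth.json"),
    config = file.path(dir, "config.yaml"))
  write_chrom_sizes(genome, files$chrom_sizes)
  write_bed(blocks, files$blocks)
  meta <- as.data.frame(blocks)[c("snp_id", "snp_location", "nearest_gene",
                                  "chrom", "start", "end", "snp_pos")]
  utils::write.table(meta, files$blocks_meta, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_bed(gg$genes, files$genes)
  utils::write.table(
    transform(dd$degs, log2fc = ifelse(is.na(log2fc), "NR",
                                       format(log2fc, trim = TRUE))),
    files$degs, sep = "\t", quote = FALSE, row.names = FALSE)
  for (i in seq_len(nrow(config$peak_sets))) {
    ps <- config$peak_sets[i, ]
    f <- file.path(dir, sprintf("peaks_%s_%s.bed", ps$cell_type, ps$mark))
    write_bed(peak_sets[[i]]$peaks, f)
    files[[sprintf("peaks_%s_%s", ps$cell_type, ps$mark)]] <- f
  }
  for (ct in names(tads)) {
    f <- file.path(dir, sprintf("tads_%s.bed", ct))
    write_bed(tads[[ct]], f)
    files[[sprintf("tads_%s", ct)]] <- f
  }
  truth <- list(planted_blocks = planted,
                tad_of_block = lapply(tad_of_block, as.list),
                tad_genes = tad_genes, deg_planted = dd$planted,
                decoys = dd$decoys)
  jsonlite::write_json(truth, files$ground_truth, auto_unbox = TRUE,
                       pretty = TRUE, null = "list")
  cfg <- unclass(config)
  cfg$chrom_lengths <- as.list(cfg$chrom_lengths)
  cfg$seed <- seed
  yaml::write_yaml(cfg, files$config)
  invisible(list(genome = genome, blocks = blocks, peak_sets = peak_sets,
                 tads = tads, genes = gg$genes, degs = dd$degs,
                 truth = truth, files = files, seed = seed))
}
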