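test_that("block generation reuses the bundled length multiset", {
  cfg <- sim_config()
  g <- gen_genome(cfg)
  blocks <- gen_blocks(cfg, g, seed = 101)
  expect_equal(nrow(blocks), 16)
  expect_setequal(interval_length(blocks), interval_length(ia_ld_blocks()))
  # pairwise non-overlapping
  for (ch in unique(blocks$chrom)) {
    b <- blocks[blocks$chrom == ch, ]
    b <- b[order(b$start), ]
    if (nrow(b) > 1) expect_true(all(b$start[-1] >= b$end[-nrow(b)]))
  }
  # sentinel SNP inside its block
  expect_true(all(blocks$snp_pos >= blocks$start &
                    blocks$snp_pos < blocks$end))
  one <- gen_blocks(sim_config(n_blocks = 1), g, seed = 102)
  expect_equal(nrow(one), 1)
  expect_error(gen_blocks(cfg, c(tiny = 1000), seed = 103), "too small")
})

test_that("peak generation plants per-block peaks over Poisson background", {
  g <- c(chrT = 10e6)
  cfg0 <- sim_config(chrom_lengths = g, lambda_per_mb = 0)
  blocks <- gen_blocks(sim_config(chrom_lengths = g), g, seed = 111)
  # lambda = 0, pi = 0: empty set
  empty <- gen_peaks(cfg0, g, blocks, planted_prob = 0, seed = 112)
  expect_equal(nrow(empty$peaks$peaks), 0)
  # pi = 1: every block overlaps >= 1 peak
  full <- gen_peaks(cfg0, g, blocks, planted_prob = 1, seed = 113)
  expect_true(all(full$planted))
  expect_equal(count_marked_regions(blocks, full$peaks), 16)
  # Poisson background count near lambda * genome size
  cfg100 <- sim_config(chrom_lengths = g, lambda_per_mb = 100)
  bg <- gen_peaks(cfg100, g, blocks, planted_prob = 0, seed = 114)
  expect_lt(abs(nrow(bg$peaks$peaks) - 1000), 4 * sqrt(1000))
  # peaks stay inside the genome
  expect_true(all(bg$peaks$peaks$end <= g[bg$peaks$peaks$chrom]))
})

test_that("TAD partitions tile chromosomes and avoid cutting blocks", {
  cfg <- sim_config()
  g <- gen_genome(cfg)
  blocks <- gen_blocks(cfg, g, seed = 121)
  tads <- gen_tads(cfg, g, blocks, cell_type = "HUVEC", seed = 122)
  for (ch in names(g)) {
    td <- tads[tads$chrom == ch, ]
    td <- td[order(td$start), ]
    expect_equal(td$start[1], 0)
    expect_equal(td$end[nrow(td)], unname(g[ch]))
    expect_true(all(td$start[-1] == td$end[-nrow(td)]))  # abutting tiles
  }
  # every block fully inside one TAD
  for (i in seq_len(nrow(blocks))) {
    a <- assign_tads(blocks[i, ], tads)
    expect_false(a$partial)
    expect_equal(nrow(a$tads), 1)
  }
})

test_that("boundary-spanning mode produces partially contained blocks", {
  g <- c(chrT = 10e6)
  cfg <- sim_config(chrom_lengths = g, n_blocks = 12,
                    block_lengths = rep(75000, 12),
                    tad_size_range = c(4e4, 8e4),
                    boundary_spanning = TRUE)
  blocks <- gen_blocks(cfg, g, seed = 131)
  tads <- gen_tads(cfg, g, blocks, seed = 132)
  partial <- vapply(seq_len(nrow(blocks)),
                    function(i) assign_tads(blocks[i, ], tads)$partial,
                    logical(1))
  expect_true(any(partial))
})

test_that("gene rosters and planted DEGs match generator bookkeeping", {
  cfg <- sim_config()
  g <- gen_genome(cfg)
  blocks <- gen_blocks(cfg, g, seed = 141)
  tads <- gen_tads(cfg, g, blocks, seed = 142)
  gg <- gen_genes(cfg, tads, seed = 143)
  # genes are placed fully inside their TAD; rosters match rule "contained"
  for (i in sample(nrow(tads), 10)) {
    expect_identical(genes_in_tads(tads[i, ], gg$genes, "contained"),
                     sort(gg$tad_genes[[tads$name[i]]]))
  }
  dd <- gen_degs(sim_config(deg_fraction = 0.3), gg$genes$symbol, seed = 144)
  n_planted <- length(dd$planted$IA_vs_control)
  n_genes <- nrow(gg$genes)
  expect_lt(abs(n_planted - 0.3 * n_genes), 4 * sqrt(0.3 * 0.7 * n_genes))
  # planted sets are recoverable exactly from the emitted table
  in_table <- unique(dd$degs$symbol[dd$degs$comparison == "IA_vs_control" &
                                      !startsWith(dd$degs$symbol, "DECOY")])
  expect_setequal(in_table, dd$planted$IA_vs_control)
  expect_true(all(startsWith(dd$decoys, "DECOY")))
  expect_false(any(dd$decoys %in% gg$genes$symbol))
})

test_that("simulated datasets are byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- sim_config(planted_prob = 0.9)
  s1 <- simulate_dataset(cfg, d1, seed = 151)
  s2 <- simulate_dataset(cfg, d2, seed = 151)
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }
  # a different seed changes the data
  d3 <- withr::local_tempdir()
  simulate_dataset(cfg, d3, seed = 152)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "blocks.bed"))),
                         unname(tools::md5sum(file.path(d3, "blocks.bed")))))
})

test_that("ground truth is recoverable from the emitted files alone", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(planted_prob = 1)
  sim <- simulate_dataset(cfg, dir, seed = 161)
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                               simplifyVector = TRUE)
  blocks <- read_bed(file.path(dir, "blocks.bed"))
  # planted blocks are marked in the emitted peak files
  for (key in names(truth$planted_blocks)) {
    ps <- read_bed(file.path(dir, paste0("peaks_", key, ".bed")))
    marked <- blocks$name[intersect_counts(blocks, ps) > 0]
    expect_true(all(unlist(truth$planted_blocks[[key]]) %in% marked))
  }
  # block -> TAD truth matches assignment on the emitted TAD files
  for (ct in names(truth$tad_of_block)) {
    tads <- read_bed(file.path(dir, paste0("tads_", ct, ".bed")))
    for (i in seq_len(nrow(blocks))) {
      a <- assign_tads(blocks[i, ], tads)
      expect_equal(a$tads$name[1],
                   truth$tad_of_block[[ct]][[blocks$name[i]]])
    }
  }
  # roster truth matches genes_in_tads on the emitted files
  genes <- read_genes(file.path(dir, "genes.bed"))
  ct1 <- names(truth$tad_genes)[1]
  tads1 <- read_bed(file.path(dir, paste0("tads_", ct1, ".bed")))
  for (nm in sample(tads1$name, 5)) {
    got <- genes_in_tads(tads1[tads1$name == nm, ], genes)
    want <- sort(unlist(truth$tad_genes[[ct1]][[nm]]))
    if (length(want) == 0) want <- character(0)
    expect_identical(got, want)
  }
})
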