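toy_genome <- c(chrT = 1e6)

test_that("random regions respect bounds and are reproducible", {
  g <- c(chrT = 1000)
  r <- sample_random_regions(g, 3, 100, seed = 7)
  expect_equal(nrow(r), 3)
  expect_true(all(r$start >= 0 & r$start <= 900))
  expect_true(all(r$end - r$start == 100))
  expect_identical(sample_random_regions(g, 3, 100, seed = 7), r)
  expect_false(identical(sample_random_regions(g, 3, 100, seed = 8), r))
  expect_error(sample_random_regions(g, 1, 2000), "exceeds every chromosome")
})

test_that("chromosomes are chosen proportionally to valid placements", {
  g <- c(chrA = 1e6, chrB = 1e6)
  r <- sample_random_regions(g, 10000, 1000, seed = 11)
  tab <- table(factor(r$chrom, levels = names(g)))
  expect_gt(stats::chisq.test(tab, p = c(0.5, 0.5))$p.value, 0.001)
  # unequal chromosomes: expected share follows len - L + 1
  g2 <- c(chrA = 3e6, chrB = 1e6)
  r2 <- sample_random_regions(g2, 10000, 1000, seed = 12)
  w <- (g2 - 1000 + 1) / sum(g2 - 1000 + 1)
  tab2 <- table(factor(r2$chrom, levels = names(g2)))
  expect_gt(stats::chisq.test(tab2, p = w)$p.value, 0.001)
})

test_that("marked-region counting is region-level, not pair-level", {
  regions <- genomic_intervals(c("chrT", "chrT"), c(0, 5000), c(1000, 6000))
  peaks <- peak_set("t", "H3K27ac",
                    genomic_intervals(rep("chrT", 3), c(10, 200, 400),
                                      c(50, 300, 600)))
  expect_equal(count_marked_regions(regions, peaks), 1)
  # saturation: every region marked
  wide <- peak_set("t", "H3K27ac", genomic_intervals("chrT", 0, 1e6))
  r16 <- sample_random_regions(toy_genome, 16, 500, seed = 3)
  expect_equal(count_marked_regions(r16, wide), 16)
})

test_that("fast overlap counting equals the brute-force oracle", {
  withr::local_seed(403)
  for (rep in 1:100) {
    regions <- rand_intervals(sample(1:30, 1))
    peaks <- rand_intervals(sample(1:200, 1))
    expect_identical(count_marked_regions(regions, peaks),
                     bf_count_marked(regions, peaks))
    ps <- peak_set("t", "m", peaks)
    expect_identical(sum(intersect_counts(regions, ps$peaks)),
                     sum(bf_intersect_counts(regions, peaks)))
  }
})

test_that("null distribution handles saturation, emptiness and coverage", {
  wide <- peak_set("t", "H3K27ac", genomic_intervals("chrT", 0, 1e6))
  nd <- build_null(toy_genome, wide, region_count = 16, region_length = 500,
                   iterations = 50, seed = 1)
  expect_true(all(nd$counts == 16))
  expect_equal(nd$sigma, 0)

  none <- peak_set("t", "H3K27ac",
                   genomic_intervals(character(), numeric(), numeric()))
  nd0 <- build_null(toy_genome, none, region_count = 16, region_length = 500,
                    iterations = 50, seed = 1)
  expect_true(all(nd0$counts == 0))
  expect_equal(nd0$mu, 0)

  # peaks covering fraction c, region length -> 0: mu/region_count -> c
  cov <- peak_set("t", "H3K27ac", genomic_intervals("chrT", 0, 3e5))
  ndc <- build_null(toy_genome, cov, region_count = 16, region_length = 1,
                    iterations = 1000, seed = 2)
  expect_lt(abs(ndc$mu / 16 - 0.3), 0.02)
})

test_that("null draws are prefix-stable in the iteration count", {
  cfg <- sim_config()
  gp <- gen_peaks(cfg, toy_genome, genomic_intervals("chrT", 0, 1000),
                  planted_prob = 0, seed = 5)
  a <- build_null(toy_genome, gp$peaks, 16, 500, iterations = 40, seed = 9)
  b <- build_null(toy_genome, gp$peaks, 16, 500, iterations = 120, seed = 9)
  expect_identical(a$counts, b$counts[1:40])
})

test_that("z-score and normal-tail p behave at the declared edge cases", {
  nd <- structure(list(counts = rep(c(2, 6), 10), iterations = 20,
                       mu = 4, sigma = 2),
                  class = "null_distribution")
  expect_equal(z_score(4, nd), 0)
  expect_equal(z_score(10, nd), 3)
  expect_equal(p_from_z(0), 0.5)
  expect_lt(abs(p_from_z(1.96, "two_sided") - 0.05), 0.001)
  expect_equal(p_from_z(Inf), 0)
  degen <- structure(list(counts = rep(5, 10), iterations = 10,
                          mu = 5, sigma = 0),
                     class = "null_distribution")
  expect_identical(z_score(9, degen), Inf)
  expect_identical(z_score(5, degen), 0)
  expect_identical(z_score(1, degen), -Inf)
})

test_that("empirical p follows the add-one rank formula", {
  nd <- structure(list(counts = c(0:9), iterations = 10),
                  class = "null_distribution")
  expect_equal(empirical_p(20, nd), 1 / 11)
  expect_equal(empirical_p(0, nd), 1)
  expect_equal(empirical_p(8, nd), 3 / 11)
  big <- structure(list(counts = rep(0, 1000), iterations = 1000),
                   class = "null_distribution")
  expect_equal(empirical_p(1, big), 1 / 1001)
})

test_that("empirical p sits near 0.5 at the null median", {
  cfg <- sim_config()
  gp <- gen_peaks(cfg, c(chrS1 = 25e6), genomic_intervals("chrS1", 0, 1000),
                  planted_prob = 0, seed = 21)
  nd <- build_null(c(chrS1 = 25e6), gp$peaks, 16, 30636,
                   iterations = 1000, seed = 22)
  expect_lt(abs(empirical_p(stats::median(nd$counts), nd) - 0.5), 0.15)
})

test_that("planted enrichment is declared significant, empty sets are not", {
  cfg <- sim_config()
  g <- gen_genome(cfg)
  blocks <- gen_blocks(cfg, g, seed = 31)
  gp <- gen_peaks(cfg, g, blocks, planted_prob = 14 / 16, seed = 32)
  res <- test_enrichment(blocks, gp$peaks, g, iterations = 300, seed = 33)
  expect_lt(res$p_z, 0.05)
  expect_true(all((res$per_block_counts > 0)[gp$planted]))

  none <- peak_set("t", "H3K27ac",
                   genomic_intervals(character(), numeric(), numeric()))
  res0 <- test_enrichment(blocks, none, g, iterations = 50, seed = 34)
  expect_equal(res0$x, 0)
  expect_true(res0$degenerate)
  expect_equal(res0$p_emp, 1)
})

test_that("results are bit-identical under a fixed seed", {
  cfg <- sim_config()
  g <- gen_genome(cfg)
  blocks <- gen_blocks(cfg, g, seed = 41)
  gp <- gen_peaks(cfg, g, blocks, planted_prob = 0.5, seed = 42)
  a <- test_enrichment(blocks, gp$peaks, g, iterations = 100, seed = 43)
  b <- test_enrichment(blocks, gp$peaks, g, iterations = 100, seed = 43)
  expect_identical(a, b)
})

test_that("marking one more block raises x by 1 and never raises p_emp", {
  cfg <- sim_config()
  g <- gen_genome(cfg)
  blocks <- gen_blocks(cfg, g, seed = 51)
  gp <- gen_peaks(cfg, g, blocks, planted_prob = 0.4, seed = 52)
  res <- test_enrichment(blocks, gp$peaks, g, iterations = 100, seed = 53)
  unmarked <- which(res$per_block_counts == 0)[1]
  extra <- genomic_intervals(blocks$chrom[unmarked],
                             blocks$start[unmarked],
                             blocks$start[unmarked] + 100)
  ps2 <- peak_set(gp$peaks$cell_type, gp$peaks$mark,
                  rbind(gp$peaks$peaks, extra))
  res2 <- test_enrichment(blocks, ps2, g, iterations = 100, seed = 53)
  expect_equal(res2$x, res$x + 1)
  expect_lte(res2$p_emp, res$p_emp)
})

test_that("x and null counts never exceed the region count", {
  cfg <- sim_config()
  g <- gen_genome(cfg)
  blocks <- gen_blocks(cfg, g, seed = 61)
  gp <- gen_peaks(cfg, g, blocks, planted_prob = 1, seed = 62)
  res <- test_enrichment(blocks, gp$peaks, g, iterations = 200, seed = 63)
  expect_equal(res$x, nrow(blocks))
  expect_true(all(res$null$counts <= nrow(blocks)))
})

test_that("pair-count mode counts overlapping pairs, not regions", {
  regions <- genomic_intervals("chrT", c(0, 5000), c(1000, 6000),
                               c("a", "b"))
  peaks <- peak_set("t", "H3K27ac",
                    genomic_intervals(rep("chrT", 3), c(10, 200, 5100),
                                      c(50, 300, 5200)))
  res <- test_enrichment(regions, peaks, toy_genome, iterations = 20,
                         seed = 2, stat = "pairs")
  expect_equal(res$x, 3)
  res_r <- test_enrichment(regions, peaks, toy_genome, iterations = 20,
                           seed = 2, stat = "regions")
  expect_equal(res_r$x, 2)
})

test_that("repressive-mark check reports per-block presence", {
  blocks <- genomic_intervals(rep("chrT", 4), c(0, 100, 200, 300) * 1000,
                              c(50, 150, 250, 350) * 1000,
                              sprintf("b%d", 1:4))
  none <- peak_set("HUVEC", "H3K9me3",
                   genomic_intervals("chrT", 900000, 901000))
  chk <- negative_mark_check(blocks, none)
  expect_equal(chk$n_marked, 0)
  expect_equal(chk$n_blocks, 4)

  one <- peak_set("HUVEC", "H3K9me3",
                  genomic_intervals("chrT", 110000, 111000))
  chk1 <- negative_mark_check(blocks, one)
  expect_equal(chk1$n_marked, 1)
  expect_true(chk1$per_block[["b2"]])

  empty <- peak_set("HUVEC", "H3K9me3",
                    genomic_intervals(character(), numeric(), numeric()))
  expect_warning(chk0 <- negative_mark_check(blocks, empty), "empty")
  expect_equal(chk0$n_marked, 0)
  # warns when handed an activating mark
  expect_warning(negative_mark_check(blocks,
                                     peak_set("HUVEC", "H3K27ac",
                                              genomic_intervals("chrT", 0, 10))),
                 "not a repressive")
})

test_that("presence bins follow the none/1-5/6-10/11+ legend", {
  expect_equal(as.character(enrichment_bin(c(0, 1, 5, 6, 7, 10, 11, 40))),
               c("none", "low", "low", "mid", "mid", "mid", "high", "high"))
  expect_error(enrichment_bin(-1), "non-negative")
})

test_that("empirical p is approximately uniform for many regions", {
  # Exchangeable construction: observed and null counts drawn identically
  # (uniform background peaks, random regions). 1024 regions give the
  # count distribution enough spread for near-uniform ranks.
  cfg <- sim_config()
  g <- gen_genome(cfg)
  gp <- gen_peaks(cfg, g, gen_blocks(cfg, g, seed = 71), planted_prob = 0,
                  seed = 72)
  nd <- build_null(g, gp$peaks, region_count = 1024, region_length = 30636,
                   iterations = 500 * 101, seed = 73)
  m <- matrix(nd$counts, nrow = 101)
  p <- vapply(seq_len(ncol(m)),
              function(r) (1 + sum(m[-1, r] >= m[1, r])) / 101, numeric(1))
  ks <- suppressWarnings(stats::ks.test(p, "punif")$statistic)
  expect_lt(ks, 1.358 / sqrt(500))  # 5% critical value
  rate <- mean(p < 0.05)
  expect_gt(rate, 0.05 - 1.96 * sqrt(0.05 * 0.95 / 500))
  expect_lt(rate, 0.05 + 1.96 * sqrt(0.05 * 0.95 / 500))
})

test_that("z-based and empirical p agree when the null is near-normal", {
  cfg <- sim_config()
  g <- gen_genome(cfg)
  gp <- gen_peaks(cfg, g, gen_blocks(cfg, g, seed = 81), planted_prob = 0,
                  seed = 82)
  nd <- build_null(g, gp$peaks, region_count = 1024, region_length = 30636,
                   iterations = 50 * 1001, seed = 83)
  m <- matrix(nd$counts, nrow = 1001)
  d <- vapply(seq_len(ncol(m)), function(r) {
    x <- m[1, r]
    cts <- m[-1, r]
    mu <- mean(cts)
    sg <- sqrt(mean((cts - mu)^2))
    abs(stats::pnorm((x - mu) / sg, lower.tail = FALSE) -
          (1 + sum(cts >= x)) / 1001)
  }, numeric(1))
  expect_lt(stats::median(d), 0.02)
})
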