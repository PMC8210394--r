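#!/usr/bin/env Rscript
# Step 4: calibration study of the enrichment test at the study operating
# point (16 blocks, bundled length multiset, 15 peaks/Mb background).
#
# Compares three ways of scoring the same observed statistic under a
# pure-null background (pi = 0):
#   fixed_z    - fixed mean-length random regions, z-score p (the
#                published procedure)
#   resample_z - null regions resample the actual block lengths, z-score p
#   resample_emp - same null, rank-based empirical p
# and measures power under planted enrichment (pi = 0.9, sparse
# background). 300 null replicates and 150 power replicates with
# 200-iteration nulls keep the study a few minutes on one core; the
# properties match the 500/200-replicate runs in the test suite.

suppressPackageStartupMessages(library(hapmark))

cfg <- sim_config(planted_prob = 0)
genome <- gen_genome(cfg)
nrep <- 300
res <- data.frame(variant = c("fixed_z", "resample_z", "resample_emp"),
                  type1 = NA_real_, stringsAsFactors = FALSE)
pf <- pr <- pe <- numeric(nrep)
for (r in seq_len(nrep)) {
  blocks <- gen_blocks(cfg, genome, seed = 600000 + 2 * r)
  gp <- gen_peaks(cfg, genome, blocks, planted_prob = 0,
                  seed = 600001 + 2 * r)
  fixed <- test_enrichment(blocks, gp$peaks, genome, iterations = 200,
                           seed = 610000 + r, null_lengths = "mean")
  resam <- test_enrichment(blocks, gp$peaks, genome, iterations = 200,
                           seed = 620000 + r, null_lengths = "resample")
  pf[r] <- fixed$p_z
  pr[r] <- resam$p_z
  pe[r] <- resam$p_emp
}
res$type1 <- c(mean(pf < 0.05), mean(pr < 0.05), mean(pe < 0.05))

cat("type-I error at alpha = 0.05 over", nrep, "null datasets:\n")
print(res, row.names = FALSE)
cat("(the fixed mean-length null is conservative here: the marked\n",
    "probability is concave in region length, so a null at the mean\n",
    "length overstates the background for a length set this dispersed;\n",
    "the rank-based p is additionally conservative at 16 tied regions)\n")

cfg9 <- sim_config(planted_prob = 0.9, lambda_per_mb = 0.1)
npow <- 150
hit <- logical(npow)
for (r in seq_len(npow)) {
  blocks <- gen_blocks(cfg9, genome, seed = 630000 + 2 * r)
  gp <- gen_peaks(cfg9, genome, blocks, planted_prob = 0.9,
                  seed = 630001 + 2 * r)
  resam <- test_enrichment(blocks, gp$peaks, genome, iterations = 200,
                           seed = 640000 + r, null_lengths = "resample")
  hit[r] <- resam$p_emp < 0.05
}
cat(sprintf("power at pi = 0.9 over sparse background: %.3f (%d replicates)\n",
            mean(hit), npow))

dir.create("results", showWarnings = FALSE)
utils::write.table(res, "results/calibration.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("table written to results/calibration.tsv\n")
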