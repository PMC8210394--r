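# Brute-force all-pairs oracles the fast engines are checked against.
# Overlap of [s1,e1) and [s2,e2): same chromosome, s1 < e2 and s2 < e1.

bf_pair_overlap <- function(q, s, i, j) {
  q$chrom[i] == s$chrom[j] && q$start[i] < s$end[j] && s$start[j] < q$end[i]
}

bf_intersect_counts <- function(queries, subjects) {
  vapply(seq_len(nrow(queries)), function(i) {
    if (nrow(subjects) == 0) return(0L)
    sum(vapply(seq_len(nrow(subjects)), function(j)
      bf_pair_overlap(queries, subjects, i, j), logical(1)))
  }, integer(1))
}

bf_count_marked <- function(regions, peaks) {
  sum(bf_intersect_counts(regions, peaks) > 0)
}

bf_assign_tads <- function(block, tads) {
  same <- tads$chrom == block$chrom
  contains <- which(same & tads$start <= block$start & block$end <= tads$end)
  overlaps <- which(same & tads$start < block$end & block$start < tads$end)
  if (length(contains)) list(idx = contains, partial = FALSE)
  else list(idx = overlaps, partial = length(overlaps) > 0)
}

# Random interval sets on a small toy genome.
rand_intervals <- function(n, chroms = c("chrA", "chrB"), max_pos = 10000,
                           max_len = 500) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1
  len <- sample.int(max_len, n, replace = TRUE)
  genomic_intervals(sample(chroms, n, replace = TRUE), start, start + len,
                    name = sprintf("iv%03d", seq_len(n)))
}
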