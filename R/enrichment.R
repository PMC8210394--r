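## Enrichment of a ChIP-seq peak set over query regions against an
## empirical null of matched-length random genomic regions.
##
## The observed statistic x is, by default, the number of query regions
## overlapped by >= 1 peak; the null repeats the measurement on random
## regions of matched length drawn uniformly from the genome, and the
## z-score (x - mu) / sigma is converted to a normal-tail p-value. A
## rank-based empirical p-value is reported alongside.

# Sorted per-chromosome peak index for O(log m) overlap counting in the
# null loop. For a region [s, e), the number of overlapping peaks is
# #{peak_start < e} - #{peak_end <= s} (valid for nested peaks too).
.peak_index <- function(peaks) {
  peaks <- .as_intervals(peaks)
  lapply(split(peaks[c("start", "end")], peaks$chrom), function(d) {
    list(starts = sort(d$start), ends = sort(d$end))
  })
}

# Per-region overlapping-peak counts against a .peak_index().
.indexed_counts <- function(chrom, start, end, idx) {
  out <- integer(length(chrom))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    px <- idx[[ch]]
    if (is.null(px)) next
    out[i] <- findInterval(end[i] - 0.5, px$starts) -
      findInterval(start[i], px$ends)
  }
  out
}

#' Sample matched-length random regions from a genome
#'
#' Draws `n` intervals of exactly `length` bp (or of the per-region lengths
#' in `lengths`), each fully inside a chromosome. Start positions are
#' uniform over all valid genome-wide placements: a chromosome is chosen
#' with probability proportional to `chrom_len - length + 1`, then the
#' start uniformly within it.
#'
#' @param genome Named numeric vector of chromosome lengths (see
#'   [read_chrom_sizes()]).
#' @param n Number of regions.
#' @param length Region length in bp (ignored when `lengths` is given).
#' @param seed Optional integer seed; the same seed reproduces the same
#'   regions exactly.
#' @param lengths Optional vector of `n` per-region lengths, for nulls that
#'   resample the actual query-region lengths instead of their mean.
#' @return A `genomic_intervals` table of `n` rows.
#' @export
sample_random_regions <- function(genome, n, length, seed = NULL,
                                  lengths = NULL) {
  stopifnot(n >= 1, !is.null(names(genome)), all(genome > 0))
  if (is.null(lengths)) lengths <- rep(length, n)
  stopifnot(length(lengths) == n, all(lengths >= 1))
  draw <- function() {
    chrom <- character(n)
    start <- numeric(n)
    for (len in unique(lengths)) {
      i <- which(lengths == len)
      valid <- genome >= len
      if (!any(valid)) {
        stop("region length ", len, " exceeds every chromosome")
      }
      w <- genome[valid] - len + 1
      ch <- sample(names(w), length(i), replace = TRUE, prob = w)
      chrom[i] <- ch
      start[i] <- floor(stats::runif(length(i)) * w[ch])
    }
    genomic_intervals(chrom, start, start + lengths)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Count query regions overlapped by at least one peak
#'
#' This is region-level counting: a region containing many peaks still
#' contributes 1. The result is bounded by the number of regions.
#'
#' @param regions A `genomic_intervals` table.
#' @param peaks A [peak_set()] or intervals table.
#' @return Integer count of marked regions.
#' @export
count_marked_regions <- function(regions, peaks) {
  regions <- .as_intervals(regions)
  idx <- .peak_index(peaks)
  sum(.indexed_counts(regions$chrom, regions$start, regions$end, idx) > 0)
}

# Prefix-stable per-iteration seeds: drawing more iterations extends the
# seed sequence without reshuffling earlier draws.
.iteration_seeds <- function(seed, iterations) {
  if (is.null(seed)) return(rep(list(NULL), iterations))
  as.list(withr::with_seed(seed, sample.int(2147483646L, iterations)))
}

#' Build the empirical null distribution of marked-region counts
#'
#' Repeats `iterations` times: draw `region_count` random regions of
#' `region_length` bp (or resampled `lengths`) and count how many of them
#' overlap at least one peak (or, with `stat = "pairs"`, the total number
#' of overlapping region-peak pairs). The mean `mu` and population standard deviation
#' `sigma` of the counts parameterise the z-score.
#'
#' @inheritParams sample_random_regions
#' @param peaks A [peak_set()] or intervals table.
#' @param region_count Regions per iteration (matched to the query set).
#' @param region_length Length of each random region, conventionally the
#'   rounded mean query-region length.
#' @param iterations Number of null draws (>= 2; 1000 by default).
#' @param stat `"regions"` (marked-region counts) or `"pairs"`
#'   (overlapping-pair counts).
#' @return A `null_distribution` object with fields `counts`, `iterations`,
#'   `mu`, `sigma`, `region_count`, `region_length`, `lengths`, `seed`,
#'   `stat`.
#' @export
build_null <- function(genome, peaks, region_count, region_length,
                       iterations = 1000, seed = NULL, lengths = NULL,
                       stat = c("regions", "pairs")) {
  stat <- match.arg(stat)
  stopifnot(iterations >= 2, region_count >= 1)
  idx <- .peak_index(peaks)
  seeds <- .iteration_seeds(seed, iterations)
  one <- function(s) {
    r <- sample_random_regions(genome, region_count, region_length,
                               seed = s, lengths = lengths)
    cts <- .indexed_counts(r$chrom, r$start, r$end, idx)
    if (stat == "regions") sum(cts > 0) else sum(cts)
  }
  counts <- vapply(seeds, one, numeric(1))
  mu <- mean(counts)
  structure(list(counts = counts, iterations = iterations, mu = mu,
                 sigma = sqrt(mean((counts - mu)^2)),
                 region_count = region_count, region_length = region_length,
                 lengths = lengths, seed = seed, stat = stat),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> %d iterations of %d regions (%s bp): mu = %.3f, sigma = %.3f\n",
              x$iterations, x$region_count,
              if (is.null(x$lengths)) format(x$region_length) else "resampled lengths",
              x$mu, x$sigma))
  invisible(x)
}

#' Z-score of an observed count against a null distribution
#'
#' `z = (x - mu) / sigma`. A degenerate null (`sigma == 0`) yields `+Inf`
#' when `x > mu`, `0` at `x == mu`, `-Inf` below; callers should inspect
#' the degenerate flag on [test_enrichment()] results rather than trust a
#' normal-tail p-value in that case.
#'
#' @param x Observed count.
#' @param null A `null_distribution`.
#' @return Numeric z-score (possibly infinite).
#' @export
z_score <- function(x, null) {
  stopifnot(inherits(null, "null_distribution"))
  if (null$sigma > 0) return((x - null$mu) / null$sigma)
  if (x > null$mu) Inf else if (x < null$mu) -Inf else 0
}

#' Normal-tail p-value from a z-score
#'
#' @param z Z-score (finite or infinite).
#' @param alternative `"greater"` (one-sided upper tail, the enrichment
#'   direction; default) or `"two_sided"`.
#' @return Probability in `[0, 1]`.
#' @export
p_from_z <- function(z, alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  if (alternative == "greater") {
    stats::pnorm(z, lower.tail = FALSE)
  } else {
    2 * stats::pnorm(abs(z), lower.tail = FALSE)
  }
}

#' Rank-based empirical p-value
#'
#' `(1 + #\{null counts >= x\}) / (1 + iterations)`; the add-one keeps the
#' p-value in `[1/(iterations+1), 1]` and valid under exchangeability.
#'
#' @inheritParams z_score
#' @return Probability.
#' @export
empirical_p <- function(x, null) {
  stopifnot(inherits(null, "null_distribution"))
  (1 + sum(null$counts >= x)) / (1 + null$iterations)
}

#' Test a peak set for enrichment over query LD blocks
#'
#' Computes the observed statistic on the blocks, builds the
#' matched-length random-region null, and reports the z-score p-value and
#' the rank-based empirical p-value, together with per-block peak counts
#' (for the presence/absence matrix).
#'
#' @param blocks LD blocks ([ia_ld_blocks()] or any intervals table).
#' @param peaks A [peak_set()].
#' @param genome Named chromosome-length vector the null samples from.
#' @param iterations Null iterations (default 1000).
#' @param seed Integer seed fixing the whole computation.
#' @param alternative Passed to [p_from_z()].
#' @param stat `"regions"`: x = number of blocks with >= 1 peak (default);
#'   `"pairs"`: x = number of overlapping block-peak pairs.
#' @param null_lengths `"mean"`: every random region has the rounded mean
#'   block length (default); `"resample"`: each null draw reuses the
#'   actual block lengths.
#' @return An `enrichment_result` with fields `cell_type`, `mark`, `x`,
#'   `z`, `p_z`, `p_emp`, `degenerate`, `per_block_counts`, `bins`, `null`
#'   and `config`.
#' @export
test_enrichment <- function(blocks, peaks, genome, iterations = 1000,
                            seed = NULL,
                            alternative = c("greater", "two_sided"),
                            stat = c("regions", "pairs"),
                            null_lengths = c("mean", "resample")) {
  alternative <- match.arg(alternative)
  stat <- match.arg(stat)
  null_lengths <- match.arg(null_lengths)
  stopifnot(inherits(peaks, "peak_set"))
  blocks <- .as_intervals(blocks)
  stopifnot(nrow(blocks) >= 1)

  lens <- interval_length(blocks)
  region_length <- round(mean(lens))
  per_block <- intersect_counts(blocks, peaks$peaks)
  x <- if (stat == "regions") sum(per_block > 0) else sum(per_block)

  null <- build_null(genome, peaks,
                     region_count = nrow(blocks),
                     region_length = region_length,
                     iterations = iterations, seed = seed,
                     lengths = if (null_lengths == "resample") lens else NULL,
                     stat = stat)
  z <- z_score(x, null)
  structure(list(
    cell_type = peaks$cell_type, mark = peaks$mark,
    x = x, mu = null$mu, sigma = null$sigma, z = z,
    p_z = p_from_z(z, alternative),
    p_emp = empirical_p(x, null),
    degenerate = null$sigma == 0,
    per_block_counts = stats::setNames(
      per_block,
      if (all(is.na(blocks$name))) NULL else blocks$name),
    bins = enrichment_bin(per_block),
    null = null,
    config = list(iterations = iterations, seed = seed,
                  alternative = alternative, stat = stat,
                  null_lengths = null_lengths,
                  region_length = region_length)),
    class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> %s %s\n", x$cell_type, x$mark))
  cat(sprintf("  x = %g of %d regions (stat = %s), null mu = %.3f, sigma = %.3f\n",
              x$x, x$null$region_count, x$config$stat, x$mu, x$sigma))
  if (x$degenerate) {
    cat("  degenerate null (sigma = 0); z and p_z are limits, prefer p_emp\n")
  }
  cat(sprintf("  z = %.3f, p_z = %.4g (%s), p_emp = %.4g [%d iterations]\n",
              x$z, x$p_z, x$config$alternative, x$p_emp, x$null$iterations))
  invisible(x)
}

#' Closed-chromatin (repressive mark) presence check
#'
#' Reports, per block, whether any peak of a repressive mark (H3K9me3)
#' overlaps it, with a summary count. Enrichment is not scored: the
#' question is bare presence of closed chromatin on the haplotypes.
#'
#' @param blocks LD blocks.
#' @param peaks A [peak_set()], conventionally carrying a repressive mark.
#' @return List with `per_block` (named logical), `n_marked`, `n_blocks`,
#'   `cell_type`, `mark`.
#' @export
negative_mark_check <- function(blocks, peaks) {
  stopifnot(inherits(peaks, "peak_set"))
  if (!peaks$mark %in% REPRESSIVE_MARKS) {
    warning("negative_mark_check on '", peaks$mark,
            "', which is not a repressive mark")
  }
  blocks <- .as_intervals(blocks)
  if (nrow(peaks$peaks) == 0) {
    warning("empty peak set in negative_mark_check; reporting 0/",
            nrow(blocks))
  }
  hit <- intersect_counts(blocks, peaks$peaks) > 0
  names(hit) <- blocks$name
  list(per_block = hit, n_marked = sum(hit), n_blocks = nrow(blocks),
       cell_type = peaks$cell_type, mark = peaks$mark)
}

#' Bin per-block peak counts into presence categories
#'
#' Categories follow the reporting convention for the block-by-dataset
#' matrix: `none` (0 peaks), `low` (1-5), `mid` (6-10), `high` (>= 11).
#'
#' @param count Non-negative integer vector of per-block peak counts.
#' @return Factor with levels none/low/mid/high.
#' @export
enrichment_bin <- function(count) {
  stopifnot(is.numeric(count))
  if (any(is.na(count)) || any(count < 0)) {
    stop("peak counts must be non-negative")
  }
  cut(count, breaks = c(-0.5, 0.5, 5.5, 10.5, Inf),
      labels = c("none", "low", "mid", "high"))
}
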