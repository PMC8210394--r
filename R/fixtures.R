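#' The 16 intracranial-aneurysm risk LD blocks (hg38)
#'
#' The linkage-disequilibrium blocks surrounding 16 sentinel SNPs reported
#' as significantly associated with intracranial aneurysm in multiple
#' studies, with the sentinel rsID, its location class relative to gene
#' models, and the nearest gene. Coordinates are hg38, 0-based half-open;
#' `interval_length()` on these rows reproduces the published block
#' lengths (mean ~30.6 kb).
#'
#' @return A `genomic_intervals` table with extra columns `snp_id`,
#'   `snp_location` (one of intronic/exonic/intergenic) and `nearest_gene`
#'   (NA where the SNP is intergenic with no assigned gene).
#' @examples
#' blocks <- ia_ld_blocks()
#' summary(interval_length(blocks))
#' @export
ia_ld_blocks <- function() {
  path <- system.file("extdata", "ia_ld_blocks_hg38.tsv", package = "hapmark",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "character",
                                          "character", "numeric", "numeric"))
  out <- genomic_intervals(tab$chrom, tab$start, tab$end, name = tab$snp_id)
  out$snp_id <- tab$snp_id
  out$snp_location <- tab$snp_location
  out$nearest_gene <- tab$nearest_gene
  class(out) <- c("ld_blocks", class(out))
  out
}

#' Published differential-expression records for IA tissue
#'
#' Differentially expressed genes reported by eight tissue studies
#' (aneurysm vs control tissue, and ruptured vs unruptured aneurysms) that
#' fall within TADs encompassing the risk LD blocks. `log2fc` is NA where
#' the source study reported no fold-change.
#'
#' @return A `deg_table` data frame (see [read_deg_table()] for columns).
#' @export
ia_deg_records <- function() {
  path <- system.file("extdata", "ia_deg_records.tsv", package = "hapmark",
                      mustWork = TRUE)
  read_deg_table(path)
}

#' Validate LD-block metadata
#'
#' Checks the [genomic_intervals()] invariants plus, when a `snp_pos`
#' column is present, that each sentinel SNP lies within its block.
#'
#' @param blocks A data frame of LD blocks.
#' @return `blocks` with class `ld_blocks`, or an error.
#' @export
ld_blocks <- function(blocks) {
  out <- .as_intervals(blocks)
  for (col in intersect(c("snp_id", "snp_location", "nearest_gene", "snp_pos"),
                        names(blocks))) {
    out[[col]] <- blocks[[col]]
  }
  if ("snp_location" %in% names(out)) {
    ok <- out$snp_location %in% c("intronic", "exonic", "intergenic") |
      is.na(out$snp_location)
    if (!all(ok)) stop("snp_location must be intronic, exonic or intergenic")
  }
  if ("snp_pos" %in% names(out)) {
    has <- !is.na(out$snp_pos)
    if (any(has & (out$snp_pos < out$start | out$snp_pos >= out$end))) {
      stop("sentinel SNP position outside its LD block")
    }
  }
  if (!inherits(out, "ld_blocks")) class(out) <- c("ld_blocks", class(out))
  out
}
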