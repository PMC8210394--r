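## Mapping histone-marked LD blocks to the topologically associated
## domains (TADs) that encompass them, and enumerating the genes within
## those domains. TADs arrive as pre-called BED intervals (e.g. published
## HiC domain lists); strand is ignored throughout.

#' Read gene models from BED or minimal GTF
#'
#' BED input uses column 4 as the gene symbol. GTF input is parsed with
#' rtracklayer; only `gene` feature lines are kept (all lines when the file
#' has no `gene` features) and the symbol is taken from `gene_name`,
#' falling back to `gene_id`. Coordinates are converted to the package's
#' 0-based half-open convention.
#'
#' @param path Gene annotation file (`.bed`, or `.gtf`/`.gff`).
#' @param format `"auto"` (by extension), `"bed"` or `"gtf"`.
#' @return A `genomic_intervals` table with a `symbol` column,
#'   deduplicated on (symbol, interval).
#' @export
read_genes <- function(path, format = c("auto", "bed", "gtf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gtf|gff3?)$", path, ignore.case = TRUE))
      "gtf" else "bed"
  }
  if (format == "bed") {
    iv <- read_bed(path)
    if (any(is.na(iv$name))) stop(path, ": BED gene models need a name column")
    iv$symbol <- iv$name
  } else {
    gr <- rtracklayer::import(path)
    if ("type" %in% names(S4Vectors::mcols(gr)) &&
        any(gr$type == "gene")) {
      gr <- gr[gr$type == "gene"]
    }
    sym <- if ("gene_name" %in% names(S4Vectors::mcols(gr))) gr$gene_name
           else gr$gene_id
    if (is.null(sym)) stop(path, ": no gene_name/gene_id attribute")
    iv <- genomic_intervals(as.character(GenomicRanges::seqnames(gr)),
                            GenomicRanges::start(gr) - 1,
                            GenomicRanges::end(gr), name = sym)
    iv$symbol <- sym
  }
  if (any(is.na(iv$symbol)) || any(!nzchar(iv$symbol))) {
    stop(path, ": empty gene symbol")
  }
  iv <- iv[!duplicated(iv[c("symbol", "chrom", "start", "end")]), ,
           drop = FALSE]
  rownames(iv) <- NULL
  iv
}

#' Assign the TAD(s) encompassing an LD block
#'
#' Default rule `encompass`: TADs fully containing the block. When no TAD
#' contains it (the block spans a domain boundary), all TADs overlapping
#' it by >= 1 bp are returned instead and the assignment is flagged
#' partial. Nested or overlapping domain calls are tolerated: every
#' containing TAD is returned.
#'
#' @param block A single-row intervals table (one LD block).
#' @param tads Intervals table of domain calls from one cell type.
#' @param rule `"encompass"` (with overlap fallback) or `"overlap"`.
#' @return `tad_assignment` list: `block`, `tads` (possibly empty),
#'   `partial` flag, `genes` (filled by [build_tad_assignments()]).
#' @export
assign_tads <- function(block, tads, rule = c("encompass", "overlap")) {
  rule <- match.arg(rule)
  block <- .as_intervals(block)
  stopifnot(nrow(block) == 1)
  tads <- .as_intervals(tads)
  same <- tads$chrom == block$chrom
  contains <- same & tads$start <= block$start & block$end <= tads$end
  overlaps <- same & tads$start < block$end & block$start < tads$end
  partial <- FALSE
  hit <- if (rule == "encompass" && any(contains)) {
    contains
  } else {
    partial <- rule == "encompass"
    overlaps
  }
  if (!any(overlaps)) {
    if (nrow(tads) == 0) warning("empty TAD set; block ", block$name,
                                 " unassigned")
    hit <- rep(FALSE, nrow(tads))
    partial <- FALSE
  }
  structure(list(block = block, tads = tads[hit, , drop = FALSE],
                 partial = partial, genes = character(0)),
            class = "tad_assignment")
}

#' Genes within a set of TADs
#'
#' @param tads Intervals table of domains.
#' @param genes Gene models from [read_genes()].
#' @param rule `"overlap"` (>= 1 bp overlap with any TAD; default, the
#'   most inclusive reading of "encompassed"), `"contained"` (gene fully
#'   inside a TAD) or `"tss_within"` (gene start inside a TAD; strand is
#'   ignored, so the 5' end is taken as the lower coordinate).
#' @return Sorted, deduplicated character vector of gene symbols.
#' @export
genes_in_tads <- function(tads, genes, rule = c("overlap", "contained",
                                                "tss_within")) {
  rule <- match.arg(rule)
  tads <- .as_intervals(tads)
  stopifnot("symbol" %in% names(genes))
  if (nrow(tads) == 0 || nrow(genes) == 0) return(character(0))
  hit <- switch(rule,
    overlap = intersect_counts(genes, tads) > 0,
    contained = vapply(seq_len(nrow(genes)), function(i) {
      any(tads$chrom == genes$chrom[i] & tads$start <= genes$start[i] &
            genes$end[i] <= tads$end)
    }, logical(1)),
    tss_within = vapply(seq_len(nrow(genes)), function(i) {
      any(tads$chrom == genes$chrom[i] & tads$start <= genes$start[i] &
            genes$start[i] < tads$end)
    }, logical(1)))
  sort(unique(genes$symbol[hit]))
}

#' Build TAD assignments with gene rosters for a set of blocks
#'
#' @param blocks LD blocks table.
#' @param tads Domain calls for one cell type.
#' @param genes Gene models.
#' @param tad_rule Passed to [assign_tads()].
#' @param gene_rule Passed to [genes_in_tads()].
#' @return List of `tad_assignment` objects, one per block, each with its
#'   deduplicated sorted gene roster.
#' @export
build_tad_assignments <- function(blocks, tads, genes,
                                  tad_rule = "encompass",
                                  gene_rule = "overlap") {
  blocks <- .as_intervals(blocks)
  lapply(seq_len(nrow(blocks)), function(i) {
    a <- assign_tads(blocks[i, , drop = FALSE], tads, rule = tad_rule)
    a$genes <- genes_in_tads(a$tads, genes, rule = gene_rule)
    a
  })
}

# Union gene roster over assignments (or pass a character vector through).
.assignment_genes <- function(x) {
  if (is.character(x)) return(sort(unique(x)))
  if (inherits(x, "tad_assignment")) return(sort(unique(x$genes)))
  sort(unique(unlist(lapply(x, function(a) a$genes), use.names = FALSE)))
}

#' Genes shared between two cell types' TAD assignments
#'
#' @param assignments_a,assignments_b Assignment lists from
#'   [build_tad_assignments()] (or plain symbol vectors).
#' @return Sorted character vector of symbols present in both.
#' @export
shared_genes <- function(assignments_a, assignments_b) {
  intersect(.assignment_genes(assignments_a), .assignment_genes(assignments_b))
}
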