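#' Bundle ChIP-seq peaks with their cell type and histone mark
#'
#' Peaks are stored sorted by chromosome and start. Zero-length peaks are
#' rejected (the interval constructor enforces `start < end`).
#'
#' @param cell_type Cell type label, e.g. `"HUVEC"`.
#' @param mark Histone mark, e.g. `"H3K27ac"`, `"H3K4me1"`, `"H3K9ac"`,
#'   `"H3K9me3"`.
#' @param peaks A `genomic_intervals` table of called peaks.
#' @param source Free-text provenance (e.g. a GEO accession).
#' @return A `peak_set` object.
#' @export
peak_set <- function(cell_type, mark, peaks, source = NA_character_) {
  stopifnot(is.character(cell_type), length(cell_type) == 1, nzchar(cell_type),
            is.character(mark), length(mark) == 1, nzchar(mark))
  peaks <- .as_intervals(peaks)
  peaks <- peaks[order(peaks$chrom, peaks$start, peaks$end), , drop = FALSE]
  rownames(peaks) <- NULL
  structure(list(cell_type = cell_type, mark = mark, peaks = peaks,
                 source = source),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %s %s: %d peaks on %d chromosome(s)%s\n",
              x$cell_type, x$mark, nrow(x$peaks),
              length(unique(x$peaks$chrom)),
              if (is.na(x$source)) "" else paste0(" [", x$source, "]")))
  invisible(x)
}

#' Read a peak BED file into a peak_set
#'
#' @inheritParams peak_set
#' @param path BED file of peaks.
#' @param min_score Optional minimum score; when supplied, the 5th BED
#'   column is parsed and peaks scoring below the threshold are dropped.
#'   Default applies no filter (peak files are consumed as published).
#' @return A `peak_set`.
#' @export
read_peaks <- function(path, cell_type, mark, source = NA_character_,
                       min_score = NULL) {
  iv <- read_bed(path)
  if (!is.null(min_score)) {
    lines <- sub("\r$", "", readLines(path, warn = FALSE))
    lines <- lines[!(grepl("^\\s*$", lines) | grepl("^(track|browser|#)", lines))]
    f5 <- vapply(strsplit(lines, "\t", fixed = TRUE),
                 function(f) if (length(f) >= 5) f[5] else NA_character_, "")
    score <- suppressWarnings(as.numeric(f5))
    keep <- !is.na(score) & score >= min_score
    iv <- iv[keep, , drop = FALSE]
  }
  peak_set(cell_type, mark, iv, source = source)
}

# Marks read as enhancer-associated (activating) chromatin versus closed
# chromatin; used by the pipeline's gating and the repressive-mark check.
ACTIVATING_MARKS <- c("H3K4me1", "H3K27ac", "H3K9ac")
REPRESSIVE_MARKS <- c("H3K9me3")
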