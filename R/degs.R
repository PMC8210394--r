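## Cross-referencing TAD gene rosters with published differential
## expression tables. Symbol matching is exact after uppercasing and
## whitespace stripping; no alias/HGNC resolution is attempted.

.norm_symbol <- function(x) toupper(gsub("\\s+", "", x))

#' Read a differential-expression table
#'
#' Expects a TSV with header columns `symbol`, `study`, `comparison`,
#' `direction` and optionally `log2fc`. `comparison` must be
#' `IA_vs_control` or `ruptured_vs_unruptured`; `direction` must be `up`
#' or `down` and, when a fold-change is given, agree with its sign.
#' `"NR"`, `"NA"` or empty fold-changes become `NA` (study reported no
#' value).
#'
#' @param path TSV path.
#' @return A `deg_table` data frame with the columns above.
#' @export
read_deg_table <- function(path) {
  if (!file.exists(path)) stop("DEG table not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("symbol", "study", "comparison", "direction")
  if (!all(need %in% names(tab))) {
    stop(path, ": header must contain ", paste(need, collapse = ", "))
  }
  if (!"log2fc" %in% names(tab)) tab$log2fc <- NA_character_
  tab$log2fc[tab$log2fc %in% c("", "NR", "NA", "nr")] <- NA_character_
  lfc <- suppressWarnings(as.numeric(tab$log2fc))
  bad <- which(!is.na(tab$log2fc) & is.na(lfc))
  if (length(bad)) stop(path, " row ", bad[1L], ": non-numeric log2fc '",
                        tab$log2fc[bad[1L]], "'")
  ok_cmp <- tab$comparison %in% c("IA_vs_control", "ruptured_vs_unruptured")
  if (!all(ok_cmp)) {
    stop(path, " row ", which(!ok_cmp)[1L], ": unknown comparison '",
         tab$comparison[!ok_cmp][1L], "'")
  }
  ok_dir <- tab$direction %in% c("up", "down")
  if (!all(ok_dir)) {
    stop(path, " row ", which(!ok_dir)[1L], ": direction must be up/down")
  }
  conflict <- which(!is.na(lfc) &
                      ((tab$direction == "up" & lfc < 0) |
                         (tab$direction == "down" & lfc > 0)))
  if (length(conflict)) {
    stop(path, " row ", conflict[1L], ": direction '",
         tab$direction[conflict[1L]], "' conflicts with log2fc ",
         lfc[conflict[1L]], " for ", tab$symbol[conflict[1L]])
  }
  out <- data.frame(symbol = tab$symbol, study = tab$study,
                    comparison = tab$comparison, direction = tab$direction,
                    log2fc = lfc, stringsAsFactors = FALSE)
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Overlap TAD gene rosters with differential-expression records
#'
#' A block's TAD "contains a DEG" when any gene in its roster matches any
#' DEG record passing the comparison filter, regardless of direction
#' (binary counting, as in x/y-TADs-with-a-DEG summaries). Duplicate DEG
#' rows for the same (symbol, study, comparison) collapse to one output
#' row; a gene reported by >= 2 studies is flagged multi-study.
#'
#' @param assignments List of `tad_assignment` objects
#'   ([build_tad_assignments()]).
#' @param degs A `deg_table`.
#' @param comparison Optional filter, one of the comparison labels; `NULL`
#'   keeps all records.
#' @return An `overlap_summary` list: `per_tad` data frame (block, has_deg,
#'   hit_genes), `per_gene` long data frame (symbol, study, comparison,
#'   direction, log2fc, blocks, multi_study), `n_marked_tads`,
#'   `n_tads_with_deg`, `fraction`.
#' @export
overlap_degs <- function(assignments, degs, comparison = NULL) {
  stopifnot(inherits(degs, "deg_table") || is.data.frame(degs))
  if (!is.null(comparison)) {
    stopifnot(comparison %in% c("IA_vs_control", "ruptured_vs_unruptured"))
    degs <- degs[degs$comparison == comparison, , drop = FALSE]
  }
  degs <- degs[!duplicated(degs[c("symbol", "study", "comparison",
                                  "direction")]), , drop = FALSE]
  deg_sym <- .norm_symbol(degs$symbol)

  per_tad <- do.call(rbind, lapply(assignments, function(a) {
    hits <- a$genes[.norm_symbol(a$genes) %in% deg_sym]
    data.frame(block = a$block$name,
               n_genes = length(a$genes),
               has_deg = length(hits) > 0,
               hit_genes = paste(hits, collapse = ","),
               partial = a$partial,
               stringsAsFactors = FALSE)
  }))
  roster <- .assignment_genes(assignments)
  roster_norm <- .norm_symbol(roster)
  keep <- deg_sym %in% roster_norm
  per_gene <- degs[keep, , drop = FALSE]
  if (nrow(per_gene)) {
    per_gene$blocks <- vapply(.norm_symbol(per_gene$symbol), function(s) {
      inb <- vapply(assignments,
                    function(a) s %in% .norm_symbol(a$genes), logical(1))
      paste(per_tad$block[inb], collapse = ",")
    }, "")
    nstud <- tapply(per_gene$study, .norm_symbol(per_gene$symbol),
                    function(s) length(unique(s)))
    per_gene$multi_study <-
      as.logical(unname(nstud[.norm_symbol(per_gene$symbol)] >= 2))
    per_gene$blocks <- unname(per_gene$blocks)
    per_gene <- per_gene[order(per_gene$symbol, per_gene$comparison,
                               per_gene$study), , drop = FALSE]
  } else {
    per_gene$blocks <- character(0)
    per_gene$multi_study <- logical(0)
  }
  rownames(per_gene) <- NULL
  n_marked <- nrow(per_tad)
  n_with <- sum(per_tad$has_deg)
  structure(list(per_tad = per_tad, per_gene = per_gene,
                 n_marked_tads = n_marked, n_tads_with_deg = n_with,
                 fraction = if (n_marked > 0) n_with / n_marked else NaN),
            class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf("<overlap_summary> %d/%d TAD-bearing blocks contain a DEG (%.0f%%); %d per-gene rows\n",
              x$n_tads_with_deg, x$n_marked_tads, 100 * x$fraction,
              nrow(x$per_gene)))
  invisible(x)
}

#' Percentage of TAD transcripts with reported differential expression
#'
#' The headline refinement figure: of all genes in the risk-haplotype
#' TADs, what share also appears in the DEG tables. Reported with its
#' numerator and denominator; `pct` rounds to the nearest percent.
#'
#' @param assignments Assignment list (or plain symbol vector) for one
#'   cell type.
#' @param degs A `deg_table`.
#' @return List `n_deg`, `n_transcripts`, `pct_exact`, `pct` (`NA` when
#'   the roster is empty).
#' @export
deg_fraction_of_transcripts <- function(assignments, degs) {
  roster <- .assignment_genes(assignments)
  n_deg <- length(intersect(.norm_symbol(roster),
                            unique(.norm_symbol(degs$symbol))))
  transcript_deg_percentage(n_deg, length(roster))
}

#' Percentage from DEG / transcript counts
#'
#' @param n_deg Number of TAD transcripts with reported differential
#'   expression.
#' @param n_transcripts Total transcripts in the TADs.
#' @return List `n_deg`, `n_transcripts`, `pct_exact` (`100 * n/d`), `pct`
#'   (rounded to nearest percent); percentages are `NA` for an empty
#'   roster.
#' @export
transcript_deg_percentage <- function(n_deg, n_transcripts) {
  stopifnot(n_deg >= 0, n_transcripts >= 0, n_deg <= max(n_transcripts, 0))
  if (n_transcripts == 0) {
    return(list(n_deg = 0, n_transcripts = 0, pct_exact = NA_real_,
                pct = NA_real_))
  }
  pct <- 100 * n_deg / n_transcripts
  list(n_deg = n_deg, n_transcripts = n_transcripts,
       pct_exact = pct, pct = round(pct))
}
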