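## One reproducible run: blocks -> per-(cell type, mark) enrichment ->
## gating -> TAD assignment -> gene rosters -> DEG overlap, with
## provenance. TAD and DEG stages run only for cell types with at least
## one significant activating mark; for gated cell types with significant
## H3K27ac, the repressive H3K9me3 mark is additionally checked when a
## peak file is available.

#' Assemble a pipeline run configuration
#'
#' @param blocks Path to the LD-block BED (block names in column 4).
#' @param chrom_sizes Path to the chrom.sizes table.
#' @param peak_manifest Data frame with columns `cell_type`, `mark`,
#'   `path`; one row per peak BED file.
#' @param tads Named list, cell type -> TAD BED path.
#' @param genes Path to gene models (BED4 or minimal GTF).
#' @param degs Path to the DEG TSV.
#' @param iterations,seed,alternative,stat,null_lengths Passed to
#'   [test_enrichment()]; each peak set gets its own seed derived from
#'   `seed`.
#' @param alpha Significance threshold on `p_z` (default 0.05).
#' @param tad_rule,gene_rule Passed to [build_tad_assignments()].
#' @param gating `"any"`: a cell type is gated in when any available
#'   activating mark is significant (a cell type with a single available
#'   mark can qualify on it alone); `"all"`: all its available activating
#'   marks must be significant.
#' @param out_dir Optional directory for `report.json`, `matrix.tsv` and
#'   per-cell-type gene lists.
#' @return A `run_config` list.
#' @export
run_config <- function(blocks, chrom_sizes, peak_manifest, tads = list(),
                       genes = NULL, degs = NULL,
                       iterations = 1000, seed = 1, alpha = 0.05,
                       alternative = "greater", stat = "regions",
                       null_lengths = "mean",
                       tad_rule = "encompass", gene_rule = "overlap",
                       gating = c("any", "all"), out_dir = NULL) {
  gating <- match.arg(gating)
  stopifnot(is.data.frame(peak_manifest),
            all(c("cell_type", "mark", "path") %in% names(peak_manifest)),
            alpha > 0, alpha < 1, iterations >= 2)
  structure(list(blocks = blocks, chrom_sizes = chrom_sizes,
                 peak_manifest = peak_manifest, tads = tads, genes = genes,
                 degs = degs, iterations = iterations, seed = seed,
                 alpha = alpha, alternative = alternative, stat = stat,
                 null_lengths = null_lengths, tad_rule = tad_rule,
                 gene_rule = gene_rule, gating = gating,
                 out_dir = out_dir),
            class = "run_config")
}

#' Configure a run directly from a simulated dataset directory
#'
#' @param dir A directory written by [simulate_dataset()].
#' @param ... Overrides passed to [run_config()].
#' @return A `run_config`.
#' @export
run_config_from_dir <- function(dir, ...) {
  peak_files <- list.files(dir, pattern = "^peaks_.*\\.bed$")
  parts <- regmatches(peak_files,
                      regexec("^peaks_(.+)_([^_]+)\\.bed$", peak_files))
  manifest <- data.frame(
    cell_type = vapply(parts, `[`, "", 2L),
    mark = vapply(parts, `[`, "", 3L),
    path = file.path(dir, peak_files), stringsAsFactors = FALSE)
  tad_files <- list.files(dir, pattern = "^tads_.*\\.bed$")
  tads <- stats::setNames(as.list(file.path(dir, tad_files)),
                          sub("^tads_(.+)\\.bed$", "\\1", tad_files))
  run_config(blocks = file.path(dir, "blocks.bed"),
             chrom_sizes = file.path(dir, "chrom.sizes"),
             peak_manifest = manifest, tads = tads,
             genes = file.path(dir, "genes.bed"),
             degs = file.path(dir, "degs.tsv"), ...)
}

#' Execute the full pipeline
#'
#' Fails fast if any configured input file is missing. A peak file that
#' fails to parse is skipped with a warning and recorded as absent.
#'
#' @param config A [run_config()].
#' @return A `run_report` list: `enrichment` (per peak set), `gated`
#'   (cell types passing the gate), `assignments`, `gene_rosters`,
#'   `overlap` and `deg_fraction` per gated cell type, `shared_genes`
#'   across gated cell types, `negative_checks`, `skipped`, `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  inputs <- c(config$blocks, config$chrom_sizes, config$peak_manifest$path,
              unlist(config$tads), config$genes, config$degs)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing)) {
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  }

  blocks <- read_bed(config$blocks)
  genome <- read_chrom_sizes(config$chrom_sizes)
  man <- config$peak_manifest
  set_seeds <- withr::with_seed(config$seed,
                                sample.int(2147483646L, nrow(man)))

  enrichment <- list()
  repressive <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(man))) {
    key <- paste(man$cell_type[i], man$mark[i], sep = "_")
    ps <- tryCatch(read_peaks(man$path[i], man$cell_type[i], man$mark[i],
                              source = man$path[i]),
                   error = function(e) {
                     warning("skipping unparseable peak file ", man$path[i],
                             ": ", conditionMessage(e))
                     NULL
                   })
    if (is.null(ps)) {
      skipped <- c(skipped, key)
      next
    }
    if (man$mark[i] %in% REPRESSIVE_MARKS) {
      repressive[[key]] <- ps
    } else {
      enrichment[[key]] <-
        test_enrichment(blocks, ps, genome,
                        iterations = config$iterations,
                        seed = set_seeds[i],
                        alternative = config$alternative,
                        stat = config$stat,
                        null_lengths = config$null_lengths)
    }
  }

  sig <- vapply(enrichment, function(r) r$p_z < config$alpha, logical(1))
  by_cell <- split(sig, vapply(enrichment, `[[`, "", "cell_type"))
  gated <- names(by_cell)[vapply(by_cell, if (config$gating == "any") any
                                 else all, logical(1))]

  assignments <- list()
  gene_rosters <- list()
  overlap <- list()
  deg_fraction <- list()
  negative_checks <- list()
  genes <- if (!is.null(config$genes)) read_genes(config$genes) else NULL
  degs <- if (!is.null(config$degs)) read_deg_table(config$degs) else NULL
  for (ct in gated) {
    # the TAD stage follows the gate; only marked blocks carry forward
    marked <- Reduce(`|`, lapply(
      enrichment[vapply(enrichment, `[[`, "", "cell_type") == ct],
      function(r) r$per_block_counts > 0))
    if (is.null(config$tads[[ct]]) || is.null(genes)) next
    tads <- read_bed(config$tads[[ct]])
    assignments[[ct]] <- build_tad_assignments(
      blocks[marked, , drop = FALSE], tads, genes,
      tad_rule = config$tad_rule, gene_rule = config$gene_rule)
    gene_rosters[[ct]] <- .assignment_genes(assignments[[ct]])
    if (!is.null(degs)) {
      overlap[[ct]] <- overlap_degs(assignments[[ct]], degs)
      deg_fraction[[ct]] <- deg_fraction_of_transcripts(assignments[[ct]],
                                                        degs)
    }
    k27 <- enrichment[[paste(ct, "H3K27ac", sep = "_")]]
    k9me3 <- repressive[[paste(ct, "H3K9me3", sep = "_")]]
    if (!is.null(k27) && k27$p_z < config$alpha && !is.null(k9me3)) {
      negative_checks[[ct]] <- negative_mark_check(blocks, k9me3)
    }
  }
  shared <- if (length(gene_rosters) >= 2) {
    Reduce(intersect, gene_rosters)
  } else character(0)

  report <- structure(list(
    enrichment = enrichment, gated = gated, assignments = assignments,
    gene_rosters = gene_rosters, overlap = overlap,
    deg_fraction = deg_fraction, shared_genes = shared,
    negative_checks = negative_checks, skipped = skipped,
    blocks = blocks,
    provenance = list(
      seed = config$seed, alpha = config$alpha,
      iterations = config$iterations, gating = config$gating,
      stat = config$stat, alternative = config$alternative,
      null_lengths = config$null_lengths, tad_rule = config$tad_rule,
      gene_rule = config$gene_rule,
      package_version = as.character(utils::packageVersion("hapmark")),
      input_md5 = as.list(stats::setNames(unname(tools::md5sum(inputs)),
                                          basename(inputs))))),
    class = "run_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d peak sets tested, gated cell types: %s\n",
              length(x$enrichment),
              if (length(x$gated)) paste(x$gated, collapse = ", ")
              else "(none)"))
  for (key in names(x$enrichment)) {
    r <- x$enrichment[[key]]
    cat(sprintf("  %-24s x = %2g  z = %6.2f  p_z = %.4g%s\n", key, r$x,
                r$z, r$p_z,
                if (r$p_z < x$provenance$alpha) " †" else ""))
  }
  invisible(x)
}

# JSON-serializable view of the report (null count vectors kept; testthat
# determinism checks compare these files byte for byte).
.report_json <- function(report) {
  enr <- lapply(report$enrichment, function(r) {
    list(cell_type = r$cell_type, mark = r$mark, x = r$x, mu = r$mu,
         sigma = r$sigma, z = r$z, p_z = r$p_z, p_emp = r$p_emp,
         degenerate = r$degenerate,
         per_block_counts = as.list(r$per_block_counts),
         bins = as.character(r$bins),
         config = r$config, null_counts = r$null$counts)
  })
  list(enrichment = enr, gated = report$gated,
       gene_rosters = report$gene_rosters,
       overlap = lapply(report$overlap, function(o) {
         list(per_tad = o$per_tad, n_marked_tads = o$n_marked_tads,
              n_tads_with_deg = o$n_tads_with_deg, fraction = o$fraction,
              per_gene = o$per_gene)
       }),
       deg_fraction = report$deg_fraction,
       shared_genes = report$shared_genes,
       negative_checks = lapply(report$negative_checks, function(n) {
         list(cell_type = n$cell_type, mark = n$mark,
              n_marked = n$n_marked, n_blocks = n$n_blocks,
              per_block = as.list(n$per_block))
       }),
       skipped = report$skipped,
       provenance = report$provenance)
}

#' Write report artifacts
#'
#' Writes `report.json` (full serializable report), `matrix.tsv` (the
#' block-by-dataset count matrix with x/z/p footer) and per-gated-cell
#' gene roster TSVs into `dir`.
#'
#' @param report A `run_report`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(json = file.path(dir, "report.json"),
             matrix = file.path(dir, "matrix.tsv"))
  jsonlite::write_json(.report_json(report), paths[["json"]],
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "list")
  write_matrix(report, paths[["matrix"]])
  for (ct in names(report$gene_rosters)) {
    f <- file.path(dir, sprintf("genes_%s.tsv", ct))
    writeLines(c("symbol", report$gene_rosters[[ct]]), f)
    paths[[paste0("genes_", ct)]] <- f
  }
  invisible(paths)
}

#' Write the block-by-dataset presence matrix
#'
#' Rows are LD blocks; columns are (cell type, mark) peak sets; cells are
#' per-block peak counts with the bin label appended in a `:bin` column.
#' Footer rows carry the observed x, z, p and a dagger for significant
#' columns.
#'
#' @param report A `run_report`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(report, path) {
  enr <- report$enrichment
  if (length(enr) == 0) {
    writeLines("block", path)
    return(invisible(path))
  }
  block_names <- names(enr[[1]]$per_block_counts)
  if (is.null(block_names)) {
    block_names <- sprintf("block_%02d", seq_along(enr[[1]]$per_block_counts))
  }
  counts <- vapply(enr, `[[`, numeric(length(block_names)),
                   "per_block_counts")
  counts <- matrix(counts, nrow = length(block_names),
                   dimnames = list(block_names, names(enr)))
  bins <- vapply(enr, function(r) as.character(r$bins),
                 character(length(block_names)))
  header <- c("block", as.vector(rbind(colnames(counts),
                                       paste0(colnames(counts), ":bin"))))
  body <- vapply(seq_along(block_names), function(i) {
    paste(c(block_names[i],
            as.vector(rbind(format(counts[i, ], trim = TRUE), bins[i, ]))),
          collapse = "\t")
  }, "")
  footer_vals <- function(f, fmt) {
    vapply(enr, function(r) sprintf(fmt, f(r)), "")
  }
  alpha <- report$provenance$alpha
  footer <- c(
    paste(c("x", as.vector(rbind(footer_vals(function(r) r$x, "%g"), ""))),
          collapse = "\t"),
    paste(c("z", as.vector(rbind(footer_vals(function(r) r$z, "%.4f"), ""))),
          collapse = "\t"),
    paste(c("p", as.vector(rbind(footer_vals(function(r) r$p_z, "%.6g"),
                                 ""))), collapse = "\t"),
    paste(c("significant",
            as.vector(rbind(vapply(enr, function(r)
              if (r$p_z < alpha) "†" else "", ""), ""))),
          collapse = "\t"))
  writeLines(c(paste(header, collapse = "\t"), body, footer), path)
  invisible(path)
}

#' Structurally validate a run report
#'
#' Checks the report (or its JSON serialization) against the required
#' fields and types of the bundled schema
#' (`inst/schema/run_report_schema.json`).
#'
#' @param report A `run_report` or a path to a `report.json`.
#' @return `TRUE`, or an error describing the first violation.
#' @export
validate_report <- function(report) {
  obj <- if (is.character(report)) {
    jsonlite::read_json(report, simplifyVector = FALSE)
  } else {
    stopifnot(inherits(report, "run_report"))
    .report_json(report)
  }
  schema <- jsonlite::read_json(
    system.file("schema", "run_report_schema.json", package = "hapmark",
                mustWork = TRUE), simplifyVector = FALSE)
  need <- unlist(schema$required)
  miss <- setdiff(need, names(obj))
  if (length(miss)) stop("report missing field(s): ",
                         paste(miss, collapse = ", "))
  for (key in names(obj$enrichment)) {
    e <- obj$enrichment[[key]]
    emiss <- setdiff(unlist(schema$properties$enrichment$itemRequired),
                     names(e))
    if (length(emiss)) stop("enrichment entry ", key, " missing: ",
                            paste(emiss, collapse = ", "))
    for (f in c("x", "mu", "sigma", "p_z", "p_emp")) {
      if (!is.numeric(e[[f]]) && !is.numeric(unlist(e[[f]]))) {
        stop("enrichment entry ", key, " field ", f, " is not numeric")
      }
    }
  }
  pmiss <- setdiff(unlist(schema$properties$provenance$itemRequired),
                   names(obj$provenance))
  if (length(pmiss)) stop("provenance missing: ",
                          paste(pmiss, collapse = ", "))
  TRUE
}
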