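#' Construct a table of genomic intervals
#'
#' Intervals are 0-based, half-open `[start, end)` (the BED convention), so
#' an interval's length is `end - start`. This is the coordinate convention
#' used throughout the package; it reproduces published haplotype-block
#' lengths exactly (see [ia_ld_blocks()]).
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer-valued vector of 0-based inclusive start positions.
#' @param end Integer-valued vector of exclusive end positions.
#' @param name Optional character vector of labels (recycled if length 1).
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `name` and
#'   class `genomic_intervals`.
#' @examples
#' genomic_intervals("chr1", 100, 200, "pk1")
#' @export
genomic_intervals <- function(chrom, start, end, name = NA_character_) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- max(length(chrom), length(start), length(end),
           if (length(chrom) == 0 || length(start) == 0) 0 else 1)
  if (length(start) == 0 || length(chrom) == 0) n <- 0
  if (length(chrom) == 1) chrom <- rep_len(chrom, n)
  name <- rep_len(as.character(name), n)
  if (length(chrom) != n || length(start) != n || length(end) != n) {
    stop("chrom, start and end must have equal length")
  }
  if (n > 0) {
    if (anyNA(chrom) || anyNA(start) || anyNA(end)) {
      stop("intervals must not contain missing chrom/start/end")
    }
    if (any(start != floor(start)) || any(end != floor(end))) {
      stop("start and end must be integer-valued base-pair positions")
    }
    if (any(start < 0)) stop("start positions must be >= 0")
    if (any(end <= start)) {
      bad <- which(end <= start)[1L]
      stop(sprintf("interval %d has end <= start (%s:%g-%g); zero- and negative-length intervals are invalid",
                   bad, chrom[bad], start[bad], end[bad]))
    }
  }
  out <- data.frame(chrom = chrom, start = start, end = end, name = name,
                    stringsAsFactors = FALSE)
  class(out) <- c("genomic_intervals", "data.frame")
  out
}

.as_intervals <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(x)))
    nm <- if ("name" %in% names(x)) x$name else NA_character_
    genomic_intervals(x$chrom, x$start, x$end, nm)
  } else if (inherits(x, "peak_set")) {
    x$peaks
  } else {
    stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
         " as genomic intervals")
  }
}

#' Interval length in base pairs
#'
#' @param iv A `genomic_intervals` table (or any data frame with
#'   `start`/`end` columns).
#' @return Numeric vector `end - start`.
#' @examples
#' interval_length(genomic_intervals("chr2", 197283467, 197358397)) # 74930
#' @export
interval_length <- function(iv) {
  iv <- .as_intervals(iv)
  iv$end - iv$start
}

#' Read a BED file
#'
#' Accepts BED3 and wider; the 4th column, when present, becomes the
#' interval name. `track`, `browser` and `#` comment lines and blank lines
#' are skipped; input order is preserved; CRLF endings are tolerated.
#'
#' @param path Path to a tab-separated BED file.
#' @return A `genomic_intervals` table in file order.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  keep <- !(grepl("^\\s*$", lines) | grepl("^(track|browser|#)", lines))
  idx <- which(keep)
  if (length(idx) == 0) return(genomic_intervals(character(), numeric(), numeric()))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  parse_one <- function(f, lineno) {
    if (length(f) < 3) {
      stop(sprintf("%s line %d: expected >= 3 tab-separated columns", path, lineno))
    }
    start <- suppressWarnings(as.numeric(f[2]))
    end <- suppressWarnings(as.numeric(f[3]))
    if (is.na(start) || is.na(end) ||
        start != floor(start) || end != floor(end)) {
      stop(sprintf("%s line %d: non-integer coordinates '%s', '%s'",
                   path, lineno, f[2], f[3]))
    }
    if (start < 0 || end <= start) {
      stop(sprintf("%s line %d: invalid interval %s:%g-%g (need 0 <= start < end)",
                   path, lineno, f[1], start, end))
    }
    c(f[1], f[2], f[3], if (length(f) >= 4) f[4] else NA_character_)
  }
  parsed <- mapply(parse_one, fields, idx, SIMPLIFY = FALSE)
  m <- do.call(rbind, parsed)
  genomic_intervals(m[, 1], as.numeric(m[, 2]), as.numeric(m[, 3]), m[, 4])
}

#' Write intervals as BED
#'
#' Emits BED4 when any interval is named, BED3 otherwise. Coordinates are
#' written in plain (non-scientific) notation so that write/read round-trips
#' are exact.
#'
#' @param iv A `genomic_intervals` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(iv, path) {
  iv <- .as_intervals(iv)
  coords <- cbind(iv$chrom,
                  format(iv$start, scientific = FALSE, trim = TRUE),
                  format(iv$end, scientific = FALSE, trim = TRUE))
  lines <- if (any(!is.na(iv$name))) {
    paste(coords[, 1], coords[, 2], coords[, 3],
          ifelse(is.na(iv$name), ".", iv$name), sep = "\t")
  } else {
    paste(coords[, 1], coords[, 2], coords[, 3], sep = "\t")
  }
  writeLines(if (nrow(iv) == 0) character() else lines, path)
  invisible(path)
}

#' Read a chrom.sizes table
#'
#' @param path Two-column TSV of chromosome name and length (bp).
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("chrom.sizes file not found: ", path)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  lines <- lines[!grepl("^\\s*$", lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2)) stop(path, ": each line needs <name>\t<length>")
  nm <- vapply(fields, `[`, "", 1L)
  len <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  if (anyNA(len)) stop(path, ": non-numeric chromosome length")
  if (anyDuplicated(nm)) {
    stop(path, ": duplicate chromosome ", nm[duplicated(nm)][1L])
  }
  if (any(len <= 0)) stop(path, ": non-positive chromosome length for ",
                          nm[len <= 0][1L])
  stats::setNames(len, nm)
}

#' Write a chrom.sizes table
#' @param sizes Named numeric vector of chromosome lengths.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(sizes, path) {
  stopifnot(!is.null(names(sizes)), all(sizes > 0))
  writeLines(paste(names(sizes),
                   format(unname(sizes), scientific = FALSE, trim = TRUE),
                   sep = "\t"), path)
  invisible(path)
}

# GRanges conversion with unified seqlevels so overlap ops don't warn when
# the two sides carry different chromosome name sets.
.as_gr_pair <- function(a, b) {
  lv <- union(unique(a$chrom), unique(b$chrom))
  make <- function(x) {
    GenomicRanges::GRanges(
      seqnames = factor(x$chrom, levels = lv),
      ranges = IRanges::IRanges(start = x$start + 1, end = x$end))
  }
  list(make(a), make(b))
}

#' Count overlapping subject intervals per query
#'
#' An overlap is >= 1 shared base under half-open semantics: intervals
#' `[s1,e1)` and `[s2,e2)` on the same chromosome overlap iff `s1 < e2` and
#' `s2 < e1`. Abutting intervals do not overlap.
#'
#' When no overlap is found at all and the two inputs use disjoint
#' chromosome name sets (e.g. "chr1" vs "1"), a warning points at the
#' likely naming-dialect mismatch.
#'
#' @param queries,subjects `genomic_intervals` tables (a [peak_set()] is
#'   accepted and its peaks used).
#' @return Integer vector, one count per query.
#' @export
intersect_counts <- function(queries, subjects) {
  queries <- .as_intervals(queries)
  subjects <- .as_intervals(subjects)
  if (nrow(queries) == 0) return(integer(0))
  if (nrow(subjects) == 0) return(integer(nrow(queries)))
  gr <- .as_gr_pair(queries, subjects)
  counts <- GenomicRanges::countOverlaps(gr[[1]], gr[[2]], minoverlap = 1L)
  if (sum(counts) == 0 &&
      length(intersect(unique(queries$chrom), unique(subjects$chrom))) == 0) {
    warning("no overlaps and the chromosome name sets are disjoint; ",
            "check for a 'chr' prefix dialect mismatch")
  }
  as.integer(counts)
}
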