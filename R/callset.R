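#' Construct a CNV loss callset
#'
#' A callset is a tibble of copy-number-loss calls, one row per call, with
#' columns `chrom`, `start`, `end` (0-based half-open coordinates),
#' `sample_id`, `cnv_type` (always `"loss"`), `copy_state` and `source`.
#' All interval arithmetic in the package assumes this single coordinate
#' convention; the readers convert from each format's native dialect.
#'
#' @param x A data frame with at least `chrom`, `start`, `end`. Missing
#'   `sample_id` defaults to `"*"` (a sites-only callset that matches any
#'   sample), missing `copy_state` to `NA`.
#' @param source Label for the callset origin (e.g. `"hapmap"`, `"1000g"`,
#'   `"cnvhac"`). Taken from `x$source` if present.
#' @param assembly_tag Genome assembly the coordinates refer to. Comparing
#'   callsets with different tags is an error.
#' @return A tibble of class `cnv_callset`, sorted by `(chrom, start, end)`.
#' @export
cnv_callset <- function(x, source = "callset", assembly_tag = "hg19") {
  x <- as_tibble(x)
  for (col in c("chrom", "start", "end")) {
    if (!col %in% names(x)) abort(paste0("callset is missing column '", col, "'"))
  }
  if (!"sample_id" %in% names(x)) x$sample_id <- rep("*", nrow(x))
  if (!"copy_state" %in% names(x)) x$copy_state <- rep(NA_character_, nrow(x))
  if (!"source" %in% names(x)) x$source <- rep(source, nrow(x))
  if (!"cnv_type" %in% names(x)) x$cnv_type <- rep("loss", nrow(x))
  x <- x[, c("chrom", "start", "end", "sample_id", "cnv_type", "copy_state", "source")]
  x$start <- as.double(x$start)
  x$end <- as.double(x$end)
  if (nrow(x) > 0) {
    if (any(is.na(x$start) | is.na(x$end))) abort("callset has NA coordinates")
    if (any(x$end <= x$start)) {
      bad <- which(x$end <= x$start)[1]
      abort(sprintf("call %d has end <= start (%s:%g-%g)",
                    bad, x$chrom[bad], x$start[bad], x$end[bad]))
    }
    if (any(!nzchar(x$chrom)) || any(is.na(x$chrom))) abort("empty chromosome name")
    if (any(x$cnv_type != "loss")) abort("only cnv_type 'loss' is supported")
    if (length(unique(x$source)) > 1) abort("all calls in a callset must share one source")
  }
  x <- arrange(x, .data$chrom, .data$start, .data$end)
  attr(x, "assembly_tag") <- assembly_tag
  class(x) <- c("cnv_callset", class(x))
  x
}

#' @export
print.cnv_callset <- function(x, ...) {
  cat(sprintf("# CNV loss callset '%s' (%s): %d calls, %d sample(s)\n",
              if (nrow(x) > 0) x$source[1] else "empty",
              attr(x, "assembly_tag") %||% "?",
              nrow(x), length(unique(x$sample_id))))
  NextMethod()
}

assembly_tag <- function(x) attr(x, "assembly_tag") %||% "hg19"

check_same_assembly <- function(a, b) {
  ta <- assembly_tag(a); tb <- assembly_tag(b)
  if (!identical(ta, tb)) {
    abort(sprintf("callsets use different assemblies ('%s' vs '%s')", ta, tb))
  }
  invisible(TRUE)
}

#' Read a BED-like callset of copy-number losses
#'
#' Reads tab-separated interval tables with columns chrom/start/end and an
#' optional sample column. The coordinate `dialect` declares how the file's
#' coordinates are encoded; everything is converted to the package-wide
#' 0-based half-open convention. Overlapping rows are retained as-is (the
#' reader never merges calls).
#'
#' @param path Path to a tab-separated text file. Lines starting with `#` or
#'   a `track` line are skipped.
#' @param source_label Source label stored on the callset.
#' @param dialect `"bed"` for 0-based half-open input (the BED standard) or
#'   `"one_based"` for 1-based fully-closed report tables.
#' @param sample_column Column index holding the sample id, or `NA` to emit a
#'   sites-only callset (`sample_id = "*"`). Default uses column 4 when
#'   present.
#' @param assembly_tag Assembly label recorded on the callset.
#' @return A [cnv_callset()] tibble.
#' @export
read_bed_callset <- function(path, source_label = "callset",
                             dialect = c("bed", "one_based"),
                             sample_column = NULL, assembly_tag = "hg19") {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(cnv_callset(tibble(chrom = character(), start = double(), end = double()),
                       source = source_label, assembly_tag = assembly_tag))
  }
  parts <- strsplit(lines, "\t| +")
  nfield <- lengths(parts)
  if (any(nfield < 3)) {
    abort(sprintf("malformed row at line %d of %s: fewer than 3 columns",
                  lineno[which(nfield < 3)[1]], path))
  }
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- suppressWarnings(as.double(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.double(vapply(parts, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    abort(sprintf("malformed row at line %d of %s: non-numeric coordinates",
                  lineno[which(is.na(start) | is.na(end))[1]], path))
  }
  if (is.null(sample_column)) sample_column <- if (all(nfield >= 4)) 4L else NA_integer_
  sample_id <- if (is.na(sample_column)) {
    rep("*", length(chrom))
  } else {
    vapply(parts, function(p) if (length(p) >= sample_column) p[[sample_column]] else "*", "")
  }
  if (dialect == "one_based") start <- start - 1
  bad <- which(end <= start)
  if (length(bad) > 0) {
    abort(sprintf("row at line %d of %s has end <= start after conversion",
                  lineno[bad[1]], path))
  }
  cnv_callset(tibble(chrom = chrom, start = start, end = end, sample_id = sample_id),
              source = source_label, assembly_tag = assembly_tag)
}

#' Write a callset as BED-like text
#'
#' Inverse of [read_bed_callset()]: `read_bed_callset()` then
#' `write_bed_callset()` under the same dialect reproduces the coordinate
#' columns textually.
#'
#' @param x A callset tibble.
#' @param path Output path.
#' @param dialect Coordinate dialect to emit (see [read_bed_callset()]).
#' @return `path`, invisibly.
#' @export
write_bed_callset <- function(x, path, dialect = c("bed", "one_based")) {
  dialect <- match.arg(dialect)
  start <- x$start
  if (dialect == "one_based") start <- start + 1
  lines <- sprintf("%s\t%d\t%d\t%s", x$chrom, as.integer(start), as.integer(x$end),
                   x$sample_id)
  writeLines(lines, path)
  invisible(path)
}

#' Read SNP-array probe positions
#'
#' Accepts BED-like text with either two columns (chrom, position) or three
#' or more (chrom, start, end; the start is taken as the probe position,
#' 0-based). Input need not be sorted; duplicates are dropped.
#'
#' @param path Path to the probe table.
#' @return A tibble of class `probe_map` with columns `chrom`, `pos`, sorted
#'   and strictly increasing within each chromosome.
#' @export
read_probe_map <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0) return(probe_map(tibble(chrom = character(), pos = double())))
  parts <- strsplit(lines, "\t| +")
  chrom <- vapply(parts, `[[`, "", 1L)
  pos <- suppressWarnings(as.double(vapply(parts, `[[`, "", 2L)))
  if (anyNA(pos)) abort("non-numeric probe coordinate")
  probe_map(tibble(chrom = chrom, pos = pos))
}

#' @rdname read_probe_map
#' @param x A data frame with columns `chrom` and `pos`.
#' @export
probe_map <- function(x) {
  x <- as_tibble(x)[, c("chrom", "pos")]
  x <- distinct(arrange(x, .data$chrom, .data$pos))
  class(x) <- c("probe_map", class(x))
  x
}

#' Read gene-region annotation
#'
#' BED-like text of gene spans used by [gene_region_filter()]. Unsorted input
#' is accepted and sorted; duplicate rows are dropped.
#'
#' @param path Path to a BED-like file.
#' @return A tibble with columns `chrom`, `start`, `end` (0-based half-open).
#' @export
read_gene_regions <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0) return(tibble(chrom = character(), start = double(), end = double()))
  parts <- strsplit(lines, "\t| +")
  if (any(lengths(parts) < 3)) abort("gene region rows need chrom/start/end")
  out <- tibble(
    chrom = vapply(parts, `[[`, "", 1L),
    start = suppressWarnings(as.double(vapply(parts, `[[`, "", 2L))),
    end = suppressWarnings(as.double(vapply(parts, `[[`, "", 3L)))
  )
  if (anyNA(out$start) || anyNA(out$end)) abort("non-numeric gene coordinates")
  distinct(arrange(out, .data$chrom, .data$start, .data$end))
}
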