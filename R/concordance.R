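#' Base pairs shared by two genomic intervals
#'
#' Vectorised overlap primitive: intervals on different chromosomes share 0
#' base pairs; otherwise `max(0, min(end) - max(start))` under the 0-based
#' half-open convention.
#'
#' @param a,b Data frames with columns `chrom`, `start`, `end`; rows are
#'   recycled to a common length.
#' @return Integer-valued vector of overlap lengths in base pairs.
#' @export
overlap_bp <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n)
  bi <- rep_len(seq_len(nrow(b)), n)
  ov <- pmax(0, pmin(a$end[ai], b$end[bi]) - pmax(a$start[ai], b$start[bi]))
  ov[a$chrom[ai] != b$chrom[bi]] <- 0
  ov
}

# Expand the (call, partner) pairs that are candidates for matching: same
# chromosome, and same sample unless either side is the sites-only wildcard
# "*" (a sites-only callset is compared against the union of samples).
candidate_pairs <- function(a, b) {
  a2 <- mutate(as_tibble(a)[, c("chrom", "start", "end", "sample_id")],
               .a_row = row_number())
  b2 <- mutate(as_tibble(b)[, c("chrom", "start", "end", "sample_id")],
               .b_row = row_number())
  pairs <- inner_join(a2, b2, by = "chrom", suffix = c("_a", "_b"),
                      relationship = "many-to-many")
  filter(pairs,
         .data$sample_id_a == .data$sample_id_b |
           .data$sample_id_a == "*" | .data$sample_id_b == "*")
}

#' Directional 50% base-pair matching of calls against a partner callset
#'
#' A call `a` matches callset `B` when a *single* partner call covers at
#' least `threshold` of `a`'s own base pairs. The rule is directional: the
#' fraction is measured against `a`'s length, so `matches(a, B)` and
#' `matches(b, A)` can disagree, which is what makes the two overlap counts
#' of a comparison table asymmetric. Calls are paired within identical
#' `sample_id`s; a sites-only side (`sample_id == "*"`) is compared against
#' all samples of the other.
#'
#' @param calls Callset whose calls are tested (query side).
#' @param partners Callset providing potential partners.
#' @param threshold Fraction of the query call's length that one partner must
#'   cover (default 0.5).
#' @return Logical vector, one element per row of `calls`.
#' @export
cnv_matches <- function(calls, partners, threshold = 0.5) {
  if (nrow(calls) == 0) return(logical(0))
  if (nrow(partners) == 0) return(rep(FALSE, nrow(calls)))
  pairs <- candidate_pairs(calls, partners)
  out <- rep(FALSE, nrow(calls))
  if (nrow(pairs) == 0) return(out)
  pairs$ov <- pmax(0, pmin(pairs$end_a, pairs$end_b) -
                     pmax(pairs$start_a, pairs$start_b))
  pairs <- filter(pairs, .data$ov >= threshold * (.data$end_a - .data$start_a))
  out[unique(pairs$.a_row)] <- TRUE
  out
}

#' Keep calls containing at least a minimum number of array probes
#'
#' Microarray callers need several consecutive probes to call a region, so
#' sequencing calls spanning fewer probe positions are not comparable across
#' platforms and are removed. Probe membership uses the half-open rule: a
#' probe at `start` counts, a probe at `end` does not.
#'
#' @param calls A callset tibble.
#' @param probes A [probe_map()] tibble.
#' @param min_probes Minimum probe count for a call to be retained (default 5).
#' @return The filtered callset.
#' @export
probe_count_filter <- function(calls, probes, min_probes = 5) {
  if (nrow(calls) == 0) return(calls)
  counts <- count_probes(calls, probes)
  keep_calls(calls, counts >= min_probes)
}

#' @rdname probe_count_filter
#' @return `count_probes()` returns the per-call probe counts.
#' @export
count_probes <- function(calls, probes) {
  counts <- integer(nrow(calls))
  for (ch in unique(calls$chrom)) {
    pos <- sort(probes$pos[probes$chrom == ch])
    ci <- which(calls$chrom == ch)
    if (length(pos) == 0) next
    counts[ci] <- findInterval(calls$end[ci] - 0.5, pos) -
      findInterval(calls$start[ci] - 0.5, pos)
  }
  counts
}

#' Keep calls overlapping annotated gene regions
#'
#' Retains calls sharing at least one base with any gene interval (a device
#' to avoid highly repetitive, gene-poor regions). Abutting intervals
#' (`call end == gene start`) share no base and are removed.
#'
#' @param calls A callset tibble.
#' @param genes Tibble of gene intervals (`chrom`, `start`, `end`).
#' @return The filtered callset.
#' @export
gene_region_filter <- function(calls, genes) {
  if (nrow(calls) == 0) return(calls)
  keep <- rep(FALSE, nrow(calls))
  for (ch in unique(calls$chrom)) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    ci <- which(calls$chrom == ch)
    if (nrow(g) == 0) next
    m <- merge_intervals(g$start, g$end)
    # call overlaps some merged interval iff the last merged start before its
    # end lies in an interval ending after the call's start
    idx <- findInterval(calls$end[ci] - 0.5, m$start)
    ok <- idx >= 1 & ifelse(idx >= 1, m$end[pmax(idx, 1)] > calls$start[ci], FALSE)
    # idx points at the merged interval with the largest start < call end;
    # earlier intervals end even earlier, so this one decides.
    keep[ci] <- ok
  }
  keep_calls(calls, keep)
}

merge_intervals <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- double(0); out_e <- double(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  list(start = c(out_s, ms), end = c(out_e, me))
}

keep_calls <- function(calls, keep) {
  out <- calls[keep, , drop = FALSE]
  attr(out, "assembly_tag") <- attr(calls, "assembly_tag")
  class(out) <- class(calls)
  out
}

#' Two-way concordance of callsets under the directional 50% rule
#'
#' Produces one comparison-table row: how many calls of `a` are matched by
#' `b` and vice versa, with percentages. The two overlapped counts generally
#' differ because several calls from one callset can match a single call from
#' the other. Filters (probe count, gene regions, shared samples, scope) are
#' expected to have been applied upstream.
#'
#' @param a,b Callset tibbles.
#' @param scope Label for the row (e.g. a chromosome name or
#'   `"whole genome"`). Defaults to `"all"`.
#' @param threshold Directional overlap threshold (default 0.5).
#' @return A one-row tibble with columns `scope`, `a_source`, `a_total`,
#'   `a_overlapped`, `a_pct`, `b_source`, `b_total`, `b_overlapped`, `b_pct`.
#'   Percentages are rounded half-up to 2 decimals.
#' @export
concordance_table <- function(a, b, scope = "all", threshold = 0.5) {
  check_same_assembly(a, b)
  a_m <- cnv_matches(a, b, threshold)
  b_m <- cnv_matches(b, a, threshold)
  pct <- function(k, n) if (n == 0) NA_real_ else round_half_up(100 * k / n, 2)
  tibble(
    scope = scope,
    a_source = if (nrow(a) > 0) a$source[1] else NA_character_,
    a_total = nrow(a), a_overlapped = sum(a_m), a_pct = pct(sum(a_m), nrow(a)),
    b_source = if (nrow(b) > 0) b$source[1] else NA_character_,
    b_total = nrow(b), b_overlapped = sum(b_m), b_pct = pct(sum(b_m), nrow(b))
  )
}

#' Overlap-length statistics over matched call pairs
#'
#' For every call of `a` that matches `b` under the directional rule, the
#' best partner (largest overlap; ties broken by sort order) is paired with
#' it; the summary reports the mean and mode of the pairwise overlap lengths
#' and each pair's overlap as a fraction of the query call's length. The mode
#' is the most frequent observed overlap length (smallest on ties).
#'
#' @inheritParams concordance_table
#' @return A list of class `overlap_stats` with elements `mean_overlap_bp`,
#'   `mode_overlap_bp`, `ratio_to_length` and the pair table `pairs`.
#' @export
overlap_length_stats <- function(a, b, threshold = 0.5) {
  empty <- structure(
    list(mean_overlap_bp = NA_real_, mode_overlap_bp = NA_real_,
         ratio_to_length = double(0),
         pairs = tibble(a_row = integer(), b_row = integer(),
                        overlap_bp = double(), ratio = double())),
    class = "overlap_stats")
  if (nrow(a) == 0 || nrow(b) == 0) return(empty)
  pairs <- candidate_pairs(a, b)
  if (nrow(pairs) == 0) return(empty)
  pairs$ov <- pmax(0, pmin(pairs$end_a, pairs$end_b) -
                     pmax(pairs$start_a, pairs$start_b))
  pairs <- filter(pairs, .data$ov >= threshold * (.data$end_a - .data$start_a))
  if (nrow(pairs) == 0) return(empty)
  pairs <- arrange(pairs, .data$.a_row, dplyr::desc(.data$ov), .data$.b_row)
  best <- pairs[!duplicated(pairs$.a_row), , drop = FALSE]
  ov <- best$ov
  tab <- sort(table(ov), decreasing = TRUE)
  mode_val <- as.double(names(tab)[tab == max(tab)])
  structure(
    list(
      mean_overlap_bp = mean(ov),
      mode_overlap_bp = min(mode_val),
      ratio_to_length = ov / (best$end_a - best$start_a),
      pairs = tibble(a_row = best$.a_row, b_row = best$.b_row,
                     overlap_bp = ov, ratio = ov / (best$end_a - best$start_a))
    ),
    class = "overlap_stats")
}

#' @export
print.overlap_stats <- function(x, ...) {
  cat(sprintf("# overlap stats over %d matched pairs: mean %.1f bp, mode %s bp\n",
              nrow(x$pairs), x$mean_overlap_bp,
              format(x$mode_overlap_bp)))
  invisible(x)
}
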