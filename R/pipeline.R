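#' Validate candidate deletions end-to-end
#'
#' The full workflow for one sample: every candidate region is tested for
#' depressed read depth against a chromosome-wide background (permutation
#' and chi-square tests) and against its two flanks (the concavity check),
#' and searched for breakpoint evidence by local assembly with a paired-end
#' fallback. Summaries mirror the shape of a published validation: per-test
#' rejection fractions at the configured significance levels and the
#' three-way evidence proportions.
#'
#' All randomness derives from `seed`; per-candidate seeds are
#' deterministic functions of it, so two runs with the same inputs and seed
#' produce byte-identical output files.
#'
#' @param bam_path Indexed BAM of the sample.
#' @param reference Reference sequence (see [seek_breakpoints()]).
#' @param candidates Candidate loss calls (`chrom`, `start`, `end`, ...).
#' @param outdir Optional directory for TSV/JSON reports.
#' @param seed Master seed.
#' @param n_resamples Permutation resamples per test (default 999).
#' @param alphas Significance levels for the summaries.
#' @param flank_factor Flank length multiple for the adjacency tests.
#' @param exclude_all_candidates Exclude every candidate region (not just
#'   the tested one) from background sampling (default TRUE).
#' @param ... Passed to [seek_breakpoints()].
#' @return A list of class `cnv_validation`: `per_candidate` tibble,
#'   `whole_summary`, `adjacency_summary`, `evidence_summary`, `paths`.
#' @export
run_full_validation <- function(bam_path, reference, candidates,
                                outdir = NULL, seed = 1, n_resamples = 999,
                                alphas = c(0.01, 0.05), flank_factor = 1,
                                exclude_all_candidates = TRUE, ...) {
  candidates <- as_tibble(candidates)
  n <- nrow(candidates)
  hdr <- Rsamtools::scanBamHeader(bam_path)[[1]]$targets
  profiles <- list()
  for (ch in unique(candidates$chrom)) {
    profiles[[ch]] <- extract_depth(bam_path, ch, 0, hdr[[ch]])
  }
  rows <- vector("list", n)
  adj_rows <- vector("list", n)
  for (i in seq_len(n)) {
    ch <- candidates$chrom[i]
    cs <- candidates$start[i]; ce <- candidates$end[i]
    prof <- profiles[[ch]]
    region <- slice_depth(prof, cs, ce)
    excl <- if (exclude_all_candidates) {
      candidates[candidates$chrom == ch, c("start", "end")]
    } else {
      tibble(start = cs, end = ce)
    }
    bg <- sample_background(prof$depth, ce - cs, exclusions = excl,
                            seed = derive_seed(seed, i))
    perm <- permutation_depth_test(region, bg, n_resamples = n_resamples,
                                   seed = derive_seed(seed, 100000 + i))
    chi <- chi2_depth_test(region, bg)
    adj <- adjacency_tests(prof, cs, ce, flank_factor = flank_factor,
                           n_resamples = n_resamples,
                           seed = derive_seed(seed, 200000 + i))
    adj_rows[[i]] <- mutate(adj, candidate = i, .before = 1)
    rows[[i]] <- tibble(
      candidate = i, chrom = ch, start = cs, end = ce,
      mu = perm$mu,
      perm_p = perm$p_value, perm_status = perm$status,
      chi2_stat = chi$statistic, chi2_p = chi$p_value,
      chi2_status = chi$status,
      up_perm_p = adj$p_value[adj$side == "upstream" & adj$test == "permutation"],
      up_chi2_p = adj$p_value[adj$side == "upstream" & adj$test == "chi2"],
      down_perm_p = adj$p_value[adj$side == "downstream" & adj$test == "permutation"],
      down_chi2_p = adj$p_value[adj$side == "downstream" & adj$test == "chi2"]
    )
  }
  per_candidate <- bind_rows(rows)
  adjacency <- bind_rows(adj_rows)
  bp <- seek_breakpoints(bam_path, reference, candidates, ...)
  if (n > 0) {
    per_candidate <- dplyr::bind_cols(
      per_candidate,
      bp[, c("left_break", "right_break", "evidence", "support_count")])
  } else {
    per_candidate <- mutate(per_candidate, left_break = double(),
                            right_break = double(), evidence = character(),
                            support_count = integer())
  }
  whole_summary <- if (n > 0) {
    batch_summary(tibble(
      test = rep(c("chi2", "permutation"), each = n),
      p_value = c(per_candidate$chi2_p, per_candidate$perm_p),
      status = c(per_candidate$chi2_status, per_candidate$perm_status)
    ), alphas = alphas)
  } else tibble()
  adjacency_summary <- if (n > 0) batch_summary(adjacency, alphas = alphas) else tibble()
  evidence_summary <- summarize_evidence(bp)
  paths <- NULL
  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    paths <- list(
      per_candidate = file.path(outdir, "validation_per_candidate.tsv"),
      adjacency = file.path(outdir, "validation_adjacency.tsv"),
      summary = file.path(outdir, "validation_summary.json")
    )
    readr::write_tsv(per_candidate, paths$per_candidate)
    readr::write_tsv(adjacency, paths$adjacency)
    jsonlite::write_json(list(whole = whole_summary,
                              adjacency = adjacency_summary,
                              evidence = evidence_summary),
                         paths$summary, digits = NA, auto_unbox = TRUE)
  }
  structure(list(per_candidate = per_candidate, adjacency = adjacency,
                 whole_summary = whole_summary,
                 adjacency_summary = adjacency_summary,
                 evidence_summary = evidence_summary, paths = paths),
            class = "cnv_validation")
}

#' Pairwise concordance study of two or more callsets
#'
#' For every unordered pair of the supplied callsets: applies the optional
#' probe-count and gene-region filters, restricts both sides to their shared
#' samples (unless one side is sites-only), and computes the directional
#' 50% concordance row per chromosome and for all chromosomes pooled, plus
#' the overlap-length statistics of matched pairs.
#'
#' @param callsets Named list of two or more callset tibbles.
#' @param probes Optional [probe_map()]; when given, calls spanning fewer
#'   than `min_probes` probes are removed from the callsets named in
#'   `probe_filter_on` (default: all of them).
#' @param genes Optional gene regions; calls not touching any gene are
#'   removed.
#' @param min_probes Probe-count threshold (default 5).
#' @param threshold Directional overlap threshold (default 0.5).
#' @param probe_filter_on Names of callsets the probe filter applies to.
#' @param outlier_factor When non-`NULL`, samples with more calls than
#'   `outlier_factor` times the callset's median per-sample count are
#'   dropped first (the guard against ultra-noisy samples); default `NULL`
#'   (off).
#' @return A list of class `cnv_concordance`: `tables` (tibble of
#'   concordance rows, one per pair and scope) and `overlap` (named list of
#'   [overlap_length_stats()] per pair, whole scope).
#' @export
run_concordance_study <- function(callsets, probes = NULL, genes = NULL,
                                  min_probes = 5, threshold = 0.5,
                                  probe_filter_on = names(callsets),
                                  outlier_factor = NULL) {
  stopifnot(length(callsets) >= 2, !is.null(names(callsets)))
  prep <- callsets
  for (nm in names(prep)) {
    cs <- prep[[nm]]
    if (!is.null(outlier_factor)) cs <- filter_outlier_samples(cs, outlier_factor)
    if (!is.null(probes) && nm %in% probe_filter_on) {
      cs <- probe_count_filter(cs, probes, min_probes)
    }
    if (!is.null(genes)) cs <- gene_region_filter(cs, genes)
    prep[[nm]] <- cs
  }
  nms <- names(prep)
  tables <- list()
  overlap <- list()
  for (i in seq_along(nms)) {
    for (j in seq_along(nms)) {
      if (j <= i) next
      ab <- restrict_shared_samples(prep[[nms[i]]], prep[[nms[j]]])
      a <- ab[[1]]; b <- ab[[2]]
      chroms <- sort(unique(c(a$chrom, b$chrom)))
      rows <- lapply(chroms, function(ch) {
        concordance_table(keep_calls(a, a$chrom == ch),
                          keep_calls(b, b$chrom == ch),
                          scope = ch, threshold = threshold)
      })
      rows <- c(rows, list(concordance_table(a, b, scope = "whole genome",
                                             threshold = threshold)))
      pair <- paste(nms[i], nms[j], sep = "_vs_")
      tables[[pair]] <- mutate(bind_rows(rows), pair = pair, .before = 1)
      overlap[[pair]] <- overlap_length_stats(a, b, threshold = threshold)
    }
  }
  structure(list(tables = bind_rows(tables), overlap = overlap),
            class = "cnv_concordance")
}

restrict_shared_samples <- function(a, b) {
  sa <- unique(a$sample_id); sb <- unique(b$sample_id)
  if ("*" %in% sa || "*" %in% sb) return(list(a, b))
  shared <- intersect(sa, sb)
  list(keep_calls(a, a$sample_id %in% shared),
       keep_calls(b, b$sample_id %in% shared))
}

#' Drop samples with outlying call counts
#'
#' Samples whose call count exceeds `factor` times the per-sample median are
#' removed — a guard against samples with an order of magnitude more calls
#' than the rest, which would dominate any comparison.
#'
#' @param calls A callset tibble.
#' @param factor Multiple of the median defining an outlier (default 10).
#' @return The filtered callset.
#' @export
filter_outlier_samples <- function(calls, factor = 10) {
  if (nrow(calls) == 0) return(calls)
  counts <- table(calls$sample_id)
  med <- stats::median(counts)
  bad <- names(counts)[counts > factor * med]
  keep_calls(calls, !(calls$sample_id %in% bad))
}

#' Read a three-sheet workbook of loss reports
#'
#' Loads an XLSX workbook whose sheets each hold one source's loss list
#' (chromosome, start, end and optionally a sample column; columns are
#' located by name, case-insensitively). Report tables are declared 1-based
#' fully-closed unless `dialect` says otherwise.
#'
#' @param path XLSX path.
#' @param sources Source label per sheet (recycled over sheets in order).
#' @param dialect Coordinate dialect of the sheets (see [read_bed_callset()]).
#' @param assembly_tag Assembly label for all three callsets.
#' @return Named list of callsets, one per sheet.
#' @export
read_s2_workbook <- function(path, sources = c("hapmap", "1000g", "cnvhac"),
                             dialect = c("one_based", "bed"),
                             assembly_tag = "hg19") {
  if (!requireNamespace("readxl", quietly = TRUE)) {
    abort("reading workbooks requires the 'readxl' package")
  }
  dialect <- match.arg(dialect)
  sheets <- readxl::excel_sheets(path)
  sources <- rep_len(sources, length(sheets))
  out <- list()
  for (i in seq_along(sheets)) {
    df <- readxl::read_excel(path, sheet = sheets[i])
    nm <- tolower(names(df))
    pick <- function(cands) {
      hit <- which(nm %in% cands)
      if (length(hit) == 0) NA_integer_ else hit[1]
    }
    ci <- pick(c("chrom", "chr", "chromosome"))
    si <- pick(c("start", "begin", "start_pos"))
    ei <- pick(c("end", "stop", "end_pos"))
    pi <- pick(c("sample", "sample_id", "id", "individual"))
    if (is.na(ci) || is.na(si) || is.na(ei)) {
      abort(sprintf("sheet '%s' lacks chrom/start/end columns", sheets[i]))
    }
    x <- tibble(chrom = as.character(df[[ci]]),
                start = as.double(df[[si]]),
                end = as.double(df[[ei]]),
                sample_id = if (is.na(pi)) "*" else as.character(df[[pi]]))
    if (dialect == "one_based") x$start <- x$start - 1
    out[[sources[i]]] <- cnv_callset(x, source = sources[i],
                                     assembly_tag = assembly_tag)
  }
  out
}

#' @rdname read_s2_workbook
#' @param outdir Directory for one TSV per sheet (`<source>.tsv`, BED
#'   dialect).
#' @export
xlsx_to_tsv <- function(path, outdir,
                        sources = c("hapmap", "1000g", "cnvhac"),
                        dialect = c("one_based", "bed")) {
  sets <- read_s2_workbook(path, sources = sources, dialect = dialect)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(sets)) {
    p <- file.path(outdir, paste0(nm, ".tsv"))
    write_bed_callset(sets[[nm]], p)
    paths[nm] <- p
  }
  invisible(paths)
}
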