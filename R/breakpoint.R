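#' Extract the reads relevant to a candidate deletion
#'
#' Collects (i) mapped reads overlapping the two breakpoint-flank windows
#' `[start - flank_bp, start + flank_bp)` and `[end - flank_bp, end + flank_bp)`
#' (clipped to the contig) and (ii) unmapped reads placed, via their mapped
#' mate, inside those windows — the reads that may contain the junction
#' itself. Windows reaching outside the contig are clipped, not an error.
#'
#' @param bam_path Indexed BAM file.
#' @param chrom Contig name.
#' @param start,end Candidate interval, 0-based half-open.
#' @param flank_bp Breakpoint window half-width in bp (default 300).
#' @param unmapped Optional prefetched tibble of the file's placed unmapped
#'   reads (see [scan_unmapped_reads()]); scanned on demand when `NULL`.
#' @return A list of class `read_bundle`: `mapped` and `unmapped` tibbles
#'   (columns `qname`, `pos`, `end`, `reverse`, `mate_pos`, `cigar`, `seq`),
#'   and `windows` (matrix of the two clipped windows).
#' @export
extract_read_bundle <- function(bam_path, chrom, start, end, flank_bp = 300,
                                unmapped = NULL) {
  hdr <- Rsamtools::scanBamHeader(bam_path)[[1]]$targets
  if (!chrom %in% names(hdr)) abort(sprintf("contig '%s' not in BAM header", chrom))
  clen <- hdr[[chrom]]
  w <- rbind(c(max(0, start - flank_bp), min(clen, start + flank_bp)),
             c(max(0, end - flank_bp), min(clen, end + flank_bp)))
  # flank_bp = 0 still means "reads crossing the exact boundary": widen
  # degenerate windows to one base
  for (i in 1:2) if (w[i, 2] <= w[i, 1]) w[i, 2] <- min(clen, w[i, 1] + 1)
  w <- w[w[, 2] > w[, 1], , drop = FALSE]
  which <- GenomicRanges::GRanges(chrom, IRanges::IRanges(w[, 1] + 1, w[, 2]))
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE, isDuplicate = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  what <- c("qname", "flag", "pos", "mpos", "cigar", "seq", "mapq")
  res <- Rsamtools::scanBam(bam_path,
                            param = Rsamtools::ScanBamParam(which = which,
                                                            flag = flag,
                                                            what = what))
  mapped <- bind_rows(lapply(res, function(r) {
    tibble(qname = r$qname, flag = r$flag, pos = r$pos - 1,
           cigar = r$cigar, seq = as.character(r$seq),
           mate_pos = r$mpos - 1)
  }))
  if (nrow(mapped) > 0) {
    mapped <- distinct(mapped, .data$qname, .data$flag, .keep_all = TRUE)
    mapped$reverse <- bitwAnd(mapped$flag, 16L) > 0
    mapped$end <- mapped$pos + cigar_ref_span(mapped$cigar)
  } else {
    mapped$reverse <- logical(0)
    mapped$end <- double(0)
  }
  if (is.null(unmapped)) unmapped <- scan_unmapped_reads(bam_path, chrom)
  in_win <- rep(FALSE, nrow(unmapped))
  for (i in seq_len(nrow(w))) {
    in_win <- in_win | (unmapped$pos >= w[i, 1] & unmapped$pos < w[i, 2])
  }
  structure(list(mapped = mapped, unmapped = unmapped[in_win, , drop = FALSE],
                 windows = w),
            class = "read_bundle")
}

#' @rdname extract_read_bundle
#' @export
scan_unmapped_reads <- function(bam_path, chrom = NULL) {
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = TRUE)
  what <- c("qname", "rname", "pos", "mpos", "seq")
  r <- Rsamtools::scanBam(bam_path,
                          param = Rsamtools::ScanBamParam(flag = flag,
                                                          what = what))[[1]]
  out <- tibble(qname = r$qname, chrom = as.character(r$rname),
                pos = r$pos - 1, mate_pos = r$mpos - 1,
                seq = as.character(r$seq))
  # unmapped records surface with NA pos; they are placed at the mate
  out$pos[is.na(out$pos)] <- out$mate_pos[is.na(out$pos)]
  out <- out[!is.na(out$pos), , drop = FALSE]
  out$reverse <- rep(FALSE, nrow(out))
  out$end <- out$pos
  out$cigar <- rep("*", nrow(out))
  if (!is.null(chrom)) out <- out[!is.na(out$chrom) & out$chrom == chrom, ]
  out
}

# Reference span consumed by a CIGAR string (M/=/X/D/N consume).
cigar_ref_span <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(0)
    ops <- gregexpr("[0-9]+[MIDNSHP=X]", cg)[[1]]
    toks <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    n <- as.double(sub("[A-Z=]$", "", toks))
    op <- sub("^[0-9]+", "", toks)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Seek deletion breakpoints for candidate regions
#'
#' For each candidate: extract the read bundle, assemble it with a de Bruijn
#' graph, split-align every sufficiently long contig against the candidate's
#' expanded reference window, and classify the evidence — `break_read` when
#' a contig spans the junction (direct evidence), otherwise `paired_end`
#' when enough straddling read pairs show a stretched insert, otherwise
#' `unsupported`. The paired-end route is only consulted for candidates the
#' assembly fails on, mirroring its fallback role at low depth.
#'
#' @param bam_path Indexed BAM of the sample's alignments.
#' @param reference Reference sequence: a character scalar (single contig),
#'   a named character vector, or a FASTA path.
#' @param candidates Data frame of candidate deletions (`chrom`, `start`,
#'   `end`, 0-based half-open).
#' @param k K-mer size (default 21).
#' @param flank_bp Breakpoint window half-width (default 300).
#' @param min_count Minimum k-mer multiplicity (default 1, the low-depth
#'   setting; raise to 2 at depths of 10x or more).
#' @param min_anchor Minimum split-alignment anchor (default `k`).
#' @param min_deletion Minimum deletion size for a junction call (default 50).
#' @param insert_mean,insert_sd,read_length Fragment model for the
#'   paired-end fallback.
#' @param min_pairs Minimum straddling pairs for paired-end evidence.
#' @param clip_rounds Assembly tip/bubble clipping rounds (default 2).
#' @return The candidate tibble with columns `left_break`, `right_break`,
#'   `evidence`, `support_count`, `contig_id`, `ambiguous` appended.
#' @export
seek_breakpoints <- function(bam_path, reference, candidates,
                             k = 21, flank_bp = 300, min_count = 1,
                             min_anchor = k, min_deletion = 50,
                             insert_mean = 300, insert_sd = 30,
                             read_length = 100, min_pairs = 2,
                             clip_rounds = 2) {
  ref <- load_reference(reference)
  candidates <- as_tibble(candidates)
  n <- nrow(candidates)
  out <- mutate(candidates,
                left_break = NA_real_, right_break = NA_real_,
                evidence = "unsupported", support_count = 0L,
                contig_id = NA_character_, ambiguous = NA)
  if (n == 0) return(out)
  unmapped_all <- scan_unmapped_reads(bam_path)
  for (i in seq_len(n)) {
    chrom <- candidates$chrom[i]
    cs <- candidates$start[i]; ce <- candidates$end[i]
    if (!chrom %in% names(ref)) next
    rseq <- ref[[chrom]]
    bundle <- extract_read_bundle(bam_path, chrom, cs, ce, flank_bp,
                                  unmapped = unmapped_all[
                                    !is.na(unmapped_all$chrom) &
                                      unmapped_all$chrom == chrom, ])
    reads <- c(bundle$mapped$seq, bundle$unmapped$seq)
    # contigs can extend past the read windows by up to an insert plus a
    # read length, so the alignment window is padded accordingly
    pad <- flank_bp + insert_mean + 2 * read_length
    win_lo <- max(0, cs - pad)
    win_hi <- min(nchar(rseq), ce + pad)
    wseq <- substring(rseq, win_lo + 1, win_hi)
    best <- NULL; best_ctg <- NULL
    if (length(reads) >= 2) {
      g <- build_graph(reads, k = k, min_count = min_count)
      contigs <- assemble_contigs(g, clip_rounds = clip_rounds)
      contigs <- contigs[contigs$length >= 2 * min_anchor, , drop = FALSE]
      for (ci in seq_len(nrow(contigs))) {
        jc <- split_align_contig(contigs$sequence[ci], wseq, win_lo,
                                 min_anchor = min_anchor,
                                 min_deletion = min_deletion)
        if (is.null(jc)) next
        better <- is.null(best) ||
          (best$ambiguous && !jc$ambiguous) ||
          (best$ambiguous == jc$ambiguous &&
             contigs$length[ci] > contigs$length[match(best_ctg, contigs$contig_id)])
        if (better) { best <- jc; best_ctg <- contigs$contig_id[ci] }
      }
      if (!is.null(best)) {
        ci <- match(best_ctg, contigs$contig_id)
        out$left_break[i] <- best$left_break
        out$right_break[i] <- best$right_break
        out$evidence[i] <- "break_read"
        out$support_count[i] <- max(1L, as.integer(round(contigs$mean_coverage[ci])))
        out$contig_id[i] <- best_ctg
        out$ambiguous[i] <- best$ambiguous
      }
    }
    if (is.null(best)) {
      pe <- paired_end_evidence(bundle$mapped, cs, ce,
                                insert_mean = insert_mean,
                                insert_sd = insert_sd,
                                read_length = read_length,
                                min_pairs = min_pairs)
      if (!is.null(pe)) {
        out$left_break[i] <- pe$left_break
        out$right_break[i] <- pe$right_break
        out$evidence[i] <- "paired_end"
        out$support_count[i] <- pe$support_count
        out$ambiguous[i] <- TRUE
      }
    }
  }
  out
}

load_reference <- function(reference) {
  if (length(reference) == 1 && !grepl("^[ACGTNacgtn]+$", reference) &&
      file.exists(reference)) {
    ss <- Biostrings::readDNAStringSet(reference)
    ref <- as.character(ss)
    names(ref) <- sub("\\s.*$", "", names(ss))
    as.list(ref)
  } else if (is.null(names(reference))) {
    stats::setNames(as.list(reference), rep("chrS", length(reference)))
  } else {
    as.list(reference)
  }
}

#' Summarise breakpoint evidence classes
#'
#' The three-way proportions of evidence classes over a batch of candidates
#' (the pie-chart summary of a validation run): direct break-read evidence,
#' paired-end-only support, and unsupported candidates, plus the combined
#' supported fraction.
#'
#' @param results Output of [seek_breakpoints()].
#' @return A one-row tibble: `n`, `break_read`, `paired_end`, `unsupported`
#'   (proportions in `[0, 1]`) and `supported` (= `break_read + paired_end`).
#' @export
summarize_evidence <- function(results) {
  n <- nrow(results)
  if (n == 0) {
    return(tibble(n = 0L, break_read = NA_real_, paired_end = NA_real_,
                  unsupported = NA_real_, supported = NA_real_))
  }
  tibble(
    n = n,
    break_read = mean(results$evidence == "break_read"),
    paired_end = mean(results$evidence == "paired_end"),
    unsupported = mean(results$evidence == "unsupported"),
    supported = mean(results$evidence != "unsupported")
  )
}
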