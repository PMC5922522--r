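#' Extract per-base read depth from a BAM file
#'
#' Counts, for every base of the queried interval, the aligned reads whose
#' alignment spans that base (CIGAR M/=/X), excluding duplicates, secondary
#' and supplementary alignments and unmapped records, optionally above a
#' mapping-quality threshold. Positions covered by no read are reported with
#' depth 0 so the profile always has exactly `end - start` rows.
#'
#' @param bam_path Path to an indexed BAM file.
#' @param chrom Contig name (must be present in the BAM header).
#' @param start,end Interval in 0-based half-open coordinates.
#' @param min_mapq Minimum mapping quality for a read to count (default 0).
#' @return A tibble of class `depth_profile` with columns `chrom`, `pos`
#'   (0-based) and `depth`.
#' @export
extract_depth <- function(bam_path, chrom, start, end, min_mapq = 0) {
  stopifnot(end > start, start >= 0)
  hdr <- Rsamtools::scanBamHeader(bam_path)[[1]]$targets
  if (!chrom %in% names(hdr)) {
    abort(sprintf("contig '%s' not present in %s", chrom, bam_path))
  }
  if (end > hdr[[chrom]]) {
    abort(sprintf("interval end %g beyond contig '%s' length %d",
                  end, chrom, hdr[[chrom]]))
  }
  which <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE, isDuplicate = FALSE,
    isSecondaryAlignment = FALSE, isSupplementaryAlignment = FALSE
  )
  pu <- Rsamtools::pileup(
    bam_path,
    scanBamParam = Rsamtools::ScanBamParam(which = which, flag = flag),
    pileupParam = Rsamtools::PileupParam(
      max_depth = 250000L, min_base_quality = 0L, min_mapq = as.integer(min_mapq),
      min_nucleotide_depth = 0L, distinguish_strands = FALSE,
      distinguish_nucleotides = FALSE, include_deletions = FALSE,
      include_insertions = FALSE
    )
  )
  depth <- integer(end - start)
  if (nrow(pu) > 0) {
    # pileup reports 1-based positions with nonzero coverage only
    depth[pu$pos - start] <- pu$count
  }
  depth_profile(chrom, start, depth)
}

#' @rdname extract_depth
#' @param depth Integer vector of per-base depths for `[start, start + length(depth))`.
#' @export
depth_profile <- function(chrom, start, depth) {
  out <- tibble(chrom = chrom, pos = start + seq_along(depth) - 1, depth = as.integer(depth))
  class(out) <- c("depth_profile", class(out))
  out
}

# Pull the depth vector of [start, end) out of a whole-chromosome profile.
slice_depth <- function(profile, start, end) {
  first <- profile$pos[1]
  i0 <- start - first + 1
  i1 <- end - first
  if (i0 < 1 || i1 > nrow(profile)) abort("requested slice outside depth profile")
  profile$depth[i0:i1]
}
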