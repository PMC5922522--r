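# Seed hit positions (1-based starts) of `seed` in `window`, allowing one
# mismatch inside the seed.
anchor_hits <- function(seed, window, max_seed_mismatch = 1) {
  m <- Biostrings::matchPattern(seed, window, max.mismatch = max_seed_mismatch,
                                with.indels = FALSE)
  Biostrings::start(m)
}

# Per-base match indicator of a contig laid onto the window with its first
# base at window position p (1-based; p may hang off either edge).
placement_matches <- function(cchars, wchars, p) {
  n <- length(cchars)
  idx <- p + seq_len(n) - 1
  valid <- idx >= 1 & idx <= length(wchars)
  m <- logical(n)
  m[valid] <- cchars[valid] == wchars[idx[valid]]
  m
}

#' Split-align a contig against a local reference window
#'
#' Decomposes a contig into a prefix matching the reference window up to a
#' left breakpoint L and a suffix matching from a right breakpoint R — the
#' split-read signature of a deletion: the donor joins L and R directly, so
#' a contig assembled across the junction maps in two pieces that are far
#' apart on the reference. Anchor placements are found by exact seeding
#' (one mismatch tolerated in a seed, seeds taken at both ends and one
#' k-block inward for robustness to end errors); the split point is then the
#' leftmost maximiser of the total number of matching bases over all
#' decompositions, which reports left-normalized junctions — the same
#' canonical form the simulator uses for planted deletions. Several equally
#' scoring splits (junction microhomology) are flagged `ambiguous`. A
#' contig that maps contiguously yields an implied deletion of length 0 and
#' therefore no call; both orientations are tried.
#'
#' @param contig Contig sequence (character scalar).
#' @param window_seq Reference window sequence the candidate was expanded to.
#' @param window_offset 0-based reference coordinate of the window's first
#'   base.
#' @param min_anchor Minimum aligned bases on each side of the junction
#'   (default 21); the `min_anchor` bases adjacent to the junction must
#'   match with at most one mismatch on each side.
#' @param min_deletion Minimum distance R - L for a junction call (smaller
#'   events are indel noise, default 50).
#' @param max_mismatch_rate Tolerated mismatch fraction per side (assembly
#'   consensus errors; default 0.03, with an absolute floor of 2 bases).
#' @return A one-row tibble (`left_break`, `right_break`, `evidence`,
#'   `ambiguous`) or `NULL`. Breakpoints are 0-based reference coordinates:
#'   `left_break` is the first deleted base, `right_break` the first base
#'   after the deletion.
#' @export
split_align_contig <- function(contig, window_seq, window_offset = 0,
                               min_anchor = 21, min_deletion = 50,
                               max_mismatch_rate = 0.03) {
  n <- nchar(contig)
  if (n < 2 * min_anchor) return(NULL)
  wn <- nchar(window_seq)
  win <- Biostrings::DNAString(window_seq)
  wchars <- strsplit(window_seq, "", fixed = TRUE)[[1]]

  try_orientation <- function(ctg) {
    cchars <- strsplit(ctg, "", fixed = TRUE)[[1]]
    # candidate placements of the contig start implied by left-end seeds
    p_left <- integer(0)
    for (off in unique(c(0L, min_anchor))) {
      if (off + min_anchor > n) break
      seed <- substring(ctg, off + 1, off + min_anchor)
      p_left <- c(p_left, anchor_hits(seed, win) - off)
    }
    p_left <- sort(unique(p_left))
    if (length(p_left) == 0) return(NULL)
    # candidate placements implied by right-end seeds
    p_right <- integer(0)
    for (off in unique(c(0L, min_anchor))) {
      if (off + min_anchor > n) break
      seed <- substring(ctg, n - min_anchor + 1 - off, n - off)
      p_right <- c(p_right, anchor_hits(seed, win) - (n - min_anchor - off))
    }
    p_right <- sort(unique(p_right))
    if (length(p_right) == 0) return(NULL)

    score_of <- function(p) sum(placement_matches(cchars, wchars, p))
    pl <- p_left[which.max(vapply(p_left, score_of, numeric(1)))]
    pr <- p_right[which.max(vapply(p_right, score_of, numeric(1)))]
    if (pr <= pl) return(NULL) # suffix must sit right of the prefix

    mA <- placement_matches(cchars, wchars, pl)
    mB <- placement_matches(cchars, wchars, pr)
    cumA <- cumsum(mA); cumB <- cumsum(mB); totB <- cumB[n]
    cc <- seq(min_anchor, n - min_anchor)
    if (length(cc) == 0) return(NULL)
    score <- cumA[cc] + totB - cumB[cc]
    best <- cc[score == max(score)]
    c_star <- best[1]
    # per-side mismatch tolerance and clean junction-adjacent anchors
    budget <- function(len) max(2, round(max_mismatch_rate * len))
    misA <- c_star - cumA[c_star]
    misB <- (n - c_star) - (totB - cumB[c_star])
    if (misA > budget(c_star) || misB > budget(n - c_star)) return(NULL)
    anchA <- cumA[c_star] - cumA[c_star - min_anchor]
    anchB <- cumB[c_star + min_anchor] - cumB[c_star]
    if (anchA < min_anchor - 1 || anchB < min_anchor - 1) return(NULL)
    left0 <- window_offset + pl + c_star - 1
    right0 <- window_offset + pr + c_star - 1
    if (right0 - left0 < min_deletion) return(NULL)
    tibble(left_break = left0, right_break = right0,
           evidence = "break_read", ambiguous = length(best) > 1)
  }

  for (ctg in c(contig, reverse_complement(contig))) {
    res <- try_orientation(ctg)
    if (!is.null(res)) return(res)
  }
  NULL
}

#' Paired-end insert-size evidence for a candidate deletion
#'
#' Read pairs whose two ends straddle the candidate with an apparent insert
#' far beyond the fragment-length model (more than 3 SDs above the mean) and
#' consistent with a deletion of roughly the candidate's length support the
#' loss even when no break-spanning contig was assembled. Breakpoints are
#' reported at the candidate's own boundaries (imprecise by nature).
#'
#' @param mapped Tibble of mapped reads near the candidate (from
#'   [extract_read_bundle()]), with columns `qname`, `pos`, `end`,
#'   `reverse`, `mate_pos`.
#' @param cand_start,cand_end Candidate interval (0-based half-open).
#' @param insert_mean,insert_sd Fragment-length model (bp).
#' @param read_length Read length used to infer the mate's span.
#' @param min_pairs Minimum supporting pairs (default 2).
#' @return One-row tibble (`left_break`, `right_break`,
#'   `evidence = "paired_end"`, `support_count`) or `NULL`.
#' @export
paired_end_evidence <- function(mapped, cand_start, cand_end,
                                insert_mean = 300, insert_sd = 30,
                                read_length = 100, min_pairs = 2) {
  if (is.null(mapped) || nrow(mapped) == 0) return(NULL)
  cand_len <- cand_end - cand_start
  fwd <- mapped[!mapped$reverse & !is.na(mapped$mate_pos) &
                  mapped$mate_pos > mapped$pos, , drop = FALSE]
  if (nrow(fwd) == 0) return(NULL)
  apparent <- (fwd$mate_pos + read_length) - fwd$pos
  implied <- apparent - insert_mean
  straddle <- fwd$pos < cand_end & (fwd$mate_pos + read_length) > cand_start
  long <- apparent > insert_mean + 3 * insert_sd
  consistent <- abs(implied - cand_len) <= 0.5 * cand_len + 4 * insert_sd
  support <- unique(fwd$qname[straddle & long & consistent])
  if (length(support) < min_pairs) return(NULL)
  tibble(left_break = cand_start, right_break = cand_end,
         evidence = "paired_end", support_count = length(support))
}
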