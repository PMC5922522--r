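#' Specification of a synthetic deletion-validation dataset
#'
#' Bundles every parameter of the simulator. The defaults emulate the data
#' regime the pipeline is designed for: low-coverage (about 4x) paired-end
#' sequencing of a sample carrying scattered deletions, plus an SNP-array
#' probe grid with irregular spacing.
#'
#' @param ref_length Reference contig length in bp.
#' @param n_deletions Number of deletions to plant.
#' @param deletion_length_range Two-element vector, uniform range of deletion
#'   lengths in bp.
#' @param zygosity_mix Fraction of deletions that are homozygous (the rest
#'   are heterozygous, on one random haplotype).
#' @param ploidy 2 for a diploid donor (default), 1 for a haploid donor
#'   (deterministic unit-test mode; all deletions behave as homozygous).
#' @param read_length Read length in bp.
#' @param mean_depth Mean total read depth over non-deleted sequence
#'   (default 4).
#' @param insert_mean,insert_sd Fragment (outer insert) length distribution
#'   in bp.
#' @param error_rate Per-base substitution error probability.
#' @param probe_spacing_mean Mean gap between adjacent array probes in bp
#'   (gaps are exponential, so spacing is irregular).
#' @param unmapped_junction_prob Probability that a read crossing a deletion
#'   junction is emitted as an unmapped record (placed at its mate's
#'   position); otherwise it is soft-clipped at the junction.
#' @param chrom Name of the simulated contig.
#' @param seed RNG seed; every simulator operation is reproducible from it.
#' @return A list of class `sim_spec`.
#' @export
simulation_spec <- function(ref_length = 200000,
                            n_deletions = 10,
                            deletion_length_range = c(500, 5000),
                            zygosity_mix = 0.5,
                            ploidy = 2,
                            read_length = 100,
                            mean_depth = 4,
                            insert_mean = 300,
                            insert_sd = 30,
                            error_rate = 0.001,
                            probe_spacing_mean = 1000,
                            unmapped_junction_prob = 1.0,
                            chrom = "chrS",
                            seed = 1) {
  stopifnot(ref_length > 0, mean_depth > 0, ploidy %in% c(1, 2),
            length(deletion_length_range) == 2,
            deletion_length_range[1] <= deletion_length_range[2],
            deletion_length_range[1] > 0,
            zygosity_mix >= 0, zygosity_mix <= 1,
            insert_mean >= 2 * read_length)
  structure(as.list(environment()), class = "sim_spec")
}

#' Generate a random reference sequence
#'
#' I.i.d. uniform A/C/G/T of the requested length; byte-identical for a
#' fixed seed. Optionally written as an indexed FASTA.
#'
#' @param spec A [simulation_spec()].
#' @param fasta_path Optional path; when given, the sequence is written there
#'   as FASTA and faidx-indexed.
#' @return A list with `seq` (character scalar), `chrom`, and `fasta_path`
#'   (`NULL` unless written).
#' @export
make_reference <- function(spec, fasta_path = NULL) {
  seq <- with_seed(spec$seed, paste(
    sample(c("A", "C", "G", "T"), spec$ref_length, replace = TRUE),
    collapse = ""))
  if (!is.null(fasta_path)) {
    ss <- Biostrings::DNAStringSet(seq)
    names(ss) <- spec$chrom
    Biostrings::writeXStringSet(ss, fasta_path)
    Rsamtools::indexFa(fasta_path)
  }
  list(seq = seq, chrom = spec$chrom, fasta_path = fasta_path)
}

# Left-normalize a deletion [s, e) (0-based): while the base before the
# deletion equals its last base, the junction can shift left one position
# without changing the donor sequence. Reporting the leftmost representation
# makes planted truth comparable with split-alignment junctions, which use
# the same canonical form.
normalize_deletion <- function(chars, s, e) {
  while (s > 0 && chars[s] == chars[e]) {
    s <- s - 1
    e <- e - 1
  }
  c(s, e)
}

#' Plant deletions into a reference and build donor haplotypes
#'
#' Chooses non-overlapping deletions (separated by at least twice the read
#' length plus a margin, and clear of the contig ends), assigns zygosity by
#' `zygosity_mix`, left-normalizes every breakpoint pair, and constructs the
#' donor haplotype sequences with coordinate maps back to the reference.
#'
#' @param reference Result of [make_reference()] (or a character scalar).
#' @param spec A [simulation_spec()].
#' @return A list of class `sim_donor`: `truth` (tibble `chrom`, `start`,
#'   `end`, `zygosity`, `del_id`), `haplotypes` (list of character scalars),
#'   `segment_maps` (per haplotype, tibble of retained reference segments
#'   `ref_start`, `ref_end`, `donor_start`), `ref`, `chrom`.
#' @export
plant_deletions <- function(reference, spec) {
  ref <- if (is.list(reference)) reference$seq else reference
  chars <- strsplit(ref, "", fixed = TRUE)[[1]]
  n <- spec$n_deletions
  edge_buffer <- max(2000, 2 * spec$insert_mean)
  min_gap <- 2 * spec$read_length + 2 * spec$insert_mean
  truth <- with_seed(derive_seed(spec$seed, 1), {
    if (n == 0) {
      tibble(chrom = character(), start = double(), end = double(),
             zygosity = character(), del_id = character())
    } else {
      lens <- round(runif(n, spec$deletion_length_range[1],
                          spec$deletion_length_range[2]))
      total_span <- sum(lens) + (n + 1) * min_gap + 2 * edge_buffer
      if (total_span > spec$ref_length) {
        abort("reference too short for the requested deletions")
      }
      # distribute the free space between deletions uniformly
      free <- spec$ref_length - 2 * edge_buffer - sum(lens) - (n + 1) * min_gap
      cuts <- sort(runif(n + 1)) # dirichlet-ish split of the free space
      gaps <- min_gap + floor(free * (cuts - c(0, head(cuts, -1))))
      starts <- edge_buffer + cumsum(gaps[seq_len(n)]) + c(0, cumsum(head(lens, -1)))
      ends <- starts + lens
      norm <- t(mapply(function(s, e) normalize_deletion(chars, s, e), starts, ends))
      zyg <- ifelse(runif(n) < spec$zygosity_mix, "hom", "het")
      if (spec$ploidy == 1) zyg[] <- "hom"
      tibble(chrom = spec$chrom, start = norm[, 1], end = norm[, 2],
             zygosity = zyg,
             del_id = sprintf("del%03d", seq_len(n)))
    }
  })
  het_hap <- with_seed(derive_seed(spec$seed, 2),
                       sample(1:2, nrow(truth), replace = TRUE))
  n_haps <- spec$ploidy
  haplotypes <- vector("list", n_haps)
  segment_maps <- vector("list", n_haps)
  for (h in seq_len(n_haps)) {
    carried <- truth$zygosity == "hom" | (truth$zygosity == "het" & het_hap == h)
    dels <- truth[carried, , drop = FALSE]
    seg_start <- c(0, dels$end)
    seg_end <- c(dels$start, spec$ref_length)
    keep <- seg_end > seg_start
    seg_start <- seg_start[keep]; seg_end <- seg_end[keep]
    donor_start <- c(0, cumsum(seg_end - seg_start))[seq_along(seg_start)]
    segment_maps[[h]] <- tibble(ref_start = seg_start, ref_end = seg_end,
                                donor_start = donor_start)
    haplotypes[[h]] <- paste(substring(ref, seg_start + 1, seg_end), collapse = "")
  }
  structure(list(truth = truth, haplotypes = haplotypes,
                 segment_maps = segment_maps, ref = ref, chrom = spec$chrom),
            class = "sim_donor")
}

# Add substitution errors to a vector of read sequences.
mutate_reads <- function(seqs, error_rate) {
  if (error_rate <= 0 || length(seqs) == 0) return(seqs)
  rl <- nchar(seqs)
  k <- rbinom(length(seqs), rl, error_rate)
  hit <- which(k > 0)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    pos <- sample.int(rl[i], k[i])
    for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1)
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Simulate paired-end alignments from donor haplotypes
#'
#' Draws fragments with Poisson-distributed starts along each haplotype at
#' the spec's mean depth, adds substitution errors, and derives alignment
#' records directly from the known donor-to-reference coordinate maps (no
#' aligner is run; the records represent an idealised mapping with exact
#' truth labels). Reads falling entirely inside a retained reference segment
#' are emitted as mapped (CIGAR all-M); reads crossing a deletion junction
#' are emitted unmapped at their mate's position with probability
#' `unmapped_junction_prob`, otherwise soft-clipped at the junction. The
#' expected per-base depth is therefore `mean_depth` over null regions,
#' about half over heterozygous deletions and 0 over homozygous ones.
#'
#' @param donor Result of [plant_deletions()].
#' @param spec The [simulation_spec()].
#' @param sample_id Read-group/sample label used in read names.
#' @return A list of class `sim_reads`: `reads` (tibble, one row per read,
#'   with donor and reference coordinates, flags, CIGAR, sequence and truth
#'   labels), `coverage` (integer vector of per-base mapped depth over the
#'   reference), `junction_read_ids` (qnames of junction-crossing reads),
#'   `chrom`, `ref_length`.
#' @export
simulate_alignments <- function(donor, spec, sample_id = "S1") {
  rl <- spec$read_length
  reads_list <- list()
  for (h in seq_along(donor$haplotypes)) {
    hap <- donor$haplotypes[[h]]
    seg <- donor$segment_maps[[h]]
    Lh <- nchar(hap)
    per_hap_depth <- spec$mean_depth / length(donor$haplotypes)
    n_frag <- with_seed(derive_seed(spec$seed, 10 + h),
                        rpois(1, Lh * per_hap_depth / (2 * rl)))
    rows <- with_seed(derive_seed(spec$seed, 20 + h), {
      ins <- pmax(2 * rl, round(rnorm(n_frag, spec$insert_mean, spec$insert_sd)))
      ins <- pmin(ins, Lh)
      fstart <- floor(runif(n_frag, 0, Lh - ins + 1))
      # mate 1 reads the fragment's left end forward, mate 2 its right end
      # reverse; donor coordinates of both reads, interleaved (r1, r2, ...)
      a <- as.double(rbind(fstart, fstart + ins - rl))
      b <- a + rl
      qname <- rep(sprintf("%s_h%d_f%06d", sample_id, h, seq_len(n_frag)),
                   each = 2)
      seg_i <- findInterval(a, seg$donor_start)
      seg_j <- findInterval(b - 1, seg$donor_start)
      within <- seg_i == seg_j
      ref_start <- ifelse(within, seg$ref_start[seg_i] + (a - seg$donor_start[seg_i]),
                          NA_real_)
      seqs <- mutate_reads(substring(hap, a + 1, b), spec$error_rate)
      tibble(
        qname = qname, hap = h, mate = rep(1:2, n_frag),
        donor_start = a, donor_end = b, seq = seqs,
        reverse = rep(c(FALSE, TRUE), n_frag),
        crosses_junction = !within,
        ref_start = ref_start,
        ref_end = ref_start + rl
      )
    })
    reads_list[[h]] <- rows
  }
  reads <- bind_rows(reads_list)

  # junction reads: unmapped (at the mate's position) or soft-clipped
  reads$mapped <- !reads$crosses_junction
  reads$cigar <- ifelse(reads$mapped, paste0(rl, "M"), "*")
  if (nrow(reads) > 0 && spec$unmapped_junction_prob < 1) {
    jidx <- which(reads$crosses_junction)
    softclip <- with_seed(derive_seed(spec$seed, 30),
                          runif(length(jidx)) >= spec$unmapped_junction_prob)
    for (t in seq_along(jidx)) {
      if (!softclip[t]) next
      i <- jidx[t]
      h <- reads$hap[i]
      seg <- donor$segment_maps[[h]]
      a <- reads$donor_start[i]; b <- reads$donor_end[i]
      si <- findInterval(a, seg$donor_start)
      left_len <- (seg$donor_start[si] + (seg$ref_end[si] - seg$ref_start[si])) - a
      if (left_len >= rl - left_len && left_len >= 20) {
        # anchor the left part
        reads$mapped[i] <- TRUE
        reads$cigar[i] <- sprintf("%dM%dS", left_len, rl - left_len)
        reads$ref_start[i] <- seg$ref_start[si] + (a - seg$donor_start[si])
        reads$ref_end[i] <- reads$ref_start[i] + left_len
      } else if (rl - left_len >= 20) {
        sj <- findInterval(b - 1, seg$donor_start)
        right_len <- b - seg$donor_start[sj]
        if (right_len < rl) {
          reads$mapped[i] <- TRUE
          reads$cigar[i] <- sprintf("%dS%dM", rl - right_len, right_len)
          reads$ref_start[i] <- seg$ref_start[sj]
          reads$ref_end[i] <- seg$ref_start[sj] + right_len
        }
      }
    }
  }

  # unmapped reads inherit the mate's coordinate so indexed region queries
  # still find them; fully unmapped pairs sit at the fragment's last known
  # reference position
  # rows are interleaved (mate1, mate2) per fragment: swap within each pair
  swap <- seq_len(nrow(reads)) + ifelse(reads$mate == 1, 1L, -1L)
  reads$mate_mapped <- reads$mapped[swap]
  reads$mate_ref_start <- reads$ref_start[swap]
  reads$mate_reverse <- reads$reverse[swap]
  placeholder <- is.na(reads$ref_start) & !is.na(reads$mate_ref_start)
  reads$pos <- ifelse(reads$mapped, reads$ref_start,
                      ifelse(!is.na(reads$mate_ref_start), reads$mate_ref_start,
                             NA_real_))
  # both mates junction-crossing and unmapped: place the pair at the start of
  # the first crossed segment's end (deterministic, near the junction)
  orphan <- which(is.na(reads$pos))
  if (length(orphan) > 0) {
    for (i in orphan) {
      seg <- donor$segment_maps[[reads$hap[i]]]
      si <- findInterval(reads$donor_start[i], seg$donor_start)
      reads$pos[i] <- seg$ref_end[si] - 1
    }
  }

  n_ref <- nchar(donor$ref)
  cov <- integer(n_ref)
  mapped <- reads[reads$mapped, , drop = FALSE]
  if (nrow(mapped) > 0) {
    d <- tabulate(mapped$ref_start + 1, nbins = n_ref + 1) -
      tabulate(mapped$ref_end + 1, nbins = n_ref + 1)
    cov <- cumsum(d[seq_len(n_ref)])
  }

  structure(list(
    reads = reads,
    coverage = as.integer(cov),
    junction_read_ids = unique(reads$qname[reads$crosses_junction]),
    chrom = donor$chrom,
    ref_length = nchar(donor$ref),
    sample_id = sample_id
  ), class = "sim_reads")
}

#' Write simulated alignments as a sorted, indexed BAM
#'
#' @param sim Result of [simulate_alignments()].
#' @param bam_path Output path (without requiring a `.bam` suffix; the final
#'   BAM lands exactly there, with its `.bai` next to it).
#' @return The BAM path, invisibly.
#' @export
write_sim_bam <- function(sim, bam_path) {
  reads <- sim$reads
  flag <- 1L + # paired
    ifelse(reads$mapped & reads$mate_mapped, 2L, 0L) +
    ifelse(!reads$mapped, 4L, 0L) +
    ifelse(!reads$mate_mapped, 8L, 0L) +
    ifelse(reads$mapped & reads$reverse, 16L, 0L) +
    ifelse(reads$mate_mapped & reads$mate_reverse, 32L, 0L) +
    ifelse(reads$mate == 1, 64L, 128L)
  pos1 <- as.integer(reads$pos) + 1L
  mpos1 <- as.integer(ifelse(is.na(reads$mate_ref_start), reads$pos,
                             reads$mate_ref_start)) + 1L
  tlen <- integer(nrow(reads))
  both <- reads$mapped & reads$mate_mapped
  span <- abs(pmax(reads$ref_end, reads$mate_ref_start + (reads$donor_end - reads$donor_start)) -
                pmin(reads$ref_start, reads$mate_ref_start))
  tlen[both] <- as.integer(ifelse(reads$reverse[both], -span[both], span[both]))
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t=\t%d\t%d\t%s\t*",
                   reads$qname, flag, sim$chrom, pos1,
                   ifelse(reads$mapped, 60L, 0L), reads$cigar,
                   mpos1, tlen, reads$seq)
  sam <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", sim$chrom, sim$ref_length),
               lines), sam)
  tmp_bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                              indexDestination = FALSE)
  Rsamtools::sortBam(tmp_bam, sub("\\.bam$", "", bam_path))
  Rsamtools::indexBam(bam_path)
  unlink(c(sam, tmp_bam))
  invisible(bam_path)
}

#' Simulate an irregular SNP-array probe grid
#'
#' Probe positions accumulate exponential gaps with the given mean, so
#' spacing is irregular as on a real array.
#'
#' @param ref_length Contig length in bp.
#' @param spacing_mean Mean probe gap in bp.
#' @param chrom Contig name.
#' @param seed RNG seed.
#' @return A [probe_map()] tibble.
#' @export
make_probe_grid <- function(ref_length, spacing_mean = 1000, chrom = "chrS",
                            seed = 1) {
  pos <- with_seed(seed, {
    n_max <- ceiling(3 * ref_length / spacing_mean) + 20
    p <- cumsum(rexp(n_max, rate = 1 / spacing_mean))
    floor(p[p < ref_length])
  })
  probe_map(tibble(chrom = chrom, pos = unique(pos)))
}

#' Tile a contig with gene regions
#'
#' An arbitrary regular gene annotation for exercising the gene-region
#' filter: genes of `gene_length` bp separated by `gap` bp.
#'
#' @param ref_length Contig length in bp.
#' @param chrom Contig name.
#' @param gene_length,gap Gene span and intergenic gap in bp.
#' @return Tibble with `chrom`, `start`, `end`.
#' @export
make_gene_regions <- function(ref_length, chrom = "chrS", gene_length = 5000,
                              gap = 10000) {
  starts <- seq(0, ref_length - gene_length, by = gene_length + gap)
  tibble(chrom = chrom, start = starts, end = starts + gene_length)
}

#' Derive discordant callsets from the simulated truth
#'
#' Emulates the disagreement regime of real cross-platform reports: per
#' profile, call boundaries are jittered uniformly, calls are dropped at a
#' missed-call rate, spurious calls are added, and calls below a minimum
#' size are censored (mimicking an array's inability to see small losses).
#'
#' @param truth Truth deletion tibble (from [plant_deletions()]).
#' @param profiles Named list of profiles, each a list with `jitter_bp`,
#'   `drop_rate`, `spurious_rate` (expected spurious calls as a fraction of
#'   true calls) and `min_size`.
#' @param ref_length Contig length (for placing spurious calls).
#' @param sample_id Sample id stamped on all calls.
#' @param seed RNG seed.
#' @return A named list of [cnv_callset()]s, one per profile, with
#'   `assembly_tag = "sim"`.
#' @export
jitter_callsets <- function(truth, profiles, ref_length, sample_id = "S1",
                            seed = 1) {
  out <- vector("list", length(profiles))
  names(out) <- names(profiles)
  for (pi in seq_along(profiles)) {
    p <- profiles[[pi]]
    calls <- with_seed(derive_seed(seed, 100 + pi), {
      n <- nrow(truth)
      if (n > 0) {
        js <- round(runif(n, -p$jitter_bp, p$jitter_bp))
        je <- round(runif(n, -p$jitter_bp, p$jitter_bp))
        start <- pmax(0, truth$start + js)
        end <- pmin(ref_length, truth$end + je)
        keep <- runif(n) >= p$drop_rate
        keep <- keep & (end - start >= max(1, p$min_size))
        base <- tibble(chrom = truth$chrom, start = start, end = end)[keep, ]
      } else {
        base <- tibble(chrom = character(), start = double(), end = double())
      }
      n_spur <- rpois(1, p$spurious_rate * max(1, nrow(truth)))
      if (n_spur > 0) {
        lens <- if (nrow(truth) > 0) {
          sample(pmax(truth$end - truth$start, p$min_size), n_spur, replace = TRUE)
        } else {
          rep(max(1000, p$min_size), n_spur)
        }
        s <- floor(runif(n_spur, 0, ref_length - lens))
        base <- bind_rows(base, tibble(chrom = truth$chrom[1] %||% "chrS",
                                       start = s, end = s + lens))
      }
      base
    })
    calls$sample_id <- rep(sample_id, nrow(calls))
    out[[pi]] <- cnv_callset(calls, source = names(profiles)[pi],
                             assembly_tag = "sim")
  }
  out
}

#' Simulate a per-base depth profile directly
#'
#' Two generative models for calibration studies of the depth tests:
#' `"iid"` draws per-base depths independently as Poisson(`mean_depth`), the
#' exchangeable null under which a per-base permutation test is exactly
#' calibrated; `"reads"` draws Poisson read starts and accumulates coverage,
#' reproducing the short-range autocorrelation of real read depth.
#'
#' @param n Number of bases.
#' @param mean_depth Mean depth.
#' @param model `"iid"` or `"reads"`.
#' @param read_length Read length for the `"reads"` model.
#' @param seed RNG seed.
#' @return Integer depth vector of length `n`.
#' @export
simulate_depth_profile <- function(n, mean_depth = 4,
                                   model = c("iid", "reads"),
                                   read_length = 100, seed = NULL) {
  model <- match.arg(model)
  with_seed(seed, {
    if (model == "iid") {
      rpois(n, mean_depth)
    } else {
      rate <- mean_depth / read_length
      starts <- rpois(1, rate * (n + read_length))
      s <- floor(runif(starts, -read_length, n))
      d <- integer(n + 1)
      a <- pmax(s, 0) + 1
      b <- pmin(s + read_length, n) + 1
      ok <- b > a
      for (i in which(ok)) {
        d[a[i]] <- d[a[i]] + 1L
        d[b[i]] <- d[b[i]] - 1L
      }
      as.integer(cumsum(d[seq_len(n)]))
    }
  })
}

#' Simulate a complete validation dataset
#'
#' Orchestrates the whole generator: reference, planted deletions, paired-end
#' alignments, probe grid, gene tiling and three discordant callsets. When
#' `dir` is given, writes `ref.fa`(+`.fai`), `reads.bam`(+`.bai`),
#' `truth.bed`, `truth.json`, `probes.bed`, `genes.bed` and one
#' `calls_<profile>.bed` per callset.
#'
#' @param spec A [simulation_spec()].
#' @param dir Optional output directory (created if missing).
#' @param profiles Jitter profiles passed to [jitter_callsets()]; the default
#'   three emulate an array-style, a sequencing-style and a conservative
#'   caller.
#' @param write_bam Write the BAM (requires `dir`); set `FALSE` for purely
#'   in-memory studies.
#' @return A list of class `cnv_simulation` with all intermediate objects and
#'   file paths.
#' @export
simulate_dataset <- function(spec, dir = NULL,
                             profiles = default_jitter_profiles(),
                             write_bam = !is.null(dir)) {
  ref <- make_reference(spec, fasta_path = if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    file.path(dir, "ref.fa")
  } else NULL)
  donor <- plant_deletions(ref, spec)
  sim <- simulate_alignments(donor, spec)
  probes <- make_probe_grid(spec$ref_length, spec$probe_spacing_mean,
                            spec$chrom, seed = derive_seed(spec$seed, 3))
  genes <- make_gene_regions(spec$ref_length, spec$chrom)
  callsets <- jitter_callsets(donor$truth, profiles, spec$ref_length,
                              sample_id = sim$sample_id,
                              seed = derive_seed(spec$seed, 4))
  bam_path <- NULL
  if (write_bam) {
    if (is.null(dir)) abort("write_bam = TRUE requires an output directory")
    bam_path <- file.path(dir, "reads.bam")
    write_sim_bam(sim, bam_path)
  }
  if (!is.null(dir)) {
    truth_cs <- cnv_callset(
      mutate(donor$truth, sample_id = sim$sample_id, copy_state = .data$zygosity),
      source = "truth", assembly_tag = "sim")
    write_bed_callset(truth_cs, file.path(dir, "truth.bed"))
    jsonlite::write_json(donor$truth, file.path(dir, "truth.json"))
    writeLines(sprintf("%s\t%d", probes$chrom, as.integer(probes$pos)),
               file.path(dir, "probes.bed"))
    writeLines(sprintf("%s\t%d\t%d", genes$chrom, as.integer(genes$start),
                       as.integer(genes$end)), file.path(dir, "genes.bed"))
    for (nm in names(callsets)) {
      write_bed_callset(callsets[[nm]], file.path(dir, paste0("calls_", nm, ".bed")))
    }
  }
  structure(list(
    spec = spec, ref = ref, donor = donor, truth = donor$truth,
    reads = sim, coverage = sim$coverage, probes = probes, genes = genes,
    callsets = callsets, bam_path = bam_path, dir = dir
  ), class = "cnv_simulation")
}

#' @rdname simulate_dataset
#' @export
default_jitter_profiles <- function() {
  list(
    array = list(jitter_bp = 300, drop_rate = 0.15, spurious_rate = 0.15,
                 min_size = 800),
    seqc = list(jitter_bp = 100, drop_rate = 0.10, spurious_rate = 0.10,
                min_size = 200),
    strict = list(jitter_bp = 50, drop_rate = 0.30, spurious_rate = 0.02,
                  min_size = 500)
  )
}
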