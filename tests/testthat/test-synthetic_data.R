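test_that("reference generation is seed-stable with balanced composition", {
  spec <- simulation_spec(ref_length = 10, seed = 5, n_deletions = 0)
  expect_equal(nchar(make_reference(spec)$seq), 10)
  expect_identical(make_reference(spec)$seq, make_reference(spec)$seq)
  big <- make_reference(simulation_spec(ref_length = 100000, seed = 6,
                                        n_deletions = 0))$seq
  gc <- sum(strsplit(big, "")[[1]] %in% c("G", "C")) / 100000
  expect_lt(abs(gc - 0.5), 3 * sqrt(0.25 / 100000))
})

test_that("planting deletions shortens the right haplotypes by the right amount", {
  spec0 <- simulation_spec(ref_length = 50000, n_deletions = 0, seed = 1)
  d0 <- plant_deletions(make_reference(spec0), spec0)
  expect_identical(d0$haplotypes[[1]], d0$ref)
  expect_identical(d0$haplotypes[[2]], d0$ref)

  spec <- simulation_spec(ref_length = 50000, n_deletions = 3,
                          deletion_length_range = c(800, 1500),
                          zygosity_mix = 1, seed = 2)
  d <- plant_deletions(make_reference(spec), spec)
  tot <- sum(d$truth$end - d$truth$start)
  expect_equal(nchar(d$haplotypes[[1]]), 50000 - tot)
  expect_equal(nchar(d$haplotypes[[2]]), 50000 - tot)

  het <- simulation_spec(ref_length = 50000, n_deletions = 3,
                         deletion_length_range = c(800, 1500),
                         zygosity_mix = 0, seed = 3)
  dh <- plant_deletions(make_reference(het), het)
  tot_het <- sum(dh$truth$end - dh$truth$start)
  expect_equal(nchar(dh$haplotypes[[1]]) + nchar(dh$haplotypes[[2]]),
               2 * 50000 - tot_het)
})

test_that("planted junctions are left-normalized and realign by string search", {
  spec <- simulation_spec(ref_length = 80000, n_deletions = 5,
                          zygosity_mix = 1, seed = 4)
  d <- plant_deletions(make_reference(spec), spec)
  chars <- strsplit(d$ref, "")[[1]]
  for (i in seq_len(nrow(d$truth))) {
    s <- d$truth$start[i]; e <- d$truth$end[i]
    # leftmost representation: the base before the deletion differs from its
    # last base
    expect_true(s == 0 || chars[s] != chars[e])
    # the 40-mer across the junction occurs in the donor haplotype exactly
    junc <- paste0(substring(d$ref, s - 19, s), substring(d$ref, e + 1, e + 20))
    expect_true(grepl(junc, d$haplotypes[[1]], fixed = TRUE))
  }
})

test_that("simulated coverage tracks the expected depth per zygosity class", {
  spec <- simulation_spec(ref_length = 120000, n_deletions = 6,
                          deletion_length_range = c(2000, 4000),
                          zygosity_mix = 0.5, mean_depth = 4,
                          error_rate = 0, seed = 8)
  donor <- plant_deletions(make_reference(spec), spec)
  sim <- simulate_alignments(donor, spec)
  cov <- sim$coverage
  in_del <- rep(FALSE, length(cov))
  for (i in seq_len(nrow(donor$truth))) {
    idx <- (donor$truth$start[i] + 1):donor$truth$end[i]
    zyg <- donor$truth$zygosity[i]
    if (zyg == "hom") {
      expect_equal(max(cov[idx]), 0)
    } else {
      expect_lt(abs(mean(cov[idx]) - 2) / 2, 0.35)
    }
    in_del[idx] <- TRUE
  }
  null_mean <- mean(cov[!in_del][5000:20000])
  expect_lt(abs(null_mean - 4) / 4, 0.1)
})

test_that("junction-crossing reads carry both flank 20-mers when centred", {
  spec <- simulation_spec(ref_length = 60000, n_deletions = 2,
                          deletion_length_range = c(1000, 2000),
                          zygosity_mix = 1, mean_depth = 10,
                          error_rate = 0, seed = 9)
  donor <- plant_deletions(make_reference(spec), spec)
  sim <- simulate_alignments(donor, spec)
  jr <- sim$reads[sim$reads$crosses_junction, ]
  expect_gt(nrow(jr), 0)
  hap <- donor$haplotypes[[1]]
  seg <- donor$segment_maps[[1]]
  # junction positions in donor coordinates = segment boundaries
  junc_donor <- seg$donor_start[-1]
  checked <- 0
  for (i in seq_len(nrow(jr))) {
    j <- junc_donor[junc_donor > jr$donor_start[i] + 20 &
                      junc_donor < jr$donor_end[i] - 20]
    if (length(j) == 0) next
    left20 <- substring(hap, j[1] - 19, j[1])
    right20 <- substring(hap, j[1] + 1, j[1] + 20)
    expect_true(grepl(left20, jr$seq[i], fixed = TRUE))
    expect_true(grepl(right20, jr$seq[i], fixed = TRUE))
    checked <- checked + 1
  }
  expect_gt(checked, 0)
})

test_that("probe grids are sorted, seed-stable, with the expected density", {
  p1 <- make_probe_grid(100000, 1000, seed = 10)
  p2 <- make_probe_grid(100000, 1000, seed = 10)
  expect_identical(p1, p2)
  expect_true(all(diff(p1$pos) > 0))
  expect_lt(abs(nrow(p1) - 100), 30)
})

test_that("jittered callsets respond to their noise profiles", {
  truth <- tibble::tibble(chrom = "chrS", start = c(10000, 30000, 50000),
                          end = c(12000, 33000, 51000),
                          zygosity = "hom", del_id = c("d1", "d2", "d3"))
  clean <- jitter_callsets(truth, list(p = list(jitter_bp = 0, drop_rate = 0,
                                                spurious_rate = 0, min_size = 1)),
                           70000, seed = 11)$p
  expect_equal(clean$start, truth$start)
  expect_equal(clean$end, truth$end)
  dropped <- jitter_callsets(truth, list(p = list(jitter_bp = 0, drop_rate = 1,
                                                  spurious_rate = 0, min_size = 1)),
                             70000, seed = 11)$p
  expect_equal(nrow(dropped), 0)
  # moderate jitter on 2 kb calls keeps 50% concordance with the truth
  jit <- jitter_callsets(truth, list(p = list(jitter_bp = 200, drop_rate = 0,
                                              spurious_rate = 0, min_size = 1)),
                         70000, seed = 12)$p
  truth_cs <- cnv_callset(dplyr::mutate(truth, sample_id = "S1"),
                          source = "truth", assembly_tag = "sim")
  expect_true(all(cnv_matches(truth_cs, jit)))
})

test_that("simulated datasets write the full file bundle", {
  dir <- withr::local_tempdir()
  spec <- simulation_spec(ref_length = 30000, n_deletions = 2,
                          zygosity_mix = 1, mean_depth = 4, seed = 13)
  sim <- simulate_dataset(spec, dir = dir)
  expect_true(all(file.exists(file.path(dir, c(
    "ref.fa", "ref.fa.fai", "reads.bam", "reads.bam.bai", "truth.bed",
    "truth.json", "probes.bed", "genes.bed",
    "calls_array.bed", "calls_seqc.bed", "calls_strict.bed")))))
  reread <- read_bed_callset(file.path(dir, "calls_array.bed"), "array",
                             assembly_tag = "sim")
  expect_equal(nrow(reread), nrow(sim$callsets$array))
})
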