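test_that("BED reader applies the declared coordinate dialect", {
  f <- withr::local_tempfile()
  writeLines(c("chr11\t1000\t2000\tNA12878",
               "chr11\t500\t800\tNA12878"), f)
  one <- read_bed_callset(f, "hapmap", dialect = "one_based")
  expect_equal(one$start, c(499, 999))
  expect_equal(one$end, c(800, 2000))
  expect_equal(one$sample_id, c("NA12878", "NA12878"))
  bed <- read_bed_callset(f, "hapmap", dialect = "bed")
  expect_equal(bed$start, c(500, 1000))
})

test_that("BED reader keeps overlapping rows, handles empty files, and flags bad rows", {
  f <- withr::local_tempfile()
  writeLines(c("c\t100\t900\ts1", "c\t100\t500\ts1"), f)
  cs <- read_bed_callset(f, "x")
  expect_equal(nrow(cs), 2) # the reader never merges
  writeLines(character(0), f)
  expect_equal(nrow(read_bed_callset(f, "x")), 0)
  writeLines(c("c\t100\t900\ts1", "c\txx\t500\ts1"), f)
  expect_error(read_bed_callset(f, "x"), "line 2")
  writeLines("c\t100", f)
  expect_error(read_bed_callset(f, "x"), "fewer than 3")
  writeLines("c\t500\t500", f)
  expect_error(read_bed_callset(f, "x"), "end <= start")
})

test_that("BED round trip is textually stable under a fixed dialect", {
  f <- withr::local_tempfile(); g <- withr::local_tempfile()
  writeLines(c("c\t100\t900\ts1", "c\t1000\t2500\ts2"), f)
  cs <- read_bed_callset(f, "x", dialect = "bed")
  write_bed_callset(cs, g, dialect = "bed")
  expect_identical(readLines(f), readLines(g))
})

test_that("callset construction validates coordinates and sorts", {
  cs <- cnv_callset(data.frame(chrom = "c", start = c(500, 10), end = c(900, 20)),
                    source = "x")
  expect_equal(cs$start, c(10, 500))
  expect_error(cnv_callset(data.frame(chrom = "c", start = 5, end = 5)),
               "end <= start")
  expect_error(concordance_table(
    cnv_callset(data.frame(chrom = "c", start = 1, end = 2), assembly_tag = "hg18"),
    cnv_callset(data.frame(chrom = "c", start = 1, end = 2), assembly_tag = "hg19")
  ), "different assemblies")
})

test_that("VCF loss extraction keeps only CN0/DEL carriers with resolvable spans", {
  f <- write_toy_vcf(withr::local_tempfile())
  expect_warning(cs <- read_vcf_losses(f), "no resolvable END")
  expect_true(all(cs$cnv_type == "loss"))
  # <CN2>-only record excluded; multiallelic <CN0>,<CN2> included once, for
  # the carrier of allele 1 only (NA2 carries allele 2 = <CN2>)
  expect_equal(nrow(cs), 3)
  expect_equal(cs$start, c(5000, 10000, 20000))
  expect_equal(cs$end - cs$start, c(3000, 2000, 1000))
  expect_equal(cs$sample_id, c("NA1", "NA1", "NA1"))
  expect_equal(cs$copy_state, c("het", "het", "hom"))
})

test_that("probe and gene readers sort, dedupe and validate", {
  f <- withr::local_tempfile()
  writeLines(c("chr11\t30", "chr11\t10", "chr11\t20", "chr11\t10"), f)
  pm <- read_probe_map(f)
  expect_equal(pm$pos, c(10, 20, 30))
  calls <- cnv_callset(data.frame(chrom = "chr11", start = 5, end = 35), "x")
  expect_equal(count_probes(calls, pm), 3)
  # half-open rule: probe at start counts, probe at end does not
  edge <- cnv_callset(data.frame(chrom = "chr11", start = c(10, 25), end = c(20, 30)), "x")
  expect_equal(count_probes(edge, pm), c(1, 0))
  writeLines("chr11\tzz", f)
  expect_error(read_probe_map(f), "non-numeric")
  writeLines(c("c\t100\t200", "c\t50\t80", "c\t100\t200"), f)
  gr <- read_gene_regions(f)
  expect_equal(nrow(gr), 2)
  expect_equal(gr$start, c(50, 100))
})

test_that("depth extraction matches the simulator's truth coverage base-wise", {
  sim <- fixture_sim()
  d <- extract_depth(sim$bam_path, "chrS", 0, sim$spec$ref_length)
  expect_equal(nrow(d), sim$spec$ref_length)
  expect_identical(d$depth, sim$coverage)
  # mean depth near nominal over a null stretch
  null_mean <- mean(d$depth[1:8000])
  expect_lt(abs(null_mean - sim$spec$mean_depth) / sim$spec$mean_depth, 0.2)
  # all zeros over a homozygous deletion
  tr <- sim$truth[1, ]
  expect_true(all(d$depth[(tr$start + 1):tr$end] == 0))
})

test_that("depth over adjacent intervals equals depth over their union", {
  sim <- fixture_sim()
  a <- extract_depth(sim$bam_path, "chrS", 5000, 6000)
  b <- extract_depth(sim$bam_path, "chrS", 6000, 7000)
  u <- extract_depth(sim$bam_path, "chrS", 5000, 7000)
  expect_identical(c(a$depth, b$depth), u$depth)
})

test_that("depth extraction rejects unknown contigs and out-of-range intervals", {
  sim <- fixture_sim()
  expect_error(extract_depth(sim$bam_path, "chrZ", 0, 100), "not present")
  expect_error(extract_depth(sim$bam_path, "chrS", 0, sim$spec$ref_length + 1),
               "beyond contig")
})
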