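# Shared fixtures, built lazily once per test run.
.fixtures <- new.env(parent = emptyenv())

# A small error-free 10x simulation with homozygous deletions and a BAM on
# disk; several test files reuse it.
fixture_sim <- function() {
  if (is.null(.fixtures$sim)) {
    spec <- simulation_spec(ref_length = 60000, n_deletions = 4,
                            deletion_length_range = c(500, 2000),
                            zygosity_mix = 1, mean_depth = 10,
                            error_rate = 0, seed = 7)
    .fixtures$sim <- simulate_dataset(spec, dir = tempfile("simfix"))
  }
  .fixtures$sim
}

ref_named <- function(sim) stats::setNames(list(sim$ref$seq), sim$spec$chrom)

random_callset <- function(n, chrom = "c", max_pos = 100000, min_len = 50,
                           max_len = 3000, source = "x", samples = "s1") {
  start <- floor(runif(n, 0, max_pos - max_len))
  len <- floor(runif(n, min_len, max_len))
  cnv_callset(tibble::tibble(chrom = chrom, start = start, end = start + len,
                             sample_id = sample(samples, n, replace = TRUE)),
              source = source)
}

# Quadratic brute-force directional matcher: the independent oracle for the
# 50% rule (single best partner, within-sample with sites-only wildcard).
brute_matches <- function(a, b, threshold = 0.5) {
  out <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    best <- 0
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      if (a$sample_id[i] != "*" && b$sample_id[j] != "*" &&
          a$sample_id[i] != b$sample_id[j]) next
      ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
      if (ov > best) best <- ov
    }
    out[i] <- best >= threshold * (a$end[i] - a$start[i])
  }
  out
}

# Exhaustive permutation p-value computed independently of the package:
# enumerate all subsets of size L from the pooled 2L values.
oracle_exhaustive_p <- function(region, background) {
  pool <- c(region, background)
  L <- length(region)
  mu <- mean(region)
  sigma <- apply(utils::combn(length(pool), L), 2, function(ix) mean(pool[ix]))
  (1 + sum(sigma <= mu)) / (length(sigma) + 1)
}

write_toy_vcf <- function(path, extra_records = character()) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tNA1\tNA2",
    "chr11\t5000\t.\tN\t<DEL>\t.\tPASS\tEND=8000\tGT\t0|1\t0|0",
    "chr11\t9000\t.\tN\t<CN2>\t.\tPASS\tEND=9500\tGT\t0|1\t1|1",
    "chr11\t10000\t.\tN\t<CN0>,<CN2>\t.\tPASS\tEND=12000\tGT\t0|1\t0|2",
    "chr11\t20000\t.\tN\t<DEL>\t.\tPASS\tEND=21000\tGT\t1|1\t.|.",
    "chr11\t30000\t.\tN\t<DEL>\t.\tPASS\t.\tGT\t0|1\t0|0",
    extra_records
  ), path)
  path
}
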