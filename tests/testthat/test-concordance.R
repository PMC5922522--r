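iv <- function(chrom, start, end, sample = "s1") {
  tibble::tibble(chrom = chrom, start = start, end = end, sample_id = sample)
}

test_that("overlap_bp follows the half-open convention", {
  expect_equal(overlap_bp(iv("c", 0, 100), iv("c", 50, 150)), 50)
  expect_equal(overlap_bp(iv("c", 0, 100), iv("c", 100, 200)), 0) # abutting
  expect_equal(overlap_bp(iv("c", 0, 100), iv("c", 500, 600)), 0)
  expect_equal(overlap_bp(iv("c", 0, 1000), iv("c", 200, 300)), 100) # contained
  expect_equal(overlap_bp(iv("c1", 0, 100), iv("c2", 0, 100)), 0)
})

test_that("the 50% rule is directional and single-partner", {
  q <- cnv_callset(iv("c", 0, 1000), "q")
  # best partner covering 499 bp fails, 500 bp passes
  expect_false(cnv_matches(q, cnv_callset(iv("c", 501, 1200), "p")))
  expect_true(cnv_matches(q, cnv_callset(iv("c", 500, 1200), "p")))
  expect_true(cnv_matches(q, cnv_callset(iv("c", 0, 1000), "p"))) # identical
  # 30% + 30% by two disjoint partners must NOT add up
  two <- cnv_callset(iv("c", c(0, 500), c(300, 800)), "p")
  expect_false(cnv_matches(q, two))
  # brute-force check over partner subsets confirms single-partner semantics
  expect_equal(cnv_matches(q, two), brute_matches(q, two))
  # matching is within-sample; sites-only "*" is a wildcard
  other <- cnv_callset(iv("c", 0, 1000, sample = "s2"), "p")
  expect_false(cnv_matches(q, other))
  sites <- cnv_callset(iv("c", 0, 1000, sample = "*"), "p")
  expect_true(cnv_matches(q, sites))
})

test_that("matching is invariant to partner order and to harmless splitting", {
  set.seed(42)
  a <- random_callset(50)
  b <- random_callset(80)
  shuffled <- keep <- b[sample(nrow(b)), ]
  shuffled <- cnv_callset(shuffled, source = "x")
  expect_equal(cnv_matches(a, b), cnv_matches(a, shuffled))
})

test_that("probe filter keeps calls with at least the minimum probe count", {
  probes <- probe_map(tibble::tibble(chrom = "c", pos = seq(0, 10000, by = 100)))
  calls <- cnv_callset(iv("c", c(0, 0, 5000), c(350, 401, 5500)), "x")
  kept <- probe_count_filter(calls, probes, min_probes = 5)
  # spans 0..350 -> probes 0,100,200,300 = 4 -> removed; 0..401 -> 5 kept
  expect_equal(kept$end, c(401, 5500))
  # random grid + random calls vs O(n*m) scan
  set.seed(7)
  grid <- probe_map(tibble::tibble(chrom = "c", pos = sort(sample(0:50000, 500))))
  rnd <- random_callset(100, max_pos = 50000)
  counts <- count_probes(rnd, grid)
  oracle <- vapply(seq_len(nrow(rnd)), function(i) {
    sum(grid$pos >= rnd$start[i] & grid$pos < rnd$end[i])
  }, numeric(1))
  expect_equal(counts, oracle)
})

test_that("gene filter requires a shared base, not mere adjacency", {
  genes <- tibble::tibble(chrom = "c", start = c(1000, 5000), end = c(2000, 6000))
  calls <- cnv_callset(iv("c", c(1999, 2000, 800), c(2500, 2600, 1001)), "x")
  kept <- gene_region_filter(calls, genes)
  expect_equal(kept$start, c(800, 1999)) # abutting call at 2000 removed
  set.seed(8)
  rnd <- random_callset(150, max_pos = 50000)
  g2 <- tibble::tibble(chrom = "c",
                       start = sort(sample(0:48000, 30)))
  g2$end <- g2$start + sample(200:3000, 30, replace = TRUE)
  kept2 <- gene_region_filter(rnd, g2)
  oracle <- vapply(seq_len(nrow(rnd)), function(i) {
    any(g2$start < rnd$end[i] & g2$end > rnd$start[i])
  }, logical(1))
  expect_equal(nrow(kept2), sum(oracle))
  expect_equal(sort(kept2$start), sort(rnd$start[oracle]))
})

test_that("concordance tables count per direction with rounded percentages", {
  a <- cnv_callset(iv("c", c(0, 5000), c(1000, 6000)), "A")
  self <- concordance_table(a, cnv_callset(iv("c", c(0, 5000), c(1000, 6000)), "B"))
  expect_equal(self$a_pct, 100)
  expect_equal(self$b_pct, 100)
  disj <- concordance_table(a, cnv_callset(iv("c", 20000, 21000), "B"))
  expect_equal(disj$a_overlapped, 0)
  expect_equal(disj$b_overlapped, 0)
  # construction is symmetric: swapping arguments swaps the two directions
  set.seed(9)
  x <- random_callset(60, source = "A")
  y <- random_callset(60, source = "B")
  xy <- concordance_table(x, y)
  yx <- concordance_table(y, x)
  expect_equal(xy$a_overlapped, yx$b_overlapped)
  expect_equal(xy$b_overlapped, yx$a_overlapped)
})

test_that("concordance counts agree exactly with a quadratic brute force", {
  set.seed(10)
  a <- random_callset(200, samples = c("s1", "s2"))
  b <- random_callset(200, samples = c("s1", "s2"))
  tab <- concordance_table(a, b)
  expect_equal(tab$a_overlapped, sum(brute_matches(a, b)))
  expect_equal(tab$b_overlapped, sum(brute_matches(b, a)))
})

test_that("overlap-length statistics summarise best-partner pairs", {
  a <- cnv_callset(iv("c", 1000, 3000), "A")
  b <- cnv_callset(iv("c", 1000, 3000), "B")
  st <- overlap_length_stats(a, b)
  expect_equal(st$mean_overlap_bp, 2000)
  expect_equal(st$mode_overlap_bp, 2000)
  expect_equal(st$ratio_to_length, 1)
  none <- overlap_length_stats(a, cnv_callset(iv("c", 9000, 9500), "B"))
  expect_equal(nrow(none$pairs), 0)
  expect_true(is.na(none$mean_overlap_bp))
  set.seed(11)
  x <- random_callset(80); y <- random_callset(80)
  st2 <- overlap_length_stats(x, y)
  # oracle: per matched call, the single largest overlap
  oracle <- c()
  for (i in seq_len(nrow(x))) {
    ovs <- pmax(0, pmin(x$end[i], y$end) - pmax(x$start[i], y$start))
    if (max(ovs) >= 0.5 * (x$end[i] - x$start[i])) oracle <- c(oracle, max(ovs))
  }
  expect_equal(sort(st2$pairs$overlap_bp), sort(oracle))
  expect_equal(st2$mean_overlap_bp, mean(oracle))
  expect_true(all(st2$ratio_to_length > 0 & st2$ratio_to_length <= 1))
})
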