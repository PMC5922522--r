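test_that("background sampling is reproducible and honours exclusions", {
  depth <- rep(1:10, 100) # 1000 bases
  b1 <- sample_background(depth, 50, seed = 3)
  b2 <- sample_background(depth, 50, seed = 3)
  expect_identical(b1, b2)
  excl <- data.frame(start = c(0, 600), end = c(400, 1000))
  for (i in 1:200) {
    s <- attr(sample_background(depth, 50, exclusions = excl, seed = i), "start")
    expect_true(s >= 400 && s + 50 <= 600)
  }
  # region spanning all but one base leaves no room
  expect_error(sample_background(depth, 999,
                                 exclusions = data.frame(start = 0, end = 999)),
               "no permissible")
  expect_error(sample_background(depth, 2000), "shorter")
})

test_that("exhaustive permutation p matches hand enumeration", {
  t <- permutation_depth_test(c(0, 0), c(2, 2), exhaustive = TRUE)
  # of the C(4,2)=6 subsets exactly one ({0,0}) has mean <= 0 -> (1+1)/7
  expect_equal(t$p_value, 2 / 7)
  expect_equal(t$n_resamples, 6)
})

test_that("permutation p is 1 on total ties and NA on an all-zero window", {
  ties <- permutation_depth_test(rep(3, 12), rep(3, 12), n_resamples = 99, seed = 1)
  expect_equal(ties$p_value, 1)
  expect_equal(ties$status, "ok")
  zero <- permutation_depth_test(rep(0, 12), rep(0, 12), n_resamples = 99, seed = 1)
  expect_equal(zero$status, "NA")
  expect_true(is.na(zero$p_value))
  expect_error(permutation_depth_test(numeric(0), numeric(0)), "zero-length")
  expect_error(permutation_depth_test(1:5, 1:4), "length")
})

test_that("an empty region against deep background attains the minimal p", {
  region <- rep(0, 40)
  background <- rep(5, 40)
  t <- permutation_depth_test(region, background, n_resamples = 999, seed = 2)
  # p = 1/1000 unless a resample drew all 40 zeros from the 80-value pool;
  # that probability is choose(40,40)/choose(80,40) < 1e-22, so never here
  expect_equal(t$p_value, 1 / 1000)
})

test_that("permutation p depends on the background multiset only", {
  set.seed(4)
  region <- rpois(60, 1)
  background <- rpois(60, 4)
  p1 <- permutation_depth_test(region, background, n_resamples = 299, seed = 9)$p_value
  p2 <- permutation_depth_test(region, sample(background), n_resamples = 299,
                               seed = 9)$p_value
  expect_equal(p1, p2)
})

test_that("Monte-Carlo permutation p converges to the exhaustive p", {
  set.seed(5)
  for (rep in 1:10) {
    L <- 6 # pool of 12 values, C(12,6) = 924 distinct resamples
    region <- rpois(L, 2)
    background <- rpois(L, 4)
    pool <- c(region, background)
    if (all(pool == 0)) next
    ex <- permutation_depth_test(region, background, exhaustive = TRUE)$p_value
    expect_equal(ex, oracle_exhaustive_p(region, background))
    R <- 4000
    mc <- permutation_depth_test(region, background, n_resamples = R,
                                 seed = rep)$p_value
    # Monte-Carlo fluctuates around (1 + Rq)/(R + 1) with q the exceedance
    # fraction over the N = C(12,6) distinct resamples; the exhaustive
    # add-one p sits a deterministic offset away
    N <- choose(12, 6)
    q <- (ex * (N + 1) - 1) / N
    offset <- ex - (1 + R * q) / (R + 1)
    tol <- 3 * sqrt(q * (1 - q) / R) + abs(offset) + 2 / R
    expect_lt(abs(mc - ex), tol)
  }
})

test_that("chi-square depth test recovers textbook contingency answers", {
  # perfectly separated 2x2 table: statistic 20 on 1 dof
  t <- chi2_depth_test(rep(0, 10), rep(1, 10))
  expect_equal(t$statistic, 20)
  expect_equal(t$dof, 1L)
  # identical histograms: statistic 0, p = 1
  x <- rep(c(0, 1, 2, 3), 50)
  t2 <- chi2_depth_test(x, x)
  expect_equal(t2$statistic, 0)
  expect_equal(t2$p_value, 1)
  # degenerate all-identical depths: fewer than 2 bins -> NA
  t3 <- chi2_depth_test(rep(2, 50), rep(2, 50))
  expect_equal(t3$status, "NA")
})

test_that("chi-square statistic equals the independently computed formula", {
  set.seed(6)
  for (rep in 1:20) {
    region <- rpois(300, sample(1:5, 1))
    background <- rpois(300, sample(1:5, 1))
    t <- chi2_depth_test(region, background)
    if (t$status != "ok") next
    # rebuild the merged table from the reported bin bounds and hand it to
    # stats::chisq.test as the independent route
    cut_of <- function(v) findInterval(pmin(v, max(t$bins)), c(-1, t$bins) + 0.5)
    tab <- rbind(tabulate(cut_of(region), length(t$bins)),
                 tabulate(cut_of(background), length(t$bins)))
    oracle <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_lt(abs(t$statistic - unname(oracle$statistic)), 1e-10)
    expect_equal(t$dof, unname(oracle$parameter))
    expect_lt(abs(t$p_value - oracle$p.value), 1e-10)
  }
})

test_that("flank tests report both sides and NA at contig edges", {
  set.seed(12)
  prof <- depth_profile("c", 0, simulate_depth_profile(6000, 4, "iid", seed = 1))
  res <- adjacency_tests(prof, 2000, 3000, n_resamples = 199, seed = 2)
  expect_equal(nrow(res), 4)
  expect_setequal(res$side, c("upstream", "downstream"))
  expect_true(all(res$status == "ok"))
  # region at the contig start has no upstream flank
  edge <- adjacency_tests(prof, 0, 1000, n_resamples = 199, seed = 2)
  up <- edge[edge$side == "upstream", ]
  expect_true(all(up$status == "NA"))
  down <- edge[edge$side == "downstream", ]
  expect_true(all(down$status == "ok"))
})

test_that("a planted zero-depth region rejects against positive flanks", {
  d <- simulate_depth_profile(9000, 4, "iid", seed = 3)
  d[4001:5000] <- 0L
  prof <- depth_profile("c", 0, d)
  res <- adjacency_tests(prof, 4000, 5000, n_resamples = 999, seed = 4)
  perm <- res[res$test == "permutation", ]
  expect_equal(perm$p_value, c(1 / 1000, 1 / 1000))
})

test_that("batch summaries tabulate rejection and NA fractions", {
  res <- tibble::tibble(
    test = rep("permutation", 10),
    p_value = c(rep(0.001, 8), 0.5, NA),
    status = c(rep("ok", 9), "NA")
  )
  s <- batch_summary(res)
  expect_equal(s$p_lt_0.01, 8 / 9)
  expect_equal(s$p_lt_0.05, 8 / 9)
  expect_equal(s$na_frac, 0.1)
  all_sig <- tibble::tibble(test = "chi2", p_value = rep(0.001, 5),
                            status = "ok")
  s2 <- batch_summary(all_sig)
  expect_equal(s2$p_lt_0.01, 1)
  expect_equal(s2$p_lt_0.05, 1)
  expect_error(batch_summary(res[0, ]), "no results")
})

test_that("tidiers return one-row summaries", {
  t <- permutation_depth_test(rep(0, 20), rep(4, 20), n_resamples = 99, seed = 1)
  td <- tidy(t)
  expect_equal(nrow(td), 1)
  expect_named(td, c("mu", "p_value", "n_resamples", "status", "exhaustive"))
  c <- chi2_depth_test(rpois(100, 2), rpois(100, 4))
  expect_named(tidy(c), c("statistic", "dof", "p_value", "n_bins", "status"))
})
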