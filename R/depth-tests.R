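#' Sample a background stretch of read depth
#'
#' Draws one contiguous stretch of per-base depths of exactly
#' `region_length` from a whole-chromosome depth vector, uniformly over all
#' permissible start positions. Placements intersecting the tested region or
#' any caller-supplied exclusion interval are forbidden; the tested region
#' itself should always be passed as an exclusion, and excluding all other
#' candidate regions keeps the null sample uncontaminated.
#'
#' @param depth Whole-chromosome per-base depth: an integer vector (position
#'   `i` is chromosome base `i - 1`) or a `depth_profile` tibble.
#' @param region_length Length of the stretch to draw (bases).
#' @param exclusions Data frame of intervals (`start`, `end`, 0-based
#'   half-open, chromosome-local) the stretch must not intersect; `NULL` for
#'   none.
#' @param seed Optional RNG seed for a reproducible placement.
#' @return Numeric depth vector of length `region_length`, with the chosen
#'   0-based start position in attribute `"start"`.
#' @export
sample_background <- function(depth, region_length, exclusions = NULL, seed = NULL) {
  if (inherits(depth, "data.frame")) depth <- depth$depth
  n <- length(depth)
  if (region_length < 1) abort("region_length must be positive")
  if (n < region_length) abort("chromosome shorter than requested background stretch")
  allowed <- rep(TRUE, n - region_length + 1) # start positions 0..n-L
  if (!is.null(exclusions) && nrow(exclusions) > 0) {
    for (i in seq_len(nrow(exclusions))) {
      lo <- max(0, exclusions$start[i] - region_length + 1)
      hi <- min(n - region_length, exclusions$end[i] - 1)
      if (hi >= lo) allowed[(lo:hi) + 1] <- FALSE
    }
  }
  starts <- which(allowed) - 1L
  if (length(starts) == 0) abort("no permissible background placement")
  s <- with_seed(seed, starts[sample.int(length(starts), 1L)])
  out <- depth[(s + 1):(s + region_length)]
  attr(out, "start") <- s
  out
}

#' Permutation test for depressed read depth in a candidate region
#'
#' Tests the one-sided null hypothesis that the candidate region's mean read
#' depth is at least that of normal background (H0: mu >= sigma). The region
#' depths and an equally long background stretch are pooled; each resample
#' draws `region_length` values from the pool without replacement and records
#' its mean; the p-value is the add-one permutation p,
#' `p = (1 + #\{sigma_i <= mu\}) / (R + 1)`. A small p is evidence that the
#' region's depth is genuinely low (a real loss); p = 1 arises when the
#' region's depth is at least as high as every resample and flags a
#' relatively high-depth region instead.
#'
#' With `exhaustive = TRUE` (pool sizes small enough to enumerate), all
#' `choose(2L, L)` distinct resamples are used instead of random draws, with
#' the same add-one formula.
#'
#' The result has status `"NA"` when every pooled value is 0 — zero depth
#' across the whole tested window carries no resampling information (the
#' situation flank tests hit when an entire window lies in a dropout).
#'
#' @param region Per-base depths of the candidate region (numeric vector or
#'   `depth_profile` tibble).
#' @param background Background depth vector of the same length (see
#'   [sample_background()]).
#' @param n_resamples Number of resamples R (default 999).
#' @param seed Optional RNG seed.
#' @param exhaustive Enumerate all resamples instead of sampling (requires
#'   `choose(2L, L) <= 2e5`).
#' @return An object of class `cnv_perm_test`: a list with `mu` (region mean
#'   depth), `sigma_samples` (resampled means), `p_value`, `n_resamples`,
#'   `status` (`"ok"` or `"NA"`) and `exhaustive`.
#' @export
permutation_depth_test <- function(region, background, n_resamples = 999,
                                   seed = NULL, exhaustive = FALSE) {
  if (inherits(region, "data.frame")) region <- region$depth
  if (inherits(background, "data.frame")) background <- background$depth
  L <- length(region)
  if (L == 0) abort("zero-length region")
  if (length(background) != L) abort("background must have the region's length")
  if (n_resamples < 1) abort("n_resamples must be >= 1")
  mu <- mean(region)
  pool <- c(region, background)
  res <- structure(
    list(mu = mu, sigma_samples = double(0), p_value = NA_real_,
         n_resamples = 0L, status = "NA", exhaustive = exhaustive),
    class = "cnv_perm_test")
  if (all(pool == 0)) return(res)
  if (exhaustive) {
    if (choose(2 * L, L) > 2e5) abort("pool too large to enumerate exhaustively")
    idx <- utils::combn(2L * L, L)
    sigma <- colSums(matrix(pool[idx], nrow = L)) / L
  } else {
    sigma <- with_seed(seed, vapply(
      seq_len(n_resamples),
      function(i) mean(pool[sample.int(2L * L, L)]),
      numeric(1)
    ))
  }
  res$sigma_samples <- sigma
  res$n_resamples <- length(sigma)
  res$p_value <- (1 + sum(sigma <= mu)) / (length(sigma) + 1)
  res$status <- "ok"
  res
}

#' Two-sample chi-square test on binned read depths
#'
#' Tests the null hypothesis that the region and background per-base depths
#' follow the same discrete distribution (H0: F = G). Depths are histogrammed
#' over shared integer bins `0..d_cap`, where `d_cap` is the 99th percentile
#' of the pooled depths (higher values are capped into the top bin); adjacent
#' bins are merged until every expected count is at least 5; the statistic is
#' the usual sum of `(O - E)^2 / E` over the 2-by-B contingency table with
#' expectations from the pooled marginals, on `B - 1` degrees of freedom.
#'
#' @inheritParams permutation_depth_test
#' @param background Background depth vector (need not match the region's
#'   length for this test).
#' @return An object of class `cnv_chi2_test`: list with `statistic`, `dof`,
#'   `p_value`, `bins` (upper depth bound of each merged bin) and `status`
#'   (`"NA"` when fewer than 2 bins survive merging).
#' @export
chi2_depth_test <- function(region, background) {
  if (inherits(region, "data.frame")) region <- region$depth
  if (inherits(background, "data.frame")) background <- background$depth
  if (length(region) == 0 || length(background) == 0) abort("empty depth vector")
  pool <- c(region, background)
  d_cap <- max(1, ceiling(quantile(pool, 0.99, names = FALSE)))
  bin_of <- function(x) pmin(x, d_cap) # depth value -> bin id 0..d_cap
  levs <- 0:d_cap
  o1 <- tabulate(bin_of(region) + 1L, nbins = d_cap + 1L)
  o2 <- tabulate(bin_of(background) + 1L, nbins = d_cap + 1L)
  upper <- levs
  # merge adjacent bins until all expected counts reach 5
  repeat {
    B <- length(o1)
    if (B < 2) break
    tot <- o1 + o2
    n <- sum(tot)
    e1 <- tot * sum(o1) / n
    e2 <- tot * sum(o2) / n
    if (min(c(e1, e2)) >= 5) break
    j <- which.min(tot)
    nb <- if (j == 1) 2L else if (j == B) B - 1L else if (tot[j - 1] <= tot[j + 1]) j - 1L else j + 1L
    lo <- min(j, nb); hi <- max(j, nb)
    o1 <- c(o1[seq_len(lo - 1)], o1[lo] + o1[hi], o1[-seq_len(hi)])
    o2 <- c(o2[seq_len(lo - 1)], o2[lo] + o2[hi], o2[-seq_len(hi)])
    upper <- c(upper[seq_len(lo - 1)], upper[hi], upper[-seq_len(hi)])
  }
  res <- structure(
    list(statistic = NA_real_, dof = NA_integer_, p_value = NA_real_,
         bins = upper, status = "NA"),
    class = "cnv_chi2_test")
  if (length(o1) < 2) return(res)
  obs <- rbind(region = o1, background = o2)
  expd <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  res$statistic <- sum((obs - expd)^2 / expd)
  res$dof <- ncol(obs) - 1L
  res$p_value <- pchisq(res$statistic, df = res$dof, lower.tail = FALSE)
  res$status <- "ok"
  res
}

#' @export
print.cnv_perm_test <- function(x, ...) {
  cat(sprintf("# permutation depth test: mu = %.3f, R = %d, p = %s, status = %s\n",
              x$mu, x$n_resamples,
              if (is.na(x$p_value)) "NA" else format(x$p_value), x$status))
  invisible(x)
}

#' @export
print.cnv_chi2_test <- function(x, ...) {
  cat(sprintf("# chi-square depth test: X2 = %s, dof = %s, p = %s, status = %s\n",
              format(x$statistic), format(x$dof), format(x$p_value), x$status))
  invisible(x)
}

#' Depth tests of a region against its upstream and downstream flanks
#'
#' Runs both the chi-square and the permutation test with each flank (of
#' length `flank_factor` times the region length) as background. A genuine
#' loss shows a concave depth profile: both flanks materially deeper than the
#' region. A flank falling outside the available chromosome, or a window of
#' all-zero depth, yields status `"NA"` for that side.
#'
#' @param profile Whole-chromosome (or whole-window) `depth_profile` tibble.
#' @param start,end Candidate region, 0-based half-open chromosome coordinates.
#' @param flank_factor Flank length as a multiple of the region length
#'   (default 1).
#' @param n_resamples Permutation resamples (default 999).
#' @param seed Optional RNG seed.
#' @return A tibble with one row per (side, test): columns `side`
#'   (`"upstream"`/`"downstream"`), `test` (`"chi2"`/`"permutation"`),
#'   `statistic`, `dof`, `mu`, `p_value`, `status`.
#' @export
adjacency_tests <- function(profile, start, end, flank_factor = 1,
                            n_resamples = 999, seed = NULL) {
  stopifnot(end > start, flank_factor > 0)
  L <- end - start
  Lf <- round(flank_factor * L)
  first <- profile$pos[1]
  last <- profile$pos[nrow(profile)] + 1
  region <- slice_depth(profile, start, end)
  sides <- list(
    upstream = c(start - Lf, start),
    downstream = c(end, end + Lf)
  )
  rows <- purrr::imap(sides, function(win, side) {
    na_row <- tibble(side = side, test = c("chi2", "permutation"),
                     statistic = NA_real_, dof = NA_integer_, mu = NA_real_,
                     p_value = NA_real_, status = "NA")
    if (win[1] < first || win[2] > last) return(na_row)
    flank <- slice_depth(profile, win[1], win[2])
    chi <- chi2_depth_test(region, flank)
    # the permutation test needs equal lengths: resize the flank stretch
    bg <- if (Lf == L) flank else if (Lf > L) flank[seq_len(L)] else
      rep(flank, length.out = L)
    perm <- permutation_depth_test(region, bg, n_resamples = n_resamples,
                                   seed = derive_seed(seed, match(side, names(sides))))
    tibble(side = side,
           test = c("chi2", "permutation"),
           statistic = c(chi$statistic, NA_real_),
           dof = c(chi$dof, NA_integer_),
           mu = c(NA_real_, perm$mu),
           p_value = c(chi$p_value, perm$p_value),
           status = c(chi$status, perm$status))
  })
  bind_rows(rows)
}

#' Summarise a batch of depth-test results
#'
#' Tabulates, per test (and per side when present), the fraction of non-NA
#' results with p-value below each significance level, plus the NA fraction —
#' the shape of the published per-test summary tables.
#'
#' @param results Tibble with at least `test`, `p_value` and `status`
#'   columns; a `side` column is used as an extra grouping variable when
#'   present.
#' @param alphas Significance levels (default 0.01 and 0.05).
#' @return A tibble with one row per group: `n`, one `p_lt_<alpha>` column
#'   per level (fraction of non-NA results rejecting at that level) and
#'   `na_frac`.
#' @export
batch_summary <- function(results, alphas = c(0.01, 0.05)) {
  if (nrow(results) == 0) abort("no results to summarise")
  grp <- intersect(c("test", "side"), names(results))
  out <- results |>
    group_by(across(all_of(grp))) |>
    summarise(
      n = n(),
      !!!setNames(
        lapply(alphas, function(a) {
          rlang::quo(mean(.data$p_value[.data$status == "ok"] < !!a))
        }),
        paste0("p_lt_", format(alphas, trim = TRUE))
      ),
      na_frac = mean(.data$status != "ok"),
      .groups = "drop"
    )
  out
}
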