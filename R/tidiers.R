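#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a permutation depth test
#'
#' @param x A `cnv_perm_test` object.
#' @param ... Unused.
#' @return A one-row tibble: `mu`, `p_value`, `n_resamples`, `status`,
#'   `exhaustive`.
#' @export
tidy.cnv_perm_test <- function(x, ...) {
  tibble(mu = x$mu, p_value = x$p_value, n_resamples = x$n_resamples,
         status = x$status, exhaustive = x$exhaustive)
}

#' @rdname tidy.cnv_perm_test
#' @export
glance.cnv_perm_test <- function(x, ...) tidy(x)

#' Tidy a chi-square depth test
#'
#' @param x A `cnv_chi2_test` object.
#' @param ... Unused.
#' @return A one-row tibble: `statistic`, `dof`, `p_value`, `n_bins`,
#'   `status`.
#' @export
tidy.cnv_chi2_test <- function(x, ...) {
  tibble(statistic = x$statistic, dof = x$dof, p_value = x$p_value,
         n_bins = length(x$bins), status = x$status)
}

#' @rdname tidy.cnv_chi2_test
#' @export
glance.cnv_chi2_test <- function(x, ...) tidy(x)

#' Tidy overlap-length statistics
#'
#' @param x An `overlap_stats` object.
#' @param ... Unused.
#' @return `tidy()` returns the per-pair table; `glance()` the one-row
#'   summary.
#' @export
tidy.overlap_stats <- function(x, ...) x$pairs

#' @rdname tidy.overlap_stats
#' @export
glance.overlap_stats <- function(x, ...) {
  tibble(n_pairs = nrow(x$pairs), mean_overlap_bp = x$mean_overlap_bp,
         mode_overlap_bp = x$mode_overlap_bp,
         mean_ratio = if (length(x$ratio_to_length)) mean(x$ratio_to_length) else NA_real_)
}

#' Tidy a validation run
#'
#' @param x A `cnv_validation` object.
#' @param ... Unused.
#' @return `tidy()` returns the per-candidate table; `glance()` one row of
#'   run-level summaries.
#' @export
tidy.cnv_validation <- function(x, ...) x$per_candidate

#' @rdname tidy.cnv_validation
#' @export
glance.cnv_validation <- function(x, ...) {
  ev <- x$evidence_summary
  tibble(n_candidates = nrow(x$per_candidate),
         break_read = ev$break_read, paired_end = ev$paired_end,
         unsupported = ev$unsupported, supported = ev$supported)
}
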