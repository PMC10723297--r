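#' Trend in the proportion of responded calls across a session
#'
#' Bins calls into `n_bins` equal-width time bins over the pooled onset
#' range, computes the proportion of responded calls per bin, and fits an
#' ordinary least-squares line through (bin center, proportion). The
#' trend's significance is assessed by a case-resampling bootstrap: calls
#' are resampled with replacement *within each session*, the binned
#' proportions and slope recomputed `n_boot` times, and the one-sided
#' p-value is the fraction of bootstrap slopes at or below zero.
#'
#' @param calls A [call_table()] with `responded` flags set.
#' @param n_bins Number of time bins.
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed for the bootstrap.
#' @return An object of class `trend_report`: list with `bin_centers`,
#'   `proportion`, `n_per_bin`, `slope`, `intercept`, `p_value`, `n_boot`
#'   and the vector of `boot_slopes`.
#' @export
response_proportion_trend <- function(calls, n_bins = 10, n_boot = 1000,
                                      seed = 1L) {
  if (inherits(calls, "simulated_session")) calls <- as_call_table(calls)
  calls <- call_table(as.data.frame(calls))
  if (anyNA(calls$responded))
    stop("response_proportion_trend: responded flags are unset; run mark_responses() first")
  n_bins <- as.integer(n_bins)
  span <- range(calls$onset_s)
  if (diff(span) <= 0) stop("response_proportion_trend: session span must be positive")
  edges <- seq(span[1L], span[2L], length.out = n_bins + 1L)
  centers <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  bin <- findInterval(calls$onset_s, edges, rightmost.closed = TRUE)
  r <- as.numeric(calls$responded)

  binned_slope <- function(bin_idx, resp) {
    n <- tabulate(bin_idx, n_bins)
    s <- vapply(seq_len(n_bins), function(b) sum(resp[bin_idx == b]), numeric(1L))
    keep <- n > 0L
    p <- s[keep] / n[keep]
    x <- centers[keep]
    if (length(x) < 2L) return(c(NA_real_, NA_real_, rep(NA_real_, 0)))
    sl <- stats::cov(x, p) / stats::var(x)
    c(sl, mean(p) - sl * mean(x))
  }

  obs <- binned_slope(bin, r)
  n <- tabulate(bin, n_bins)
  s <- vapply(seq_len(n_bins), function(b) sum(r[bin == b]), numeric(1L))
  prop <- ifelse(n > 0L, s / n, NA_real_)

  set.seed(seed)
  by_session <- split(seq_len(nrow(calls)), calls$session_id)
  boot_slopes <- vapply(seq_len(n_boot), function(i) {
    idx <- unlist(lapply(by_session, function(ii)
      ii[sample.int(length(ii), length(ii), replace = TRUE)]),
      use.names = FALSE)
    binned_slope(bin[idx], r[idx])[1L]
  }, numeric(1L))
  boot_slopes <- boot_slopes[is.finite(boot_slopes)]

  structure(list(bin_centers = centers, proportion = prop, n_per_bin = n,
                 slope = obs[1L], intercept = obs[2L],
                 p_value = mean(boot_slopes <= 0), n_boot = n_boot,
                 boot_slopes = boot_slopes),
            class = "trend_report")
}

#' @export
print.trend_report <- function(x, ...) {
  cat(sprintf("trend_report: slope %.4g per s over %d bins; one-sided bootstrap p = %.4g (%d replicates)\n",
              x$slope, length(x$bin_centers), x$p_value, x$n_boot))
  invisible(x)
}

#' Response proportion as a function of call duration
#'
#' Bins calls by duration into equal-width half-open bins `[lo, hi)` (the
#' last bin closed) over the observed duration range and computes the
#' proportion of responded calls per bin. Bins without calls are reported
#' as absent (`NA` proportion, `n = 0`), not as zero.
#'
#' @param calls A [call_table()] with `responded` flags set.
#' @param n_duration_bins Number of duration bins.
#' @return An object of class `response_curve`: data frame with `bin_lo`,
#'   `bin_hi`, `bin_center`, `n`, `proportion`.
#' @export
response_by_duration <- function(calls, n_duration_bins = 12) {
  if (inherits(calls, "simulated_session")) calls <- as_call_table(calls)
  calls <- call_table(as.data.frame(calls))
  if (anyNA(calls$responded))
    stop("response_by_duration: responded flags are unset; run mark_responses() first")
  nb <- as.integer(n_duration_bins)
  if (is.na(nb) || nb < 1L) stop("response_by_duration: need at least 1 bin")
  rng <- range(calls$duration_s)
  if (diff(rng) <= 0) rng <- rng + c(-0.5, 0.5)  # all durations identical
  edges <- seq(rng[1L], rng[2L], length.out = nb + 1L)
  bin <- findInterval(calls$duration_s, edges, rightmost.closed = TRUE)
  n <- tabulate(bin, nb)
  s <- vapply(seq_len(nb), function(b) sum(calls$responded[bin == b]), numeric(1L))
  out <- data.frame(bin_lo = edges[-(nb + 1L)], bin_hi = edges[-1L],
                    bin_center = (edges[-1L] + edges[-(nb + 1L)]) / 2,
                    n = n, proportion = ifelse(n > 0L, s / n, NA_real_))
  class(out) <- c("response_curve", "data.frame")
  out
}

#' Duration bin with the highest response proportion
#'
#' Convenience accessor: the center of the non-empty duration bin whose
#' response proportion is largest (ties resolve to the shortest duration).
#'
#' @param curve A `response_curve`.
#' @return A duration (seconds).
#' @export
response_curve_argmax <- function(curve) {
  stopifnot(inherits(curve, "response_curve"))
  ok <- !is.na(curve$proportion)
  if (!any(ok)) stop("response_curve_argmax: curve has no populated bins")
  curve$bin_center[ok][which.max(curve$proportion[ok])]
}
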