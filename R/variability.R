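#' Time-binned coefficient of variation of call durations
#'
#' Splits the session span (first to last onset) into `n_bins` equal-width
#' time bins and computes, in every bin holding at least `min_calls` calls,
#' the coefficient of variation (standard deviation divided by mean) of the
#' call durations. Bins below the threshold are omitted from the series.
#'
#' @param calls A [call_table()] or `simulated_session`.
#' @param n_bins Number of time bins.
#' @param min_calls Minimum calls a bin needs to be retained.
#' @return An object of class `cv_series`: list with `bins` (data frame of
#'   `bin_center`, `cv`, `n`), `bin_edges`, and `sigmoid` (`NULL` until
#'   [fit_sigmoid()] is applied).
#' @export
binned_cv <- function(calls, n_bins = 10, min_calls = 3) {
  if (inherits(calls, "simulated_session")) calls <- as_call_table(calls)
  calls <- call_table(as.data.frame(calls))
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 1L) stop("binned_cv: n_bins must be >= 1")
  span <- range(calls$onset_s)
  if (diff(span) <= 0) stop("binned_cv: session span must be positive")
  edges <- seq(span[1L], span[2L], length.out = n_bins + 1L)
  idx <- findInterval(calls$onset_s, edges, rightmost.closed = TRUE)
  rows <- lapply(seq_len(n_bins), function(b) {
    d <- calls$duration_s[idx == b]
    if (length(d) < min_calls) return(NULL)
    data.frame(bin_center = (edges[b] + edges[b + 1L]) / 2,
               cv = stats::sd(d) / mean(d), n = length(d))
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows))
    stop("binned_cv: no bin holds at least min_calls calls")
  structure(list(bins = do.call(rbind, rows), bin_edges = edges,
                 min_calls = min_calls, sigmoid = NULL),
            class = "cv_series")
}

#' Sigmoid fit to a coefficient-of-variation series
#'
#' Fits the 4-parameter logistic
#' `cv(t) = floor + (ceiling - floor) / (1 + exp(steepness * (t - midpoint)))`
#' to the retained bins by bounded least squares (`floor`, `ceiling` >= 0,
#' `midpoint` within the session span). With positive steepness the curve
#' decreases from `ceiling` to `floor`, the long-to-short stereotypy
#' transition seen across a session; the magnitude of `steepness` measures
#' how sudden that transition is. Several starting points are tried and the
#' convergent fit with the lowest residual sum of squares is kept.
#'
#' @param series A `cv_series` from [binned_cv()] with at least 4 retained
#'   bins.
#' @return The series with `sigmoid` filled in: named parameter vector
#'   (`floor`, `ceiling`, `midpoint`, `steepness`), `rss`, and `converged`.
#'   If no start converges, `converged` is `FALSE` and the failure
#'   diagnostics are kept in `message`.
#' @export
fit_sigmoid <- function(series) {
  stopifnot(inherits(series, "cv_series"))
  d <- series$bins
  if (nrow(d) < 4L)
    stop("fit_sigmoid: need at least 4 retained bins")
  t <- d$bin_center
  y <- d$cv
  span <- range(series$bin_edges)
  w <- diff(span)
  if (diff(range(y)) < 1e-12) {
    # flat series: the logistic degenerates to a constant; fit it exactly
    series$sigmoid <- list(
      params = c(floor = mean(y), ceiling = mean(y),
                 midpoint = mean(span), steepness = 0),
      rss = sum((y - mean(y))^2), converged = TRUE, message = NULL)
    return(series)
  }
  starts <- expand.grid(mid = span[1L] + c(1 / 3, 1 / 2, 2 / 3) * w,
                        st = c(4 / w, 20 / w, -4 / w))
  best <- NULL
  msgs <- character(0)
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ fl + (ce - fl) / (1 + exp(st * (t - mid))),
        start = list(fl = max(min(y), 1e-6), ce = max(y),
                     mid = starts$mid[i], st = starts$st[i]),
        lower = c(fl = 0, ce = 0, mid = span[1L], st = -1e3),
        upper = c(fl = Inf, ce = Inf, mid = span[2L], st = 1e3),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      msgs <- c(msgs, conditionMessage(fit))
      next
    }
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    series$sigmoid <- list(params = NULL, rss = NA_real_, converged = FALSE,
                           message = paste(unique(msgs), collapse = "; "))
    return(series)
  }
  cf <- stats::coef(best$fit)
  series$sigmoid <- list(
    params = c(floor = unname(cf["fl"]), ceiling = unname(cf["ce"]),
               midpoint = unname(cf["mid"]), steepness = unname(cf["st"])),
    rss = best$rss, converged = TRUE, message = NULL)
  series
}

#' @export
print.cv_series <- function(x, ...) {
  cat(sprintf("cv_series: %d retained bins (min %d calls each)\n",
              nrow(x$bins), x$min_calls))
  if (!is.null(x$sigmoid)) {
    if (isTRUE(x$sigmoid$converged)) {
      p <- x$sigmoid$params
      cat(sprintf("  sigmoid: floor %.3g, ceiling %.3g, midpoint %.4g, steepness %.4g\n",
                  p["floor"], p["ceiling"], p["midpoint"], p["steepness"]))
    } else cat("  sigmoid fit did not converge:", x$sigmoid$message, "\n")
  }
  invisible(x)
}

#' @export
plot.cv_series <- function(x, ...) {
  graphics::plot(x$bins$bin_center, x$bins$cv, xlab = "session time (s)",
                 ylab = "CV of call duration", ...)
  if (!is.null(x$sigmoid) && isTRUE(x$sigmoid$converged)) {
    p <- x$sigmoid$params
    tt <- seq(min(x$bin_edges), max(x$bin_edges), length.out = 200)
    graphics::lines(tt, p["floor"] + (p["ceiling"] - p["floor"]) /
                      (1 + exp(p["steepness"] * (tt - p["midpoint"]))))
  }
  invisible(x)
}
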