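#' Call-event table
#'
#' The common currency of the analysis pipeline: one row per call with the
#' session it belongs to, the caller, the onset (seconds from session
#' start), the duration (seconds) and, once marked, whether it received a
#' response. Both empirical tables (after [segment_calls()]) and simulated
#' sessions (via [as_call_table()]) take this shape.
#'
#' @param df Data frame with columns `session_id`, `caller_id`, `onset_s`,
#'   `duration_s` and optionally `responded` (logical; `NA` when unset).
#' @return The validated data frame with class `call_table`, sorted by
#'   session and onset.
#' @export
call_table <- function(df) {
  req <- c("session_id", "caller_id", "onset_s", "duration_s")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("call_table: missing column(s): ", paste(miss, collapse = ", "))
  if (!is.numeric(df$onset_s) || !is.numeric(df$duration_s))
    stop("call_table: onset_s and duration_s must be numeric")
  if (any(!is.finite(df$onset_s)) || any(!is.finite(df$duration_s)))
    stop("call_table: onsets and durations must be finite")
  if (any(df$duration_s <= 0))
    stop("call_table: durations must be positive")
  if (is.null(df$responded)) df$responded <- NA
  df$responded <- as.logical(df$responded)
  df <- df[order(df$session_id, df$onset_s), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("call_table", "data.frame")
  df
}

#' Syllable-event table
#'
#' Pre-segmented syllables (continuous bouts of vocalization) with onsets
#' and offsets, the raw input of the empirical pipeline.
#'
#' @param df Data frame with columns `session_id`, `caller_id`, `onset_s`,
#'   `offset_s`; every offset must exceed its onset.
#' @return The validated data frame with class `syllable_table`.
#' @export
syllable_table <- function(df) {
  req <- c("session_id", "caller_id", "onset_s", "offset_s")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("syllable_table: missing column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(df$onset_s)) || any(!is.finite(df$offset_s)))
    stop("syllable_table: onsets and offsets must be finite")
  if (any(df$offset_s <= df$onset_s))
    stop("syllable_table: every offset_s must exceed its onset_s")
  df <- df[order(df$session_id, df$caller_id, df$onset_s), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("syllable_table", "data.frame")
  df
}

#' Merge syllables into calls
#'
#' Within each caller and session, consecutive syllables separated by a
#' gap strictly less than `max_gap_s` (default 1 second) are merged into a
#' single call whose onset is the first syllable's onset and whose duration
#' runs from that onset to the last syllable's offset. A gap of exactly
#' `max_gap_s` starts a new call.
#'
#' @param syllables A [syllable_table()].
#' @param max_gap_s Maximum intra-call gap, seconds.
#' @return A [call_table()] (with `responded` unset).
#' @examples
#' syl <- syllable_table(data.frame(session_id = "s", caller_id = "A",
#'                                  onset_s = c(0, 0.5), offset_s = c(0.2, 0.8)))
#' segment_calls(syl) # one call, duration 0.8
#' @export
segment_calls <- function(syllables, max_gap_s = 1.0) {
  syllables <- syllable_table(as.data.frame(syllables))
  if (max_gap_s <= 0) stop("segment_calls: max_gap_s must be positive")
  pieces <- split(syllables,
                  list(syllables$session_id, syllables$caller_id),
                  drop = TRUE)
  out <- lapply(pieces, function(d) {
    d <- d[order(d$onset_s), , drop = FALSE]
    if (nrow(d) > 1L) {
      gap <- d$onset_s[-1L] - d$offset_s[-nrow(d)]
      if (any(gap < 0))
        stop("segment_calls: overlapping syllables for caller ",
             d$caller_id[1L], " in session ", d$session_id[1L])
      grp <- cumsum(c(0, gap >= max_gap_s))
    } else grp <- 0
    on <- tapply(d$onset_s, grp, min)
    off <- tapply(d$offset_s, grp, max)
    data.frame(session_id = d$session_id[1L], caller_id = d$caller_id[1L],
               onset_s = as.numeric(on), duration_s = as.numeric(off - on))
  })
  call_table(do.call(rbind, c(out, make.row.names = FALSE)))
}

#' Mark which calls received a response
#'
#' A call counts as responded if any call by a *different* caller in the
#' same session has its onset within the half-open window
#' `(onset, onset + window_s]` after the call's onset (default 12 seconds).
#' Every call is evaluated independently, so responses can chain.
#'
#' @param calls A [call_table()].
#' @param window_s Response window, seconds.
#' @return The call table with the `responded` column filled in.
#' @export
mark_responses <- function(calls, window_s = 12.0) {
  calls <- call_table(as.data.frame(calls))
  if (window_s <= 0) stop("mark_responses: window_s must be positive")
  resp <- logical(nrow(calls))
  for (sid in unique(calls$session_id)) {
    idx <- which(calls$session_id == sid)
    on <- calls$onset_s[idx]
    who <- calls$caller_id[idx]
    resp[idx] <- vapply(seq_along(idx), function(i) {
      any(who != who[i] & on > on[i] & on <= on[i] + window_s)
    }, logical(1L))
  }
  calls$responded <- resp
  calls
}
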