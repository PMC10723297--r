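#' Read and write call and syllable tables
#'
#' Tables are plain tab-delimited UTF-8 text with a header row and seconds
#' as decimal numbers; columns as in [call_table()] / [syllable_table()].
#' A `responded` column, when present, is read as logical.
#'
#' @param path File path.
#' @param sep Field separator.
#' @return `read_call_table()` returns a [call_table()];
#'   `read_syllable_table()` a [syllable_table()]. The writers return the
#'   path, invisibly.
#' @name table_io
NULL

#' @rdname table_io
#' @export
read_call_table <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  call_table(df)
}

#' @rdname table_io
#' @param x Table to write.
#' @export
write_call_table <- function(x, path, sep = "\t") {
  utils::write.table(as.data.frame(x), path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_syllable_table <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  syllable_table(df)
}

#' @rdname table_io
#' @export
write_syllable_table <- function(x, path, sep = "\t") {
  utils::write.table(as.data.frame(x), path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a session's belief snapshots to a plain-text matrix file
#'
#' One file per agent is written: rows are grid points (first column the
#' duration), remaining columns the belief mass at each snapshot iteration.
#'
#' @param session A `simulated_session`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Character vector of the two file paths, invisibly.
#' @export
write_belief_snapshots <- function(session, dir, prefix = "beliefs") {
  stopifnot(inherits(session, "simulated_session"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pts <- session$config$observation$grid$points
  paths <- character(2L)
  for (agent in 1:2) {
    m <- cbind(duration = pts, session$belief_snapshots[[agent]])
    colnames(m) <- c("duration",
                     paste0("iter", session$snapshot_iterations))
    paths[agent] <- file.path(dir, sprintf("%s_agent%d.tsv", prefix, agent))
    utils::write.table(m, paths[agent], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(paths)
}

# Strip non-serializable bulk from report objects before JSON export.
report_to_list <- function(x) {
  if (inherits(x, "clustering_report"))
    return(list(k_range = x$k_range, bic = x$bic, k_selected = x$k_selected,
                k_bicmin = x$k_bicmin, n_used = x$n_used,
                components = x$components))
  if (inherits(x, "cv_series"))
    return(list(bins = x$bins, bin_edges = x$bin_edges,
                sigmoid = if (!is.null(x$sigmoid))
                  list(params = as.list(x$sigmoid$params),
                       rss = x$sigmoid$rss,
                       converged = x$sigmoid$converged)))
  if (inherits(x, "trend_report"))
    return(list(bin_centers = x$bin_centers, proportion = x$proportion,
                n_per_bin = x$n_per_bin, slope = x$slope,
                intercept = x$intercept, p_value = x$p_value,
                n_boot = x$n_boot))
  if (inherits(x, "response_curve"))
    return(as.list(as.data.frame(x)))
  if (is.list(x)) return(lapply(x, report_to_list))
  x
}

#' Serialize analysis reports to machine-readable JSON
#'
#' @param reports Named list of report objects (`clustering_report`,
#'   `cv_series`, `trend_report`, `response_curve`, or nested lists of
#'   them).
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_report_json <- function(reports, path) {
  jsonlite::write_json(report_to_list(reports), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}
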