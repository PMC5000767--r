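#' Read a per-conformation barrier table
#'
#' Reads a delimited text table (TSV by default) with a header row and
#' returns a \code{\link{barrier_ensemble}} or \code{\link{paired_ensemble}}
#' depending on which schema the header matches:
#' \itemize{
#'   \item single region: \code{conformation_id}, \code{barrier};
#'   \item paired: \code{conformation_id}, \code{barrier_small},
#'     \code{barrier_big}.
#' }
#' An optional \code{time_ns} column supplies sampling times.  Unknown
#' columns are preserved (as an \code{"extra"} attribute) and re-emitted by
#' \code{\link{write_barriers}}, so transcribed tables with annotation
#' columns round-trip unchanged.  Row order is file order and is treated
#' as sampling order.  Numeric fields must parse as finite decimals
#' (decimal point, no locale commas).
#'
#' @param path Path to the table.
#' @param delimiter Field delimiter; default tab.  Use \code{","} for CSV.
#' @param system_label Label attached to the returned ensemble; default
#'   the file name.
#' @param qm_region QM-region tag for single-region tables.
#' @return A \code{barrier_ensemble} or \code{paired_ensemble}.
#' @export
read_barriers <- function(path, delimiter = "\t",
                          system_label = basename(path),
                          qm_region = c("small", "big")) {
  qm_region <- match.arg(qm_region)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  if (nrow(df) == 0L) stop("empty table: no data rows", call. = FALSE)
  cols <- names(df)
  paired <- all(c("conformation_id", "barrier_small", "barrier_big") %in% cols)
  single <- all(c("conformation_id", "barrier") %in% cols)
  if (!paired && !single) {
    stop("missing columns: need conformation_id plus either 'barrier' or ",
         "'barrier_small'+'barrier_big'; found: ",
         paste(cols, collapse = ", "), call. = FALSE)
  }
  num_cols <- if (paired) c("barrier_small", "barrier_big") else "barrier"
  if ("time_ns" %in% cols) num_cols <- c(num_cols, "time_ns")
  parsed <- lapply(num_cols, function(col) parse_numeric_column(df, col))
  names(parsed) <- num_cols
  ids <- df$conformation_id
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate conformation_id '%s'",
                 ids[duplicated(ids)][1L]), call. = FALSE)
  }
  times <- if ("time_ns" %in% cols) parsed$time_ns else NULL
  known <- c("conformation_id", "time_ns", num_cols)
  extra <- df[, setdiff(cols, known), drop = FALSE]
  out <- if (paired) {
    paired_ensemble(parsed$barrier_small, parsed$barrier_big,
                    conformation_id = ids, sample_time = times,
                    system_label = system_label)
  } else {
    barrier_ensemble(parsed$barrier, conformation_id = ids,
                     sample_time = times, system_label = system_label,
                     qm_region = qm_region)
  }
  if (ncol(extra) > 0L) attr(out, "extra") <- extra
  out
}

parse_numeric_column <- function(df, col) {
  raw <- df[[col]]
  val <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(val) | !is.finite(val))
  if (length(bad) > 0L) {
    stop(sprintf("unparsable numeric '%s' at row %d, column '%s'",
                 raw[bad[1L]], bad[1L], col), call. = FALSE)
  }
  val
}

#' Write a barrier table
#'
#' Writes a \code{\link{barrier_ensemble}} or \code{\link{paired_ensemble}}
#' in the schema \code{\link{read_barriers}} reads, preserving row order
#' and any extra columns carried on the object.  Sampling times are
#' written as a \code{time_ns} column when present.
#'
#' @param x A \code{barrier_ensemble} or \code{paired_ensemble}.
#' @param path Destination path.
#' @param delimiter Field delimiter; default tab.
#' @return \code{path}, invisibly.
#' @export
write_barriers <- function(x, path, delimiter = "\t") {
  stopifnot(inherits(x, "barrier_ensemble") || inherits(x, "paired_ensemble"))
  df <- x
  attr(df, "extra") <- NULL
  class(df) <- "data.frame"
  if (all(is.na(df$sample_time))) {
    df$sample_time <- NULL
  } else {
    names(df)[names(df) == "sample_time"] <- "time_ns"
  }
  extra <- attr(x, "extra")
  if (!is.null(extra)) df <- cbind(df, extra)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an analysis report
#'
#' Serializes a convergence trace, a protocol result, or any named list of
#' scalars to JSON (default) or TSV.  Traces serialize as their point/
#' change series plus metadata (statistic, metric, converged-after count);
#' protocol results include the evaluation order, costs and savings.  A
#' missing converged-after count is written as an explicit \code{null},
#' never omitted, and numbers are written at full precision so identical
#' inputs give byte-identical reports.
#'
#' @param result A \code{convergence_trace}, \code{protocol_result}, or
#'   named list.
#' @param path Destination path.
#' @param format \code{"json"} (default) or \code{"tsv"}.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(result, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  payload <- report_payload(result)
  if (format == "json") {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null", null = "null", pretty = TRUE)
  } else {
    write_report_tsv(payload, path)
  }
  invisible(path)
}

report_payload <- function(result) {
  if (inherits(result, "convergence_trace")) {
    df <- merge(result$points, result$changes, by = "n", all.x = TRUE)
    list(type = "convergence_trace",
         statistic = result$statistic,
         metric = result$metric,
         converged_after = if (is.na(result$converged_after)) NA_integer_
                           else result$converged_after,
         points = df)
  } else if (inherits(result, "protocol_result")) {
    list(type = "protocol_result",
         evaluation_order = result$evaluation_order,
         n_big_evaluated = result$n_big_evaluated,
         converged = result$converged,
         converged_after = if (is.na(result$converged_after)) NA_integer_
                           else result$converged_after,
         final_boltzmann_average = result$final_boltzmann_average,
         final_disproportionate_effect = result$final_disproportionate_effect,
         total_cost = result$total_cost,
         savings = result$savings,
         n_pairs = result$n_pairs,
         baseline = result$baseline)
  } else if (is.list(result) && !is.null(names(result))) {
    result
  } else {
    stop("unsupported report object", call. = FALSE)
  }
}

write_report_tsv <- function(payload, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  scalars <- payload[!vapply(payload, is.data.frame, logical(1))]
  for (nm in names(scalars)) {
    v <- scalars[[nm]]
    v <- if (length(v) == 0L || all(is.na(v))) "null" else
      paste(format(v, digits = 17, scientific = FALSE, trim = TRUE),
            collapse = ",")
    writeLines(sprintf("# %s\t%s", nm, v), con)
  }
  tables <- payload[vapply(payload, is.data.frame, logical(1))]
  for (df in tables) {
    utils::write.table(format(df, digits = 17, scientific = FALSE,
                              trim = TRUE),
                       con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
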