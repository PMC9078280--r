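# Plain-text dialects: thermogram CSV with '# key=value' header lines, and
# generic (T_K, molality, value, sigma) data tables.

#' Write and read thermogram CSV files
#'
#' The dialect is a CSV with columns `time_s`, `T_K`, `heatflow_W`, preceded
#' by comment header lines of the form `# key=value` carrying the heating
#' rate (`rate_K_per_s`), the `scan_id`, and any scalar metadata.
#'
#' @param tg a [thermogram()].
#' @param path file path.
#' @return `path` invisibly (writer); a [thermogram()] (reader).
#' @export
write_thermogram <- function(tg, path) {
  stopifnot(inherits(tg, "thermogram"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rate_K_per_s=%.10g", tg$beta), con)
  writeLines(sprintf("# scan_id=%s", tg$scan_id), con)
  for (key in names(tg$meta)) {
    val <- tg$meta[[key]]
    if (length(val) == 1L && (is.numeric(val) || is.character(val) ||
                                is.logical(val))) {
      writeLines(sprintf("# %s=%s", key,
                         if (is.numeric(val)) sprintf("%.10g", val)
                         else as.character(val)), con)
    }
  }
  writeLines("time_s,T_K,heatflow_W", con)
  utils::write.table(
    data.frame(time_s = tg$time_s, T_K = tg$T_K, heatflow_W = tg$hf_W),
    con, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_thermogram
#' @export
read_thermogram <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    key <- sub("=.*$", "", kv)
    val <- sub("^[^=]*=", "", kv)
    num <- suppressWarnings(as.numeric(val))
    meta[[key]] <- if (!is.na(num)) num else val
  }
  if (is.null(meta$rate_K_per_s)) stop("missing '# rate_K_per_s=' header")
  body <- utils::read.csv(text = lines[!grepl("^#", lines)])
  tg <- thermogram(
    scan_id = if (!is.null(meta$scan_id)) meta$scan_id else basename(path),
    beta = meta$rate_K_per_s,
    time_s = body$time_s, T_K = body$T_K, hf_W = body$heatflow_W,
    meta = meta[setdiff(names(meta), c("rate_K_per_s", "scan_id"))])
  tg
}

#' Read and write (T_K, molality, value, sigma) data tables
#'
#' CSV tables for osmotic-coefficient and solubility observations.
#'
#' @param data a data frame with columns `T_K`, `molality`, `value` and
#'   optionally `sigma`.
#' @param path file path.
#' @export
write_data_table <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_data_table
#' @export
read_data_table <- function(path) {
  df <- utils::read.csv(path)
  need <- c("T_K", "molality", "value")
  if (!all(need %in% names(df))) {
    stop("data table must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(df$sigma)) df$sigma <- NA_real_
  df
}
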