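#' Spectrum CSV export / import
#'
#' Comma-separated, '.' decimal, header row, '#' comment lines carrying the
#' normalization state and metadata. Read-back parses by header names, so
#' column order is irrelevant.
#'
#' @param s a \code{spectrum_measurement}.
#' @param path output file.
#' @return \code{write_spectrum_csv}: the path, invisibly;
#'   \code{read_spectrum_csv}: a \code{spectrum_measurement}.
#' @export
write_spectrum_csv <- function(s, path) {
  stopifnot(inherits(s, "spectrum_measurement"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# state: ", paste(s$state, collapse = ",")),
               paste0("# lambda_iso: ",
                      if (is.null(s$meta$lambda_iso)) "NA"
                      else s$meta$lambda_iso),
               paste0("# fluence_source: ",
                      if (is.null(s$meta$fluence_source)) "NA"
                      else s$meta$fluence_source)), con)
  utils::write.csv(data.frame(wavelength_nm = s$wavelengths, mean = s$mean,
                              sd = s$sd),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    v <- sub(paste0("^# ", key, ": "), "", grep(paste0("^# ", key, ":"),
                                                hdr, value = TRUE))
    if (length(v) == 0 || v == "NA") NULL else v
  }
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  for (col in c("wavelength_nm", "mean", "sd"))
    if (!col %in% names(df)) stop("spectrum CSV lacks column: ", col)
  state <- get("state")
  li <- get("lambda_iso")
  structure(list(wavelengths = df$wavelength_nm, mean = df$mean, sd = df$sd,
                 state = if (is.null(state)) "raw"
                         else strsplit(state, ",")[[1]],
                 meta = list(lambda_iso = if (is.null(li)) NULL
                             else as.numeric(li),
                             fluence_source = get("fluence_source"))),
            class = "spectrum_measurement")
}

#' Array-payload persistence
#'
#' Image stacks and fluence maps are persisted as versioned R serialization
#' files (binary, run-time artifacts); a schema tag is checked on read and a
#' version mismatch warns. Write-then-read is identity.
#'
#' @param x a \code{pa_stack} or \code{fluence_map}.
#' @param path file path.
#' @return the path (write), or the object (read).
#' @export
write_pa_stack <- function(x, path) {
  stopifnot(inherits(x, "pa_stack"))
  saveRDS(list(schema = "paoxy_pa_stack", schema_version = 1L,
               package_version = as.character(utils::packageVersion("paoxy")),
               payload = x), path)
  invisible(path)
}

#' @rdname write_pa_stack
#' @export
read_pa_stack <- function(path) .read_payload(path, "paoxy_pa_stack", "pa_stack")

#' @rdname write_pa_stack
#' @export
write_fluence_map <- function(x, path) {
  stopifnot(inherits(x, "fluence_map"))
  saveRDS(list(schema = "paoxy_fluence_map", schema_version = 1L,
               package_version = as.character(utils::packageVersion("paoxy")),
               payload = x), path)
  invisible(path)
}

#' @rdname write_pa_stack
#' @export
read_fluence_map <- function(path)
  .read_payload(path, "paoxy_fluence_map", "fluence_map")

.read_payload <- function(path, schema, cls) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("integrity error reading ", path, ": ", conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$schema, schema) ||
      !inherits(obj$payload, cls))
    stop("integrity error: ", path, " is not a ", schema, " file")
  if (!identical(obj$schema_version, 1L))
    warning("file schema version ", obj$schema_version,
            " is newer than this package understands")
  obj$payload
}

#' Error-report export
#'
#' Writes the report's long table as CSV and its summary (plus error
#' reduction, ANOVA and config echo) as JSON.
#'
#' @param report an \code{error_report}.
#' @param csv_path,json_path output paths (NULL skips either).
#' @return list of written paths, invisibly.
#' @export
write_error_report <- function(report, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "error_report"))
  out <- list()
  if (!is.null(csv_path)) {
    utils::write.csv(report$table, csv_path, row.names = FALSE)
    out$csv <- csv_path
  }
  if (!is.null(json_path)) {
    payload <- list(experiment = report$experiment, summary = report$summary,
                    error_reduction_pct = report$error_reduction_pct,
                    anova = report$anova,
                    config = unclass(report$config))
    payload$config$mccfg <- unclass(payload$config$mccfg)
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    out$json <- json_path
  }
  invisible(out)
}
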