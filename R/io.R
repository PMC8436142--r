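#' Default stage-token alias map
#'
#' Maps common hypnogram vocabularies onto the canonical AASM-style codes,
#' including the Rechtschaffen–Kales stages used by the DREAMS database
#' (S1–S4) and a few numeric conventions.
#'
#' @return named character vector: names are input tokens (uppercased),
#'   values canonical codes.
#' @export
stage_aliases <- function() {
  c(W = "W", WAKE = "W", "0" = "W",
    N1 = "N1", S1 = "N1", "1" = "N1",
    N2 = "N2", S2 = "N2", "2" = "N2",
    N3 = "N3", S3 = "N3", S4 = "N3", "3" = "N3", "4" = "N3",
    REM = "REM", R = "REM", "5" = "REM",
    UNKNOWN = "UNKNOWN", "?" = "UNKNOWN", MT = "UNKNOWN")
}

#' Read a plain-text hypnogram
#'
#' Accepts one stage token per line, or comma-separated tokens; tokens are
#' mapped through an alias table and unrecognized tokens become UNKNOWN
#' with a warning.
#'
#' @param path text file path.
#' @param epoch_s epoch length in seconds (default 30).
#' @param aliases token alias map, see [stage_aliases()].
#' @return a [hypnogram()].
#' @export
read_hypnogram <- function(path, epoch_s = 30, aliases = stage_aliases()) {
  if (!file.exists(path)) stop("hypnogram file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  toks <- toupper(trimws(unlist(strsplit(lines, ","))))
  toks <- toks[nzchar(toks)]
  if (!length(toks)) stop("hypnogram file is empty: ", path)
  mapped <- unname(aliases[toks])
  if (anyNA(mapped)) {
    warning("unrecognized stage token(s) mapped to UNKNOWN: ",
            paste(unique(toks[is.na(mapped)]), collapse = ", "))
    mapped[is.na(mapped)] <- "UNKNOWN"
  }
  hypnogram(mapped, epoch_s = epoch_s)
}

#' Write a hypnogram as one token per line
#' @param hyp a [hypnogram()].
#' @param path output path.
#' @export
write_hypnogram <- function(hyp, path) {
  writeLines(hyp$stages, path)
  invisible(path)
}

#' Read/write event tables as CSV
#'
#' Comma-separated, "." decimal, UTF-8, header mandatory; times in seconds.
#' Intervals are validated on read (`start_s < end_s`) and the round trip
#' is lossless for all columns.
#'
#' @param path CSV path.
#' @return [read_event_table()] returns a validated `tfs_events` data frame.
#' @export
read_event_table <- function(path) {
  if (!file.exists(path)) stop("event table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_event_table(df)
}

#' @rdname read_event_table
#' @param table an event table ([event_table()]).
#' @export
write_event_table <- function(table, path) {
  validate_event_table(as.data.frame(table))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a YAML pipeline configuration
#'
#' @param path YAML file; top-level keys may include `spectrogram`,
#'   `artifact`, `tfsigma`, `wavelet`, `synth`, each a list of parameter
#'   overrides for the corresponding constructor.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}
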