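#' Read and write R-peak event tables
#'
#' The shared plain-text interchange format for R-wave series: a delimited
#' table with header columns `subject_id` and `r_time_ms`. Times are
#' written as integer-rounded milliseconds.
#'
#' @param rwaves Tibble with `subject` (or `subject_id`) and `time_ms`
#'   (or `r_time_ms`) columns.
#' @param path File path.
#' @param delim Field delimiter (tab by default).
#' @return `read_rwave_table()` returns a tibble with `subject`, `beat`,
#'   `time_ms`; `write_rwave_table()` returns `path` invisibly.
#' @export
write_rwave_table <- function(rwaves, path, delim = "\t") {
  df <- as_tibble(rwaves)
  if ("subject" %in% names(df)) df <- dplyr::rename(df, subject_id = "subject")
  if ("time_ms" %in% names(df)) df <- dplyr::rename(df, r_time_ms = "time_ms")
  stopifnot(all(c("subject_id", "r_time_ms") %in% names(df)))
  readr::write_delim(df |>
                       dplyr::mutate(r_time_ms = round(.data$r_time_ms)) |>
                       dplyr::select("subject_id", "r_time_ms"),
                     path, delim = delim)
  invisible(path)
}

#' @rdname write_rwave_table
#' @export
read_rwave_table <- function(path, delim = "\t") {
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
  stopifnot(all(c("subject_id", "r_time_ms") %in% names(df)))
  df |>
    dplyr::rename(subject = "subject_id", time_ms = "r_time_ms") |>
    dplyr::group_by(.data$subject) |>
    dplyr::mutate(beat = dplyr::row_number(), .after = "subject") |>
    dplyr::ungroup()
}

#' Read a WFDB-style beat annotation export
#'
#' Parses the plain-text form produced by WFDB's `rdann -v` style tools:
#' whitespace-separated columns time, sample index, annotation symbol
#' (plus trailing fields, ignored). Only beat annotations (`N`, `L`, `R`,
#' `V`, `A` by default) are kept; times are converted to ms using the
#' sampling frequency.
#'
#' @param path Annotation text file.
#' @param fs Sampling frequency in Hz used to convert sample indices.
#' @param beat_symbols Annotation symbols treated as beats.
#' @return A tibble with `beat` and `time_ms`.
#' @export
read_wfdb_ann <- function(path, fs = 1000,
                          beat_symbols = c("N", "L", "R", "V", "A")) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  fields <- strsplit(trimws(lines), "\\s+")
  ok <- vapply(fields, length, integer(1)) >= 3
  fields <- fields[ok]
  sym <- vapply(fields, `[[`, character(1), 3)
  samp <- as.numeric(vapply(fields, `[[`, character(1), 2))
  keep <- sym %in% beat_symbols & !is.na(samp)
  t <- samp[keep] / fs * 1000
  tibble(beat = seq_along(t), time_ms = t)
}

#' Read and write trial logs
#'
#' Delimited trial tables with header, the shared format emitted by the
#' gating and recoding stages.
#'
#' @param trials Trial tibble.
#' @param path File path.
#' @param delim Field delimiter.
#' @return `read_trial_log()` returns a tibble; `write_trial_log()`
#'   returns `path` invisibly.
#' @export
write_trial_log <- function(trials, path, delim = "\t") {
  readr::write_delim(as_tibble(trials), path, delim = delim)
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path, delim = "\t") {
  readr::read_delim(path, delim = delim, show_col_types = FALSE)
}

#' Read a declarative pipeline configuration
#'
#' A single YAML file covering the generator settings consumed by
#' [run_pipeline()]: `heart`, `behavior`, `gating`, `p_correct` (list of
#' cell records), `trials_per_cell`, `baseline`, `gap_systole`,
#' `gap_diastole`, `seed`.
#'
#' @param path YAML file path.
#' @return A named list; a `p_correct` entry is converted to a tibble.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$p_correct)) {
    cfg$p_correct <- purrr::map(cfg$p_correct, as_tibble) |>
      purrr::list_rbind()
  }
  cfg
}
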