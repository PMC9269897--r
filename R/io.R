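#' Read and write association datasets
#'
#' Long TSV with header columns `participant_id`, `age_bin`, `gender`,
#' `level`, `cue`, `cue_position`, `position`, `response` (UTF-8).
#'
#' @param path File path.
#' @return `read_associations()` returns the association tibble.
#' @export
read_associations <- function(path) {
  cols <- readr::cols(
    participant_id = readr::col_character(),
    age_bin = readr::col_integer(),
    gender = readr::col_character(),
    level = readr::col_integer(),
    cue = readr::col_character(),
    cue_position = readr::col_integer(),
    position = readr::col_integer(),
    response = readr::col_character()
  )
  out <- readr::read_tsv(path, col_types = cols, na = c("", "NA"))
  missing <- setdiff(c("participant_id", "level", "cue", "position", "response"),
                     names(out))
  if (length(missing)) {
    stop_snowsem("Association file lacks required column(s): %s.",
                 paste(missing, collapse = ", "))
  }
  out
}

#' @rdname read_associations
#' @param associations Association tibble.
#' @export
write_associations <- function(associations, path) {
  readr::write_tsv(associations, path)
  invisible(path)
}

#' Read a sentiment lexicon
#'
#' Two-column TSV `word` / `sentiment` with scores in `[-1, 1]`.
#'
#' @param path File path.
#' @return Tibble with `word`, `sentiment`.
#' @export
read_sentiment_lexicon <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    word = readr::col_character(),
    sentiment = readr::col_double()
  ))
  if (any(abs(out$sentiment) > 1, na.rm = TRUE)) {
    stop_snowsem("Sentiment scores must lie in [-1, 1].")
  }
  out
}

#' Read a seven-item risk-propensity survey
#'
#' CSV with `participant_id` plus the integer items `general`, `driving`,
#' `financial`, `recreational`, `occupational`, `health`, `social` on the
#' 0-10 scale.
#'
#' @param path File path.
#' @return Tibble of survey responses.
#' @export
read_survey <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    .default = readr::col_integer()
  ))
  missing <- setdiff(snowsem_items, names(out))
  if (length(missing)) {
    stop_snowsem("Survey file lacks item column(s): %s.",
                 paste(missing, collapse = ", "))
  }
  rng <- range(as.matrix(out[snowsem_items]), na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 10) {
    stop_snowsem("Survey ratings must lie on the 0-10 scale.")
  }
  out
}

#' Read a SWOW-style cue-response table
#'
#' Long CSV with columns `cue`, `response`, `count` (aggregated association
#' frequencies, as distributed by the Small World of Words projects after
#' aggregation). Tokens are normalised on read.
#'
#' @param path File path.
#' @return Tibble `cue`, `response`, `count`.
#' @export
read_swow <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    cue = readr::col_character(),
    response = readr::col_character(),
    count = readr::col_double()
  ))
  dplyr::mutate(out, cue = normalize_response(.data$cue),
                response = normalize_response(.data$response))
}

#' Convert a SWOW-style table to profile rows
#'
#' Builds a cue x response count matrix analogous to the level-1 x level-2
#' co-occurrence matrix, so that SWOW data can enter [similarity_matrix()]
#' and [crosslingual_compare()].
#'
#' @param swow Tibble from [read_swow()].
#' @param cues Optional character vector restricting (and ordering) the rows.
#' @return Numeric count matrix with cue rownames and response colnames.
#' @export
swow_to_profiles <- function(swow, cues = NULL) {
  if (!is.null(cues)) {
    swow <- dplyr::filter(swow, .data$cue %in% cues)
  }
  agg <- dplyr::summarise(dplyr::group_by(swow, .data$cue, .data$response),
                          count = sum(.data$count), .groups = "drop")
  rows <- if (is.null(cues)) sort(unique(agg$cue)) else intersect(cues, agg$cue)
  cols <- sort(unique(agg$response))
  M <- matrix(0, length(rows), length(cols), dimnames = list(rows, cols))
  M[cbind(match(agg$cue, rows), match(agg$response, cols))] <- agg$count
  M
}

#' Read a two-column translation table
#'
#' TSV mapping terms of the reference language to another language; used to
#' align similarity matrices in [crosslingual_compare()].
#'
#' @param path File path.
#' @return Tibble `ref`, `other`.
#' @export
read_term_map <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    ref = readr::col_character(),
    other = readr::col_character()
  ))
  dplyr::mutate(out, ref = normalize_response(.data$ref),
                other = normalize_response(.data$other))
}
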