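#' Normalise a response token
#'
#' Trims surrounding whitespace, case-folds, and collapses internal runs of
#' whitespace to single spaces. Empty results are returned as `""` so that
#' downstream filtering can flag them (see [filter_associations()]).
#'
#' @param raw Character vector of raw responses.
#' @return Character vector of normalised tokens.
#' @export
normalize_response <- function(raw) {
  out <- trimws(tolower(as.character(raw)))
  gsub("\\s+", " ", out)
}

#' Restricted Damerau-Levenshtein (optimal string alignment) distance
#'
#' Edit distance allowing substitutions, insertions, deletions, and
#' transpositions of adjacent characters, with the optimal-string-alignment
#' restriction that no substring is edited twice. Used to quality-check
#' supplied spelling-correction pairs.
#'
#' @param a,b Character vectors (recycled to a common length).
#' @return Integer vector of distances.
#' @export
damerau_levenshtein <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  vapply(seq_len(n), function(i) osa_dist(a[i], b[i]), integer(1))
}

osa_dist <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  la <- length(x); lb <- length(y)
  if (la == 0L) return(lb)
  if (lb == 0L) return(la)
  d <- matrix(0L, la + 1L, lb + 1L)
  d[, 1L] <- 0:la
  d[1L, ] <- 0:lb
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      cost <- if (x[i] == y[j]) 0L else 1L
      d[i + 1L, j + 1L] <- min(d[i, j + 1L] + 1L,       # deletion
                               d[i + 1L, j] + 1L,       # insertion
                               d[i, j] + cost)          # substitution
      if (i > 1L && j > 1L && x[i] == y[j - 1L] && x[i - 1L] == y[j]) {
        d[i + 1L, j + 1L] <- min(d[i + 1L, j + 1L], d[i - 1L, j - 1L] + cost)
      }
    }
  }
  d[la + 1L, lb + 1L]
}

#' Filter an association dataset and determine the eligible vocabulary
#'
#' Drops records (at both levels) whose normalised response is empty or in
#' the exclusion list, then computes the eligible level-1 vocabulary: level-1
#' responses produced at least `min_count` times across all participants.
#' Level-2 records are retained regardless of their own frequency; they form
#' the profile dimensions. Responses are normalised before matching.
#'
#' @param associations Long association tibble (see
#'   [generate_associations()] / [read_associations()]).
#' @param exclusions Character vector of tokens to remove (nonwords, failed
#'   responses); normalised before matching.
#' @param min_count Minimum level-1 token count for a word to enter the
#'   network vocabulary.
#' @return A list of class `snowsem_filtered`: `associations` (filtered
#'   tibble with normalised `cue`/`response`), `vocabulary` (character),
#'   `n_input`, `n_dropped` (records removed), `level1_counts` (tibble).
#' @export
filter_associations <- function(associations, exclusions = character(),
                                min_count = 3) {
  n_input <- nrow(associations)
  excl <- unique(normalize_response(exclusions))
  dat <- dplyr::mutate(associations,
                       response = normalize_response(.data$response),
                       cue = normalize_response(.data$cue))
  drop <- dat$response == "" | dat$response %in% excl
  dat <- dat[!drop, , drop = FALSE]

  l1 <- dplyr::filter(dat, .data$level == 1L)
  counts <- dplyr::count(l1, .data$response, name = "n")
  vocab <- sort(counts$response[counts$n >= min_count])
  if (length(vocab) == 0L) {
    stop_snowsem("no level-1 word passes the frequency threshold (min_count = %d).",
                 min_count)
  }
  structure(list(associations = dat,
                 vocabulary = vocab,
                 n_input = n_input,
                 n_dropped = sum(drop),
                 min_count = min_count,
                 level1_counts = dplyr::arrange(counts, dplyr::desc(.data$n))),
            class = "snowsem_filtered")
}

#' @export
print.snowsem_filtered <- function(x, ...) {
  cat("<snowsem_filtered>\n")
  cat(sprintf("  %d of %d records retained (%d dropped); %d eligible level-1 words (min_count = %d)\n",
              nrow(x$associations), x$n_input, x$n_dropped,
              length(x$vocabulary), x$min_count))
  invisible(x)
}

#' Quality-control summary of cleaning decisions
#'
#' Reports the fraction of records removed by the exclusion list and, when a
#' table of spelling corrections is supplied, the fraction corrected and the
#' median restricted Damerau-Levenshtein distance between original and
#' corrected tokens.
#'
#' @param filtered A `snowsem_filtered` object.
#' @param corrections Optional tibble with columns `original`, `corrected`.
#' @return A list (JSON-serialisable) with fields `n_input`, `n_removed`,
#'   `fraction_removed`, and, if corrections given, `n_corrected`,
#'   `fraction_corrected`, `median_correction_distance`.
#' @export
qc_report <- function(filtered, corrections = NULL) {
  stopifnot(inherits(filtered, "snowsem_filtered"))
  out <- list(n_input = filtered$n_input,
              n_removed = filtered$n_dropped,
              fraction_removed = filtered$n_dropped / filtered$n_input)
  if (!is.null(corrections)) {
    d <- damerau_levenshtein(normalize_response(corrections$original),
                             normalize_response(corrections$corrected))
    out$n_corrected <- nrow(corrections)
    out$fraction_corrected <- nrow(corrections) / filtered$n_input
    out$median_correction_distance <- median(d)
  }
  out
}
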