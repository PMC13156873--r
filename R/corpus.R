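#' Construct a labeled screening corpus
#'
#' A corpus is the screening universe of one simulated review: every citation
#' record carries its title, abstract and the oracle relevance label assigned
#' by the original review authors (1 = included, 0 = excluded). Internally it
#' is a tibble with class `screen_corpus` and columns `record_id`, `title`,
#' `abstract`, `label`.
#'
#' @param records A data frame with columns `record_id`, `title`, `abstract`,
#'   `label`. `record_id` values must be unique; labels must be 0/1.
#' @return A `screen_corpus` tibble.
#' @export
corpus <- function(records) {
  stopifnot(is.data.frame(records))
  needed <- c("record_id", "title", "abstract", "label")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    stop("corpus records lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  out <- tibble::as_tibble(records[needed])
  out$record_id <- as.character(out$record_id)
  out$title <- as.character(out$title)
  out$abstract <- as.character(out$abstract)
  out$title[is.na(out$title)] <- ""
  out$abstract[is.na(out$abstract)] <- ""
  out$label <- as.integer(out$label)
  validate_corpus(out)
  class(out) <- c("screen_corpus", class(tibble::tibble()))
  out
}

validate_corpus <- function(records) {
  if (anyNA(records$label) || !all(records$label %in% c(0L, 1L))) {
    bad <- which(is.na(records$label) | !(records$label %in% c(0L, 1L)))[1]
    stop("invalid label at row ", bad, ": labels must be 0 or 1")
  }
  dup <- records$record_id[duplicated(records$record_id)]
  if (length(dup) > 0) {
    stop("duplicate record_id: ", dup[1])
  }
  invisible(records)
}

#' @exportS3Method base::print
print.screen_corpus <- function(x, ...) {
  s <- corpus_summary(x)
  cat(sprintf(
    "<screen_corpus> %d records, %d relevant (%.1f%%), %d flagged empty\n",
    s$N, s$R, s$prevalence_pct, sum(empty_text(x))
  ))
  NextMethod()
}

#' Records with neither title nor abstract
#'
#' Such records stay in the corpus (dropping them would change every
#' percentage statistic) but are flagged and always ranked last by the
#' screener, since they carry no text signal.
#'
#' @param corpus A `screen_corpus`.
#' @return Logical vector, `TRUE` where both fields are empty after
#'   whitespace stripping.
#' @export
empty_text <- function(corpus) {
  stringr::str_trim(corpus$title) == "" & stringr::str_trim(corpus$abstract) == ""
}

#' Summarize corpus composition
#'
#' @param corpus A `screen_corpus`.
#' @return A list with `N` (records), `R` (relevant records) and
#'   `prevalence_pct` (share of relevant records in percent, rounded half-up
#'   to one decimal).
#' @examples
#' co <- corpus(data.frame(record_id = 1:3, title = c("a b", "c d", "e f"),
#'                         abstract = "", label = c(1, 0, 0)))
#' corpus_summary(co)$prevalence_pct  # 33.3
#' @export
corpus_summary <- function(corpus) {
  N <- nrow(corpus)
  if (N == 0) stop("cannot summarize an empty corpus")
  R <- sum(corpus$label)
  list(N = N, R = R, prevalence_pct = round_half_up(R / N * 100, 1))
}

# A corpus must contain both classes before a screening simulation can start.
check_screenable <- function(corpus) {
  s <- corpus_summary(corpus)
  if (s$N < 2 || s$R < 1 || s$R >= s$N) {
    stop("screening requires N >= 2, R >= 1 and R < N (got N=", s$N,
         ", R=", s$R, ")")
  }
  invisible(s)
}
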