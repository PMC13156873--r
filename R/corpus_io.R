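#' Read a labeled citation corpus
#'
#' Reads a screening corpus from SYNERGY-style delimited text (CSV by
#' default) or from an RIS file. Columns are mapped by name, never guessed:
#' `col_map` names the file's id/title/abstract/label columns, and
#' `label_map` translates label spellings to 0/1. Row order is preserved.
#'
#' @param path Path to the corpus file.
#' @param dialect `"synergy-delimited"` (delimited text) or `"ris"`.
#' @param col_map Named character vector mapping the roles `id`, `title`,
#'   `abstract`, `label` to column names in the file (delimited dialect).
#' @param label_map Named integer vector mapping label spellings
#'   (case-insensitive) to 0/1. Values outside the map are a hard error.
#' @param delim Field delimiter for the delimited dialect (no autodetection).
#' @param label_tag Two-letter RIS tag holding the label (RIS dialect).
#' @return A [corpus()] object.
#' @export
read_labeled_corpus <- function(path,
                                dialect = c("synergy-delimited", "ris"),
                                col_map = c(id = "record_id", title = "title",
                                            abstract = "abstract", label = "label"),
                                label_map = default_label_map(),
                                delim = ",",
                                label_tag = "C1") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "ris") {
    return(read_corpus_ris(path, label_map = label_map, label_tag = label_tag))
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), na = character(), progress = FALSE, show_col_types = FALSE)
  for (role in c("id", "label")) {
    if (!col_map[[role]] %in% names(raw)) {
      stop("required column '", col_map[[role]], "' (", role,
           ") missing from ", path)
    }
  }
  title <- if (col_map[["title"]] %in% names(raw)) raw[[col_map[["title"]]]] else ""
  abstract <- if (col_map[["abstract"]] %in% names(raw)) raw[[col_map[["abstract"]]]] else ""
  corpus(data.frame(
    record_id = raw[[col_map[["id"]]]],
    title = title,
    abstract = abstract,
    label = parse_labels(raw[[col_map[["label"]]]], label_map),
    stringsAsFactors = FALSE
  ))
}

#' Default label spellings
#'
#' The accepted label encodings: numeric 0/1 plus the common
#' included/excluded aliases found in screening exports. Anything else is an
#' error, never a silent guess.
#'
#' @return Named integer vector.
#' @export
default_label_map <- function() {
  c("0" = 0L, "1" = 1L,
    "included" = 1L, "excluded" = 0L,
    "include" = 1L, "exclude" = 0L,
    "relevant" = 1L, "irrelevant" = 0L)
}

parse_labels <- function(x, label_map) {
  key <- tolower(stringr::str_trim(as.character(x)))
  hit <- match(key, names(label_map))
  if (anyNA(hit)) {
    bad <- which(is.na(hit))[1]
    stop("unparseable label value '", x[bad], "' at data row ", bad)
  }
  as.integer(unname(label_map[hit]))
}

#' Write a corpus to disk
#'
#' Delimited output is quoted CSV (embedded delimiters and newlines survive);
#' empty titles/abstracts are written as empty fields, not missing values, so
#' a read/write round trip reproduces the corpus exactly.
#'
#' @param corpus A [corpus()] object.
#' @param path Output path.
#' @param dialect `"synergy-delimited"` or `"ris"`.
#' @param label_tag RIS tag used for the label (RIS dialect).
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path,
                         dialect = c("synergy-delimited", "ris"),
                         label_tag = "C1") {
  dialect <- match.arg(dialect)
  if (dialect == "ris") return(write_corpus_ris(corpus, path, label_tag))
  readr::write_csv(as.data.frame(corpus), path, na = "", progress = FALSE)
  invisible(path)
}

# Minimal RIS support: TY/ID/TI/AB + a configured label tag, ER terminator.
# Newlines inside fields are not representable in single-line RIS tags and
# are replaced by spaces on write.
write_corpus_ris <- function(corpus, path, label_tag = "C1") {
  flat <- function(x) gsub("[\r\n]+", " ", x)
  lines <- unlist(lapply(seq_len(nrow(corpus)), function(i) {
    c(paste0("TY  - JOUR"),
      paste0("ID  - ", flat(corpus$record_id[i])),
      paste0("TI  - ", flat(corpus$title[i])),
      paste0("AB  - ", flat(corpus$abstract[i])),
      paste0(label_tag, "  - ", corpus$label[i]),
      "ER  - ",
      "")
  }))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

read_corpus_ris <- function(path, label_map = default_label_map(),
                            label_tag = "C1") {
  lines <- readLines(path, warn = FALSE)
  tag_re <- "^([A-Z][A-Z0-9])  - ?(.*)$"
  recs <- list()
  cur <- NULL
  for (ln in lines) {
    if (!grepl(tag_re, ln)) next
    tag <- sub(tag_re, "\\1", ln)
    val <- sub(tag_re, "\\2", ln)
    if (tag == "TY") {
      cur <- list(record_id = NA_character_, title = "", abstract = "",
                  label_raw = NA_character_)
    } else if (tag == "ER") {
      if (is.null(cur)) stop("RIS record terminator before any TY tag")
      recs[[length(recs) + 1]] <- cur
      cur <- NULL
    } else if (!is.null(cur)) {
      if (tag == "ID") cur$record_id <- val
      if (tag == "TI") cur$title <- val
      if (tag == "AB") cur$abstract <- val
      if (tag == label_tag) cur$label_raw <- val
    }
  }
  if (length(recs) == 0) stop("no RIS records found in ", path)
  df <- do.call(rbind, lapply(recs, as.data.frame))
  if (anyNA(df$label_raw)) {
    stop("RIS record without label tag '", label_tag, "' at record ",
         which(is.na(df$label_raw))[1])
  }
  corpus(data.frame(record_id = df$record_id, title = df$title,
                    abstract = df$abstract,
                    label = parse_labels(df$label_raw, label_map),
                    stringsAsFactors = FALSE))
}
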