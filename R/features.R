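#' TF-IDF featurization of a corpus
#'
#' Builds the sparse term-weight matrix the relevance ranker works on. The
#' text of a record is `title + " " + abstract`, lowercased and tokenized on
#' runs of non-alphanumeric characters; tokens shorter than two characters
#' are dropped. Weights are smoothed TF-IDF,
#' `tf(t, d) * (ln((1 + N) / (1 + df(t))) + 1)`, followed by per-record
#' Euclidean (L2) normalization, so every non-empty record has unit norm.
#' The vocabulary is fit once on the whole corpus: featurization never sees
#' labels, so no oracle information can leak into the ranking.
#'
#' The tokenizer is deliberately minimal and frozen: cross-dialect TF-IDF
#' differences would otherwise make trajectories irreproducible.
#'
#' @param corpus A [corpus()].
#' @return A `tfidf_features` object: list with `X` (N x V sparse dgCMatrix,
#'   rows named by record id), `vocab` (terms in column order) and `empty`
#'   (logical; records that produced no tokens, always ranked last).
#' @export
featurize <- function(corpus) {
  text <- tolower(paste(corpus$title, corpus$abstract))
  toks <- strsplit(text, "[^a-z0-9]+")
  toks <- lapply(toks, function(t) t[nchar(t) >= 2])
  n_tok <- lengths(toks)
  if (all(n_tok == 0)) stop("corpus has no tokenizable text")
  vocab <- sort(unique(unlist(toks)))
  n <- nrow(corpus)

  doc_i <- rep.int(seq_len(n), n_tok)
  term_j <- match(unlist(toks), vocab)
  X <- Matrix::sparseMatrix(i = doc_i, j = term_j, x = 1,
                            dims = c(n, length(vocab)),
                            dimnames = list(corpus$record_id, vocab))
  # duplicate (i, j) entries summed -> raw term frequencies
  df <- Matrix::colSums(X > 0)
  idf <- log((1 + n) / (1 + df)) + 1
  X <- X %*% Matrix::Diagonal(x = idf)
  norms <- sqrt(Matrix::rowSums(X^2))
  norms[norms == 0] <- 1
  X <- Matrix::Diagonal(x = 1 / norms) %*% X
  X <- methods::as(X, "CsparseMatrix")
  dimnames(X) <- list(corpus$record_id, vocab)
  structure(list(X = X, vocab = vocab, empty = n_tok == 0),
            class = "tfidf_features")
}

#' @exportS3Method base::print
print.tfidf_features <- function(x, ...) {
  cat(sprintf("<tfidf_features> %d records x %d terms, %d empty\n",
              nrow(x$X), ncol(x$X), sum(x$empty)))
  invisible(x)
}
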