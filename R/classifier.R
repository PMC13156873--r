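#' Fit the multinomial naive-Bayes relevance model
#'
#' The ranker at the heart of the simulated screen: a two-class multinomial
#' naive Bayes over TF-IDF weighted term vectors with additive (Lidstone)
#' smoothing, the default pipeline of the screening tool the study emulates.
#' Class-conditional term probabilities are
#' `theta[t, c] = (alpha + s[t, c]) / (V * alpha + sum_t s[t, c])` where
#' `s[t, c]` sums the (fractional) TF-IDF weights of term `t` over labeled
#' records of class `c`; class priors are the labeled class frequencies.
#'
#' @param features A [featurize()] result covering (at least) the labeled
#'   records.
#' @param labeled Data frame with columns `record_id` and `label`; must
#'   contain at least one record of each class.
#' @param alpha Additive smoothing parameter (default 1).
#' @return A `relevance_model` with a [predict()] method returning
#'   `P(relevant | record)`.
#' @export
fit_classifier <- function(features, labeled, alpha = 1) {
  stopifnot(inherits(features, "tfidf_features"))
  labeled <- as.data.frame(labeled)
  rows <- match(labeled$record_id, rownames(features$X))
  if (anyNA(rows)) stop("labeled record_id not present in features: ",
                        labeled$record_id[which(is.na(rows))[1]])
  lab <- as.integer(labeled$label)
  if (length(unique(lab)) < 2) {
    stop("training set must contain both a relevant and an irrelevant record")
  }
  s1 <- Matrix::colSums(features$X[rows[lab == 1L], , drop = FALSE])
  s0 <- Matrix::colSums(features$X[rows[lab == 0L], , drop = FALSE])
  new_relevance_model(s1, s0, n1 = sum(lab == 1L), n0 = sum(lab == 0L),
                      alpha = alpha)
}

new_relevance_model <- function(s1, s0, n1, n0, alpha) {
  V <- length(s1)
  structure(list(
    log_theta1 = log(alpha + s1) - log(V * alpha + sum(s1)),
    log_theta0 = log(alpha + s0) - log(V * alpha + sum(s0)),
    log_prior1 = log(n1) - log(n1 + n0),
    log_prior0 = log(n0) - log(n1 + n0),
    alpha = alpha, n1 = n1, n0 = n0
  ), class = "relevance_model")
}

#' Predict relevance probabilities
#'
#' @param object A `relevance_model`.
#' @param features A [featurize()] result.
#' @param record_id Records to score (default: all rows of `features`).
#' @param ... Unused.
#' @return Named numeric vector of `P(relevant | record)` in `[0, 1]`;
#'   `P(relevant) + P(irrelevant) = 1` by construction.
#' @export
predict.relevance_model <- function(object, features,
                                    record_id = rownames(features$X), ...) {
  rows <- match(record_id, rownames(features$X))
  if (anyNA(rows)) stop("unknown record_id: ", record_id[which(is.na(rows))[1]])
  d <- decision_values(object, features)[rows]
  stats::setNames(stats::plogis(d), record_id)
}

# Log posterior-odds of relevance for every record in the feature matrix.
decision_values <- function(model, features) {
  w <- model$log_theta1 - model$log_theta0
  as.numeric(features$X %*% w) + (model$log_prior1 - model$log_prior0)
}

#' Rank unlabeled records by predicted relevance
#'
#' Orders the not-yet-screened records by descending `P(relevant)`. Ties are
#' broken by ascending corpus row order so that rankings are deterministic;
#' records flagged as having no text are always ranked last.
#'
#' @param model A `relevance_model`.
#' @param features A [featurize()] result.
#' @param unlabeled Character vector of record ids still unscreened.
#' @return `unlabeled` reordered by descending predicted relevance.
#' @export
rank_unlabeled <- function(model, features, unlabeled) {
  if (length(unlabeled) == 0) stop("no unlabeled records to rank")
  rows <- match(unlabeled, rownames(features$X))
  if (anyNA(rows)) stop("unknown record_id: ", unlabeled[which(is.na(rows))[1]])
  d <- decision_values(model, features)[rows]
  d[features$empty[rows]] <- -Inf
  unlabeled[order(-d, rows)]
}
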