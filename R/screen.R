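new_trajectory <- function(record_id, label, prior_len, seed, dataset, f,
                           n_s = prior_len, r_s = sum(label[seq_len(prior_len)]),
                           resamples = 0L) {
  stopifnot(length(record_id) == length(label), !anyDuplicated(record_id))
  structure(list(
    record_id = as.character(record_id),
    label = as.integer(label),
    prior_len = as.integer(prior_len),
    N = length(label),
    R = sum(as.integer(label)),
    seed = seed, dataset = dataset, f = f,
    n_s = as.integer(n_s), r_s = as.integer(r_s),
    resamples = as.integer(resamples)
  ), class = "screen_trajectory")
}

#' @exportS3Method base::print
print.screen_trajectory <- function(x, ...) {
  cat(sprintf(
    "<screen_trajectory> %s: N=%d, R=%d, prior %d (r_s=%d), f=%.2f, seed=%s\n",
    x$dataset, x$N, x$R, x$prior_len, x$r_s, x$f, format(x$seed)))
  invisible(x)
}

#' Convert a trajectory to a tibble
#'
#' One row per screening step: step index (1-based), record id, oracle label
#' and phase (`prior` or `active`). This is also the serialization layout
#' used by [run_grid()].
#'
#' @param x A `screen_trajectory`.
#' @param ... Unused.
#' @return A tibble with columns `step`, `record_id`, `label`, `phase`.
#' @export
as_tibble.screen_trajectory <- function(x, ...) {
  tibble::tibble(
    step = seq_len(x$N),
    record_id = x$record_id,
    label = x$label,
    phase = rep(c("prior", "active"), c(x$prior_len, x$N - x$prior_len))
  )
}

#' Draw the prior (training) sample
#'
#' The initial randomly drawn, fully labeled subset that seeds the model —
#' the simulated analogue of the records a reviewer screens manually before
#' switching the ranker on. Sample size is `max(2, round_half_up(f * N))`,
#' drawn uniformly without replacement.
#'
#' A classifier needs both classes, so by default a sample lacking a
#' relevant or an irrelevant record is redrawn under an incremented sub-seed
#' up to `max_attempts` times (`policy = "resample"`), and the number of
#' redraws is recorded: at small `f` and low prevalence this conditioning
#' biases the sample's relevant count upward, which is exactly the situation
#' the count-extrapolation stop rule faces in practice.
#' `policy = "accept-degenerate"` returns the first draw unconditionally.
#'
#' @param corpus A [corpus()].
#' @param f Prior fraction in (0, 1).
#' @param seed Integer seed.
#' @param policy `"resample"` or `"accept-degenerate"`.
#' @param max_attempts Resampling budget before a hard error.
#' @return A `prior_sample`: list with `record_id`, `n_s`, `r_s`, `f`,
#'   `resamples`.
#' @export
draw_prior <- function(corpus, f, seed,
                       policy = c("resample", "accept-degenerate"),
                       max_attempts = 1000L) {
  policy <- match.arg(policy)
  if (f <= 0 || f >= 1) stop("f must be in (0, 1)")
  N <- nrow(corpus)
  n_s <- max(2L, as.integer(round_half_up(f * N)))
  draw <- function(s) with_rng(s, sample.int(N, n_s))
  idx <- draw(seed)
  attempts <- 0L
  if (policy == "resample") {
    while (length(unique(corpus$label[idx])) < 2) {
      attempts <- attempts + 1L
      if (attempts >= max_attempts) {
        stop("could not draw a two-class prior sample in ", max_attempts,
             " attempts (R=", sum(corpus$label), ", n_s=", n_s, ")")
      }
      idx <- draw(mix_seed(seed, attempts))
    }
  }
  structure(list(record_id = corpus$record_id[idx], n_s = n_s,
                 r_s = sum(corpus$label[idx]), f = f, resamples = attempts),
            class = "prior_sample")
}

#' Simulate one active-learning screening run
#'
#' The full screening loop of a technology-assisted review, run to
#' exhaustion: a random prior sample is screened first (in sampling order),
#' then the loop alternates between fitting the naive-Bayes ranker on all
#' labels revealed so far, ranking the unscreened remainder by predicted
#' relevance, and revealing the oracle label of the top-ranked record
#' (certainty-based selection). With `retrain_every > 1` the current ranking
#' is consumed for that many reveals between refits. Stop criteria are never
#' applied inside the loop — every run screens all `N` records, and stopping
#' rules are evaluated retrospectively on the recorded trajectory.
#'
#' @param corpus A [corpus()] with both classes present.
#' @param f Prior fraction in (0, 1).
#' @param seed Integer seed (drives the prior draw; the rest of the loop is
#'   deterministic).
#' @param retrain_every Reveals between refits (default 1: retrain after
#'   every screening decision).
#' @param alpha Naive-Bayes smoothing parameter.
#' @param prior_policy Passed to [draw_prior()].
#' @param features Optional precomputed [featurize()] result for `corpus`
#'   (shared across replicates by [run_grid()]).
#' @return A `screen_trajectory`: a permutation of the corpus with the
#'   revealed labels, prior length and prior-sample statistics attached.
#' @export
simulate_screening <- function(corpus, f, seed, retrain_every = 1L,
                               alpha = 1, prior_policy = "resample",
                               features = NULL) {
  check_screenable(corpus)
  if (retrain_every < 1) stop("retrain_every must be >= 1")
  features <- features %||% featurize(corpus)
  prior <- draw_prior(corpus, f, seed, policy = prior_policy)
  N <- nrow(corpus)
  V <- ncol(features$X)

  revealed <- match(prior$record_id, corpus$record_id)
  is_revealed <- logical(N)
  is_revealed[revealed] <- TRUE
  labels <- corpus$label

  # Incremental naive-Bayes sufficient statistics: per-class TF-IDF column
  # sums and class counts, updated as labels are revealed. Equivalent to
  # refitting fit_classifier() on the revealed set at every step (tested),
  # but O(nnz) per reveal instead of O(nnz revealed).
  s1 <- numeric(V); s0 <- numeric(V); n1 <- 0L; n0 <- 0L
  add_record <- function(row) {
    x <- features$X[row, ]
    if (labels[row] == 1L) { s1 <<- s1 + x; n1 <<- n1 + 1L }
    else { s0 <<- s0 + x; n0 <<- n0 + 1L }
  }
  for (row in revealed) add_record(row)

  order_out <- integer(N)
  order_out[seq_along(revealed)] <- revealed
  pos <- length(revealed)
  queue <- integer(0)

  while (pos < N) {
    if (length(queue) == 0) {
      if (n1 == 0L || n0 == 0L) {
        # degenerate training set (accept-degenerate policy): no ranking
        # signal, fall back to corpus order
        queue <- which(!is_revealed)
      } else {
        w <- (log(alpha + s1) - log(V * alpha + sum(s1))) -
             (log(alpha + s0) - log(V * alpha + sum(s0)))
        d <- as.numeric(features$X %*% w)
        d[features$empty] <- -Inf
        cand <- which(!is_revealed)
        queue <- cand[order(-d[cand], cand)]
        queue <- utils::head(queue, retrain_every)
      }
    }
    row <- queue[1]
    queue <- queue[-1]
    pos <- pos + 1L
    order_out[pos] <- row
    is_revealed[row] <- TRUE
    add_record(row)
  }

  new_trajectory(record_id = corpus$record_id[order_out],
                 label = labels[order_out],
                 prior_len = length(revealed), seed = seed,
                 dataset = attr(corpus, "dataset_name") %||% "corpus", f = f,
                 n_s = prior$n_s, r_s = prior$r_s,
                 resamples = prior$resamples)
}
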