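#' Specify a synthetic labeled corpus
#'
#' Defines the generative model for a synthetic screening corpus: a rare
#' relevant class whose word usage is separated from the background by a
#' topic-term block. Each record's tokens are drawn from a two-component
#' multinomial mixture. Background records (and a `hard_fraction` subset of
#' relevant records) draw from a Zipf-weighted background distribution over
#' the non-topic vocabulary; the remaining relevant records draw from
#' `delta * topic + (1 - delta) * background`. `delta = 0` makes the classes
#' statistically identical, `delta = 1` gives them disjoint vocabularies.
#' "Hard" relevants are textually indistinguishable from the background and
#' therefore surface late in a ranked screen, emulating the late discoveries
#' that make early stopping risky.
#'
#' @param N Total number of records.
#' @param R Number of relevant records. Give either `R` or `prevalence_pct`.
#' @param prevalence_pct Relevant share in percent; converted to
#'   `R = round_half_up(N * prevalence_pct / 100)`.
#' @param vocab_size Number of distinct terms (>= 2); the topic block is 10%
#'   of the vocabulary (at least 2 terms).
#' @param doc_length Mean tokens per record (Poisson, floor 3).
#' @param delta Class separability in `[0, 1]`.
#' @param hard_fraction Fraction of relevant records drawn from the
#'   background distribution; `floor(hard_fraction * R)` records.
#' @param seed Integer seed; the same spec always regenerates the identical
#'   corpus.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(N, R = NULL, prevalence_pct = NULL,
                           vocab_size = 300, doc_length = 40,
                           delta = 0.8, hard_fraction = 0.1, seed = 1) {
  if (is.null(R)) {
    if (is.null(prevalence_pct)) stop("give either R or prevalence_pct")
    R <- as.integer(round_half_up(N * prevalence_pct / 100))
  }
  if (R < 1 || R >= N) stop("need 1 <= R < N (got R=", R, ", N=", N, ")")
  if (vocab_size < 2) stop("vocab_size must be >= 2")
  if (delta < 0 || delta > 1) stop("delta must be in [0, 1]")
  if (hard_fraction < 0 || hard_fraction > 1) stop("hard_fraction must be in [0, 1]")
  structure(list(N = as.integer(N), R = as.integer(R),
                 vocab_size = as.integer(vocab_size),
                 doc_length = doc_length, delta = delta,
                 hard_fraction = hard_fraction, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic labeled corpus
#'
#' @param spec A [synthetic_spec()].
#' @return A [corpus()] with exactly `spec$R` records labeled 1. Record ids
#'   are `d0001, d0002, ...`; relevant records are scattered uniformly over
#'   the id sequence. All tokens go to the abstract field and the first five
#'   tokens are repeated as the title, exercising the screener's
#'   title+abstract concatenation path.
#' @examples
#' co <- generate_corpus(synthetic_spec(N = 200, prevalence_pct = 5, seed = 7))
#' corpus_summary(co)$R  # 10
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_rng(spec$seed, {
    V <- spec$vocab_size
    Vt <- max(2L, as.integer(ceiling(0.1 * V)))
    if (Vt >= V) Vt <- V - 1L
    vocab <- sprintf("tok%04d", seq_len(V))
    bg_idx <- seq_len(V - Vt)
    topic_idx <- (V - Vt + 1):V
    p_bg <- numeric(V)
    p_bg[bg_idx] <- 1 / seq_along(bg_idx)       # Zipf background frequencies
    p_bg <- p_bg / sum(p_bg)
    p_topic <- numeric(V)
    p_topic[topic_idx] <- 1 / seq_along(topic_idx)
    p_topic <- p_topic / sum(p_topic)
    p_rel <- spec$delta * p_topic + (1 - spec$delta) * p_bg

    labels <- integer(spec$N)
    labels[sample.int(spec$N, spec$R)] <- 1L
    rel_rows <- which(labels == 1L)
    n_hard <- floor(spec$hard_fraction * spec$R)
    hard_rows <- if (n_hard > 0) sample(rel_rows, n_hard) else integer(0)

    len <- pmax(3L, stats::rpois(spec$N, spec$doc_length))
    text <- character(spec$N)
    for (i in seq_len(spec$N)) {
      p <- if (labels[i] == 1L && !(i %in% hard_rows)) p_rel else p_bg
      counts <- stats::rmultinom(1, len[i], p)[, 1]
      toks <- rep(vocab, counts)
      text[i] <- paste(sample(toks), collapse = " ")
    }
    title <- vapply(strsplit(text, " ", fixed = TRUE), function(t) {
      paste(utils::head(t, 5), collapse = " ")
    }, character(1))
    corpus(data.frame(record_id = sprintf("d%04d", seq_len(spec$N)),
                      title = title, abstract = text, label = labels,
                      stringsAsFactors = FALSE))
  })
}

#' Analytic reference rankers
#'
#' Produce screening trajectories from three closed-form rankers used as
#' oracles for the evaluation metrics: `perfect` presents every relevant
#' record first, `adversarial` presents them all last, and `random` screens
#' in uniformly random order. All three have an empty prior phase.
#'
#' @param corpus A [corpus()].
#' @param mode `"perfect"`, `"random"` or `"adversarial"`.
#' @param seed Seed for the random mode.
#' @return A `screen_trajectory` (see [simulate_screening()]).
#' @export
reference_rankers <- function(corpus, mode = c("perfect", "random", "adversarial"),
                              seed = 1) {
  mode <- match.arg(mode)
  n <- nrow(corpus)
  ord <- switch(mode,
    perfect = order(-corpus$label, seq_len(n)),
    adversarial = order(corpus$label, seq_len(n)),
    random = with_rng(seed, sample.int(n))
  )
  new_trajectory(record_id = corpus$record_id[ord],
                 label = corpus$label[ord],
                 prior_len = 0L, seed = seed,
                 dataset = paste0("reference-", mode), f = 0)
}
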