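# Independent brute-force oracles. These deliberately share no code with the
# package: plain loops over label sequences, used to cross-check every
# trajectory-evaluation operation.

# trajectory from a bare label vector
lab_traj <- function(labels, prior_len = 0L, n_s = max(prior_len, 1L),
                     r_s = sum(labels[seq_len(prior_len)])) {
  screenstop:::new_trajectory(
    record_id = paste0("r", seq_along(labels)), label = labels,
    prior_len = prior_len, seed = 0L, dataset = "toy", f = 0.1,
    n_s = n_s, r_s = r_s
  )
}

# longest run of 0s strictly between two 1s, by explicit scan
bf_interior_gap <- function(labels) {
  best <- 0L; run <- 0L; seen_one <- FALSE
  for (x in labels) {
    if (x == 1L) {
      if (seen_one && run > best) best <- run
      seen_one <- TRUE
      run <- 0L
    } else {
      run <- run + 1L
    }
  }
  best
}

# first position where cumulative 1s reach R_hat; N if never
bf_stop_c1 <- function(labels, R_hat) {
  if (R_hat == 0) return(0L)
  tot <- 0L
  for (i in seq_along(labels)) {
    tot <- tot + labels[i]
    if (tot >= R_hat) return(i)
  }
  length(labels)
}

# position where a run of c consecutive 0s completes, scanning from `start`
bf_stop_c2 <- function(labels, c, start = 1L) {
  run <- 0L
  if (start <= length(labels)) {
    for (i in start:length(labels)) {
      run <- if (labels[i] == 0L) run + 1L else 0L
      if (run >= c) return(i)
    }
  }
  length(labels)
}

# smallest consecutive-irrelevant threshold missing nothing, by trying all
bf_min_safe_c <- function(labels, start = 1L) {
  last_rel <- max(which(labels == 1L))
  for (c in 1:(length(labels) + 1L)) {
    stop_at <- bf_stop_c2(labels, c, start)
    if (stop_at >= last_rel) return(c)
  }
  stop("unreachable")
}

bf_last_rel_pct <- function(labels) {
  max(which(labels == 1L)) / length(labels) * 100
}

# dense loop-based smoothed TF-IDF with L2 norm, independent of featurize()
bf_tfidf <- function(texts) {
  toks <- lapply(texts, function(s) {
    t <- strsplit(tolower(s), "[^a-z0-9]+")[[1]]
    t[nchar(t) >= 2]
  })
  vocab <- sort(unique(unlist(toks)))
  n <- length(texts)
  M <- matrix(0, n, length(vocab), dimnames = list(NULL, vocab))
  for (i in seq_len(n)) for (tk in toks[[i]]) M[i, tk] <- M[i, tk] + 1
  for (j in seq_along(vocab)) {
    df <- sum(M[, j] > 0)
    M[, j] <- M[, j] * (log((1 + n) / (1 + df)) + 1)
  }
  for (i in seq_len(n)) {
    nrm <- sqrt(sum(M[i, ]^2))
    if (nrm > 0) M[i, ] <- M[i, ] / nrm
  }
  M
}

# uniformly random label trajectory
rand_traj <- function(N, R, prior_len = 0L) {
  labels <- integer(N)
  labels[sample.int(N, R)] <- 1L
  lab_traj(labels, prior_len = prior_len)
}

toy_corpus <- function(titles, abstracts = "", labels) {
  corpus(data.frame(record_id = paste0("t", seq_along(titles)),
                    title = titles, abstract = abstracts, label = labels,
                    stringsAsFactors = FALSE))
}
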