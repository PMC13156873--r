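test_that("tf-idf weights match a hand-rolled dense oracle on a toy corpus", {
  co <- toy_corpus(titles = c("alpha beta", "alpha alpha"), labels = c(1, 0))
  fe <- featurize(co)
  oracle <- bf_tfidf(paste(co$title, co$abstract))
  expect_equal(unname(as.matrix(fe$X)), unname(oracle), tolerance = 1e-12)
  # spot-check the idf formula itself: df(alpha)=2, df(beta)=1, N=2
  idf_beta <- log((1 + 2) / (1 + 1)) + 1
  expect_equal(as.numeric(fe$X[1, "beta"]),
               idf_beta / sqrt(1^2 + idf_beta^2), tolerance = 1e-12)
})

test_that("every non-empty record has a unit-norm non-negative vector", {
  co <- generate_corpus(synthetic_spec(N = 50, R = 5, vocab_size = 60, seed = 9))
  fe <- featurize(co)
  expect_true(all(fe$X@x >= 0))
  expect_equal(unname(sqrt(Matrix::rowSums(fe$X^2))), rep(1, 50),
               tolerance = 1e-12)
})

test_that("a single repeated term normalizes to 1.0 and duplicates get identical rows", {
  co <- toy_corpus(titles = c("gene gene gene", "same words", "same words"),
                   labels = c(1, 0, 0))
  fe <- featurize(co)
  expect_equal(as.numeric(fe$X[1, "gene"]), 1.0)
  expect_equal(sum(fe$X[1, ] != 0), 1)
  expect_equal(as.numeric(fe$X[2, ]), as.numeric(fe$X[3, ]))
})

test_that("tokenizer lowercases, splits on non-alphanumerics, drops 1-char tokens", {
  co <- toy_corpus(titles = "Gene-EXPRESSION: a B12 x!", labels = 1)
  fe <- featurize(co)
  expect_setequal(fe$vocab, c("gene", "expression", "b12"))
  expect_error(featurize(toy_corpus(titles = c("a !", "-"), labels = c(1, 0))),
               "no tokenizable text")
})

test_that("two-class posterior on disjoint vocabularies matches direct enumeration", {
  co <- toy_corpus(titles = c("heart attack", "soil microbe"), labels = c(1, 0))
  fe <- featurize(co)
  model <- fit_classifier(fe, data.frame(record_id = c("t1", "t2"), label = c(1, 0)))
  p <- predict(model, fe)
  expect_gt(p[["t1"]], 0.5)
  expect_lt(p[["t2"]], 0.5)

  # direct enumeration of the smoothed two-class posterior for record t1
  x <- as.numeric(fe$X[1, ])
  V <- length(x)
  s1 <- as.numeric(fe$X[1, ]); s0 <- as.numeric(fe$X[2, ])
  log_lik <- function(s) sum(x * (log(1 + s) - log(V + sum(s))))
  expected <- 1 / (1 + exp(log_lik(s0) - log_lik(s1)))  # equal priors
  expect_equal(p[["t1"]], expected, tolerance = 1e-12)
})

test_that("relevance probabilities are complementary and bounded", {
  co <- generate_corpus(synthetic_spec(N = 40, R = 6, seed = 4))
  fe <- featurize(co)
  model <- fit_classifier(fe, data.frame(record_id = co$record_id[1:20],
                                         label = co$label[1:20]))
  p <- predict(model, fe)
  expect_true(all(p >= 0 & p <= 1))
  # P(irrelevant) recomputed by swapping the classes
  swapped <- fit_classifier(fe, data.frame(record_id = co$record_id[1:20],
                                           label = 1L - co$label[1:20]))
  expect_equal(unname(p + predict(swapped, fe)), rep(1, 40), tolerance = 1e-9)
})

test_that("duplicating the training data with proportional smoothing leaves
           the model unchanged, and plain duplication keeps class separation", {
  co <- generate_corpus(synthetic_spec(N = 60, R = 8, delta = 0.9, seed = 11))
  fe <- featurize(co)
  train <- data.frame(record_id = co$record_id[1:30], label = co$label[1:30])
  doubled <- rbind(train, train)
  test_ids <- co$record_id[31:60]

  # 2x data with 2x alpha is exactly the same smoothed model
  r1 <- rank_unlabeled(fit_classifier(fe, train, alpha = 1), fe, test_ids)
  r2 <- rank_unlabeled(fit_classifier(fe, doubled, alpha = 2), fe, test_ids)
  expect_identical(r1, r2)
  expect_equal(predict(fit_classifier(fe, train, alpha = 1), fe),
               predict(fit_classifier(fe, doubled, alpha = 2), fe),
               tolerance = 1e-12)

  # plain duplication shifts theta toward the MLE but cannot flip the
  # relevant/irrelevant separation on a separable corpus
  sep <- generate_corpus(synthetic_spec(N = 80, R = 10, delta = 1,
                                        hard_fraction = 0, seed = 12))
  fes <- featurize(sep)
  tr2 <- data.frame(record_id = sep$record_id[1:40], label = sep$label[1:40])
  held <- sep$record_id[41:80]
  held_lab <- sep$label[41:80]
  for (lab_set in list(tr2, rbind(tr2, tr2))) {
    ranked <- rank_unlabeled(fit_classifier(fes, lab_set), fes, held)
    k <- sum(held_lab)
    expect_equal(sum(held_lab[match(ranked[seq_len(k)], held)]), k)
  }
})

test_that("fitting demands both classes", {
  co <- toy_corpus(titles = c("aa bb", "cc dd"), labels = c(1, 0))
  fe <- featurize(co)
  expect_error(fit_classifier(fe, data.frame(record_id = "t1", label = 1)),
               "both")
})

test_that("ranking ties break by corpus row order and handle singletons", {
  co <- toy_corpus(titles = c("train rel", "train irr", rep("same text", 3)),
                   labels = c(1, 0, 0, 0, 0))
  fe <- featurize(co)
  model <- fit_classifier(fe, data.frame(record_id = c("t1", "t2"),
                                         label = c(1, 0)))
  expect_identical(rank_unlabeled(model, fe, c("t5", "t3", "t4")),
                   c("t3", "t4", "t5"))
  expect_identical(rank_unlabeled(model, fe, "t4"), "t4")
  expect_error(rank_unlabeled(model, fe, character(0)), "no unlabeled")
})

test_that("records with no text rank last regardless of the model", {
  co <- corpus(data.frame(record_id = c("x1", "x2", "x3"),
                          title = c("topic term", "", "topic term"),
                          abstract = c("more text", "", "words here"),
                          label = c(1, 0, 0)))
  fe <- featurize(co)
  model <- fit_classifier(fe, data.frame(record_id = c("x1", "x3"),
                                         label = c(1, 0)))
  ranked <- rank_unlabeled(model, fe, c("x2", "x1", "x3"))
  expect_equal(ranked[3], "x2")
})
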