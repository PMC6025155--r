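test_that("build_dataset integer-codes docs and labels and excludes empty ones", {
  ds <- build_dataset(list(d1 = c("x", "y", "x")), list(d1 = "lab"))
  expect_lte(length(ds$vocab), 3)
  expect_equal(ds$vocab[ds$docs[[1]]$tokens], c("x", "y", "x"))

  ds2 <- build_dataset(list(a = c("x", "y"), b = c("x", "y")),
                       list(a = "l1", b = "l2"))
  expect_equal(ds2$docs[[1]]$tokens, ds2$docs[[2]]$tokens)
  expect_false(identical(ds2$docs[[1]]$labels, ds2$docs[[2]]$labels))

  expect_message(ds3 <- build_dataset(list(a = "x", b = character()),
                                      list(a = "l1", b = "l2")),
                 "excluded")
  expect_equal(ds3$doc_ids, "a")
})

test_that("dataset from the generator matches its label-topic map after filtering", {
  cfg <- synth_config(n_posts = 80, seed = 23)
  g <- generate_corpus(cfg)
  lb <- apply_label_filters(g$corpus, pipeline_config(label_min_doc_count = 10))
  tk <- lapply(g$corpus$posts, function(p) tokenize(p$text))
  ds <- build_dataset(tk, lb$labels)
  freq <- table(unlist(lapply(g$corpus$posts, function(p) unique(p$labels))))
  expect_setequal(ds$label_names,
                  intersect(names(cfg$label_topic_map),
                            names(freq)[freq >= 10]))
})

test_that("a single allowed label forces a point-mass doc_topic", {
  ds <- build_dataset(list(d = c("w1", "w2", "w3", "w1")), list(d = "only"))
  m <- train_cvb0(ds, n_iterations = 20, seed = 1)
  expect_equal(unname(m$doc_topic["d", "only"]), 1.0)
})

test_that("disjoint label vocabularies concentrate topic mass (>= 0.9)", {
  fix <- separated_docs()
  ds <- build_dataset(fix$docs, fix$labels)
  m <- train_cvb0(ds, n_iterations = 100, seed = 2)
  for (k in seq_along(fix$vocab)) {
    own <- intersect(fix$vocab[[k]], m$vocab)
    mass <- sum(m$topic_word[sprintf("lab%d", k), own])
    expect_gte(mass, 0.9)
  }
  # and each topic's top terms come from its own vocabulary
  tops <- top_terms(m, 5)
  for (k in seq_along(fix$vocab)) {
    expect_true(all(tops[[sprintf("lab%d", k)]] %in% fix$vocab[[k]]))
  }
})

test_that("training is bitwise reproducible given the seed", {
  # all labels allowed: initialization actually matters here (with one
  # label per doc the variational distributions are point masses and every
  # seed gives the same counts)
  fix <- separated_docs(seed = 7, all_labels = TRUE)
  ds <- build_dataset(fix$docs, fix$labels)
  m1 <- train_cvb0(ds, n_iterations = 30, seed = 11)
  m2 <- train_cvb0(ds, n_iterations = 30, seed = 11)
  expect_identical(m1$topic_word, m2$topic_word)
  expect_identical(m1$doc_topic, m2$doc_topic)
  m3 <- train_cvb0(ds, n_iterations = 30, seed = 12)
  expect_false(identical(m3$topic_word, m1$topic_word))
})

test_that("n_iterations = 0 returns a valid initialized model", {
  fix <- separated_docs(n_labels = 2, docs_per_label = 3)
  ds <- build_dataset(fix$docs, fix$labels)
  m <- train_cvb0(ds, n_iterations = 0, seed = 5)
  expect_equal(unname(rowSums(m$topic_word)), rep(1, 2), tolerance = 1e-12)
  expect_equal(unname(rowSums(m$doc_topic)), rep(1, nrow(m$doc_topic)),
               tolerance = 1e-12)
})

test_that("infer_doc: point mass, argmax on exclusive vocabulary, uniform on empty", {
  fix <- separated_docs()
  ds <- build_dataset(fix$docs, fix$labels)
  m <- train_cvb0(ds, n_iterations = 100, seed = 3)

  th1 <- infer_doc(m, c("lab1_word01", "lab1_word02"), "lab1")
  expect_equal(unname(th1["lab1"]), 1)

  th2 <- infer_doc(m, rep(fix$vocab[[2]][1:4], 3),
                   c("lab1", "lab2", "lab3"))
  expect_equal(names(which.max(th2)), "lab2")
  expect_equal(sum(th2), 1, tolerance = 1e-12)

  th3 <- infer_doc(m, character(), c("lab1", "lab2"))
  expect_equal(unname(th3[c("lab1", "lab2")]), c(0.5, 0.5))
  expect_equal(unname(th3["lab3"]), 0)
})

test_that("perplexity closed forms: uniform model = V, perfect model = 1", {
  # hand-built model with uniform topic-word rows
  V <- 7
  vocab <- sprintf("w%d", 1:V)
  m <- structure(list(
    topic_word = matrix(1 / V, 2, V, dimnames = list(c("l1", "l2"), vocab)),
    doc_topic = NULL, alpha = 0.1, beta = 0.01, vocab = vocab,
    label_names = c("l1", "l2")), class = "kitm_model")
  ds <- build_dataset(list(d = sample(vocab, 20, replace = TRUE)),
                      list(d = c("l1", "l2")))
  expect_equal(perplexity(m, ds)$value, V, tolerance = 1e-9)

  # degenerate one-word vocabulary: every token predicted with probability 1
  m1 <- structure(list(
    topic_word = matrix(1, 1, 1, dimnames = list("l", "only")),
    doc_topic = NULL, alpha = 0.1, beta = 0.01, vocab = "only",
    label_names = "l"), class = "kitm_model")
  ds1 <- build_dataset(list(d = rep("only", 10)), list(d = "l"))
  expect_equal(perplexity(m1, ds1)$value, 1, tolerance = 1e-12)
})

test_that("perplexity is base-invariant and errors with nothing to score", {
  fix <- separated_docs(n_labels = 2, docs_per_label = 4)
  ds <- build_dataset(fix$docs, fix$labels)
  m <- train_cvb0(ds, n_iterations = 20, seed = 4)
  p2 <- perplexity(m, ds, base = 2)
  p10 <- perplexity(m, ds, base = 10)
  expect_equal(p2$value, p10$value, tolerance = 1e-12)

  oov <- build_dataset(list(d = c("unseen1", "unseen2")), list(d = "lab1"))
  expect_error(suppressMessages(perplexity(m, oov)), "no scorable")
})

test_that("training perplexity is non-increasing over early iterations", {
  # all labels allowed per doc: inference has real work to do, yet the
  # separated vocabularies make the objective improve steadily
  fix <- separated_docs(seed = 10, all_labels = TRUE)
  ds <- build_dataset(fix$docs, fix$labels)
  pk <- vapply(seq(0, 50, by = 10), function(it) {
    m <- train_cvb0(ds, n_iterations = it, seed = 6)
    perplexity(m, ds, method = "full")$value
  }, numeric(1))
  expect_true(all(diff(pk) <= 1e-8))
})

test_that("support restriction and normalization hold after training", {
  g <- generate_corpus(synth_config(n_posts = 60, doc_length_mean = 25,
                                    seed = 33))
  lb <- apply_label_filters(g$corpus, pipeline_config(label_min_doc_count = 5))
  tk <- lapply(g$corpus$posts, function(p) tokenize(p$text))
  ds <- build_dataset(tk, lb$labels)
  m <- train_cvb0(ds, n_iterations = 50, seed = 7)
  for (d in seq_along(ds$docs)) {
    allowed <- ds$label_names[ds$docs[[d]]$labels]
    outside <- setdiff(ds$label_names, allowed)
    expect_identical(unname(m$doc_topic[d, outside]),
                     rep(0, length(outside)))
  }
  expect_true(all(abs(rowSums(m$topic_word) - 1) < 1e-9))
  expect_true(all(abs(rowSums(m$doc_topic) - 1) < 1e-9))
})

test_that("top_terms: k = 0, full ranking, deterministic shape", {
  fix <- separated_docs(n_labels = 2, docs_per_label = 3)
  ds <- build_dataset(fix$docs, fix$labels)
  m <- train_cvb0(ds, n_iterations = 10, seed = 8)
  expect_true(all(lengths(top_terms(m, 0)) == 0))
  expect_true(all(lengths(top_terms(m, 10000)) == length(m$vocab)))
  expect_identical(top_terms(m, 5), top_terms(m, 5))
})
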