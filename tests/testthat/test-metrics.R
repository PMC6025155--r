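test_that("EKR is the concept-bearing fraction, 0 on empty text", {
  kb <- load_toy_kb(toy_kb_path())
  # 10 raw tokens, 4 of them knowledge-base terms
  toks <- c("aspirin", "headache", "trazodone", "grogginess",
            "xx1", "xx2", "xx3", "xx4", "xx5", "xx6")
  enc <- encode_terms(toks, kb)
  expect_equal(ekr(enc), 0.4)
  expect_equal(ekr(encode_terms(c("nothing", "matches"), kb)), 0)
  expect_equal(ekr(encode_terms(character(), kb)), 0)
})

test_that("EKR of a fixture post equals a hand-traced count", {
  kb <- load_toy_kb(toy_kb_path())
  crp <- example_posts()
  text <- crp$posts[["t2p4"]]$text
  # hand trace: tokens after the three tokenizer rules
  toks <- tokenize(text)
  expect_equal(toks, c("trazodone", "nonaddictive", "no", "grogginess",
                       "and", "something", "that", "i", "d", "suggest",
                       "to", "anyone"))
  # hand count: "trazodone" and "grogginess" are in the toy KB -> 2 of 12
  enc <- encode_terms(toks, kb, post_id = "t2p4")
  expect_equal(ekr(enc), 2 / 12)
  expect_equal(ekr(enc, unique = TRUE), 2 / 12)
})

test_that("LKR on a chain follows the closed form", {
  kb <- chain_kb(3)  # A1 - A2 - A3
  enc_codes <- "A1"
  expect_equal(lkr(enc_codes, kb, m = 1), 1.0)  # k_r = 2, k_d = 1
  expect_equal(lkr(enc_codes, kb, m = 2), 2.0)  # k_r = 3
  expect_equal(lkr(enc_codes, kb, m = 5), 2.0)  # exhausted chain
  expect_error(lkr(character(), kb, m = 1), "k_d")
  expect_error(lkr("A1", kb, m = 0), "m must be")
})

test_that("reachable-mode LKR equals a BFS oracle on random fixtures", {
  skip_if_not_installed("igraph")
  for (seed in c(2, 5, 8)) {
    kb <- random_kb(18, 30, seed = seed)
    ora <- igraph_distances(kb)
    names18 <- vapply(kb$concepts, `[[`, character(1), "preferred_name")
    for (trial in 1:4) {
      set.seed(seed * 100 + trial)
      anchors <- sample(names(kb$concepts), 3)
      for (m in 1:3) {
        got <- lkr(anchors, kb, m, edges = "all")
        reach <- colnames(ora)[apply(ora[anchors, , drop = FALSE], 2,
                                     function(col) any(col <= m))]
        k_r <- length(reach)  # includes the anchors themselves
        expect_equal(got, (k_r - 3) / 3, info = paste(seed, trial, m))
      }
    }
  }
})

test_that("path-count LKR equals exhaustive path enumeration", {
  kb <- random_kb(8, 12, seed = 6)
  adj <- matrix(FALSE, 8, 8, dimnames = list(names(kb$concepts),
                                             names(kb$concepts)))
  adj[cbind(kb$relations$source, kb$relations$target)] <- TRUE
  adj[cbind(kb$relations$target, kb$relations$source)] <- TRUE
  # oracle: recursively enumerate walks of exactly m edges
  count_walks <- function(from, m) {
    if (m == 0) return(1L)
    nb <- colnames(adj)[adj[from, ]]
    sum(vapply(nb, count_walks, integer(1), m = m - 1L))
  }
  anchors <- names(kb$concepts)[c(1, 4)]
  for (m in 1:3) {
    k_r <- sum(vapply(anchors, count_walks, integer(1), m = m))
    expect_equal(lkr(anchors, kb, m, mode = "path_count", edges = "all"),
                 (k_r - 2) / 2, info = m)
  }
})

test_that("KCR closed forms: all found = 1, none = 0, planted 7/10 = 0.7", {
  kb <- random_kb(12, 18, seed = 9)
  rel <- kb$relations
  copied <- data.frame(source_code = rel$source[1:7],
                       target_code = rel$target[1:7],
                       stringsAsFactors = FALSE)
  expect_equal(kcr(copied, kb), 1.0)

  # 3 planted random pairs at distance > 1 (or unknown codes)
  bogus <- data.frame(source_code = c("ZZ1", "ZZ2", "ZZ3"),
                      target_code = c("ZZ4", "ZZ5", "ZZ6"),
                      stringsAsFactors = FALSE)
  expect_equal(kcr(bogus, kb), 0.0)
  expect_equal(kcr(rbind(copied, bogus), kb), 0.7)
  expect_message(v <- kcr(copied[0, ], kb), "convention")
  expect_equal(v, 1)
})

test_that("metric ranges and LKR monotonicity hold over random posts", {
  for (seed in c(1, 4)) {
    kb <- random_kb(20, 32, seed = seed)
    names20 <- vapply(kb$concepts, `[[`, character(1), "preferred_name")
    set.seed(seed)
    for (trial in 1:3) {
      toks <- c(sample(names20, 4), sprintf("fill%d", 1:6))
      enc <- encode_terms(sample(toks), kb, post_id = "r")
      expect_gte(ekr(enc), 0); expect_lte(ekr(enc), 1)
      vals <- vapply(1:4, function(m) lkr(enc, kb, m, edges = "all"),
                     numeric(1))
      expect_true(all(vals >= 0))
      expect_true(all(diff(vals) >= 0))
      items <- extract_relation_items(enc, kb)
      if (nrow(items)) {
        v <- kcr(items, kb)
        expect_gte(v, 0); expect_lte(v, 1)
      }
    }
  }
})

test_that("LKR agrees with expansion frontiers across modules", {
  kb <- random_kb(20, 32, seed = 14)
  names20 <- vapply(kb$concepts, `[[`, character(1), "preferred_name")
  enc <- encode_terms(c(names20[3], names20[11], "pad"), kb, post_id = "x")
  k_d <- enc$n_unique_concepts
  for (m in 1:3) {
    ex <- expand_text(enc, kb, m, edges = "all")
    cum <- unique(unlist(ex$latent_terms))
    got <- lkr(enc, kb, m, edges = "all")
    expect_equal(got, length(cum) / k_d)
  }
})

test_that("EKR ignores relation edits; LKR ignores redundant synonyms", {
  concepts <- list(concept_rec("A", "worda"), concept_rec("B", "wordb"),
                   concept_rec("C", "wordc"))
  rel <- data.frame(source = "A", label = "IS_A", target = "B",
                    stringsAsFactors = FALSE)
  kb1 <- knowledge_base("k", concepts, rel)
  rel2 <- rbind(rel, data.frame(source = "B", label = "IS_A", target = "C"))
  kb2 <- knowledge_base("k", concepts, rel2)
  toks <- c("worda", "other", "stuff")
  expect_equal(ekr(encode_terms(toks, kb1)), ekr(encode_terms(toks, kb2)))

  concepts2 <- concepts
  concepts2[[1]]$synonyms <- "worda2"   # synonym for already-matched concept
  kb3 <- knowledge_base("k", concepts2, rel)
  expect_equal(lkr(encode_terms(toks, kb1), kb1, 1),
               lkr(encode_terms(toks, kb3), kb3, 1))
})

test_that("metric_report assembles per-post rows", {
  kb <- load_toy_kb(toy_kb_path())
  enc <- encode_terms(tokenize("trazodone grogginess and some filler"), kb,
                      post_id = "p1")
  rep <- metric_report(enc, kb, m = 1:2)
  expect_equal(rep$post_id, "p1")
  expect_equal(rep$ekr, 2 / 5)
  expect_true(all(c("lkr_m1", "lkr_m2", "kcr") %in% names(rep)))
  expect_gte(rep$lkr_m2, rep$lkr_m1)
})
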