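test_that("load_rrf_kb reads minimal well-formed input and merges rows by code", {
  conso <- tempfile(fileext = ".rrf")
  rel <- tempfile(fileext = ".rrf")
  pad <- function(code, sab, str) {
    f <- rep("", 18); f[1] <- code; f[12] <- sab; f[15] <- str; f[18] <- "x"
    paste(f, collapse = "|")
  }
  writeLines(c(pad("C1", "VOC", "aspirin"), pad("C2", "VOC", "headache")),
             conso)
  rf <- rep("", 16); rf[1] <- "C1"; rf[4] <- "may_treat"; rf[5] <- "C2"
  rf[16] <- "x"
  writeLines(paste(rf, collapse = "|"), rel)
  kb <- load_rrf_kb(conso, rel)
  expect_length(kb$concepts, 2)
  expect_equal(nrow(kb$relations), 1)
  expect_equal(kb$concepts[["C1"]]$preferred_name, "aspirin")

  # merging: a second row for C1 adds a synonym, not a concept
  writeLines(c(pad("C1", "VOC", "aspirin"), pad("C1", "VOC", "ASA"),
               pad("C2", "VOC", "headache")), conso)
  kb2 <- load_rrf_kb(conso, rel)
  expect_length(kb2$concepts, 2)
  expect_setequal(kb2$concepts[["C1"]]$synonyms, c("aspirin", "ASA"))
})

test_that("load_rrf_kb rejects malformed lines and dangling endpoints", {
  conso <- tempfile(fileext = ".rrf")
  writeLines(c(paste(c("C1", rep("x", 17)), collapse = "|"), "C2|short"),
             conso)
  expect_error(load_rrf_kb(conso, NULL), "line 2")

  pad <- function(code, str) {
    f <- rep("", 18); f[1] <- code; f[12] <- "VOC"; f[15] <- str; f[18] <- "x"
    paste(f, collapse = "|")
  }
  writeLines(c(pad("C1", "aspirin"), pad("C2", "headache")), conso)
  rel <- tempfile(fileext = ".rrf")
  rf <- rep("", 16); rf[1] <- "C1"; rf[4] <- "may_treat"; rf[5] <- "C9"
  rf[16] <- "x"
  writeLines(paste(rf, collapse = "|"), rel)
  expect_error(load_rrf_kb(conso, rel), "C9")
})

test_that("mini RRF fixture: term_index size equals independent synonym union", {
  conso <- system.file("extdata", "mini_mrconso.rrf", package = "kitm")
  rel <- system.file("extdata", "mini_mrrel.rrf", package = "kitm")
  kb <- load_rrf_kb(conso, rel)
  expect_length(kb$concepts, 12)
  expect_equal(nrow(kb$relations), 15)

  # independent set-union oracle: re-read the file raw, normalize with a
  # locally written normalizer, count distinct strings
  raw <- readLines(conso)
  strs <- vapply(strsplit(raw, "|", fixed = TRUE), `[[`, character(1), 15)
  norm <- trimws(gsub("\\s+", " ", gsub("[^[:alnum:]]+", " ", tolower(strs))))
  expect_equal(length(ls(kb$term_index)), length(unique(norm)))
})

test_that("load_toy_kb handles empty relations, duplicates and cycles", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("#KB t", "#CONCEPTS", "A\tV\talpha", "B\tV\tbeta",
               "#RELATIONS"), f)
  kb <- load_toy_kb(f)
  expect_equal(nrow(kb$relations), 0)
  expect_equal(nrow(build_hierarchy(kb)$isa_edges), 0)

  writeLines(c("#KB t", "#CONCEPTS", "A\tV\talpha", "A\tV\talpha2"), f)
  expect_error(load_toy_kb(f), "duplicate")

  writeLines(c("#KB t", "#CONCEPTS", "A\tV\talpha", "B\tV\tbeta",
               "#RELATIONS", "A\tIS_A\tB", "B\tIS_A\tA"), f)
  expect_error(load_toy_kb(f), "cyclic")
})

test_that("toy_kb.tsv fixture agrees with direct line counts", {
  path <- toy_kb_path()
  kb <- load_toy_kb(path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "//")]
  c_start <- which(lines == "#CONCEPTS")
  r_start <- which(lines == "#RELATIONS")
  expect_length(kb$concepts, r_start - c_start - 1)

  # hierarchy edge set equals a grep of the IS_A lines (text-grep oracle)
  isa_lines <- lines[grepl("\tIS_A\t", lines)]
  parts <- strsplit(isa_lines, "\t", fixed = TRUE)
  h <- build_hierarchy(kb)
  expect_setequal(paste(h$isa_edges$child, h$isa_edges$parent),
                  vapply(parts, function(p) paste(p[1], p[3]), character(1)))
})

test_that("build_hierarchy selects exactly the labelled relations", {
  kb <- knowledge_base("t", list(concept_rec("A", "a"), concept_rec("B", "b"),
                                 concept_rec("C", "c")),
                       data.frame(source = c("A", "A"),
                                  label = c("IS_A", "may_treat"),
                                  target = c("B", "C"),
                                  stringsAsFactors = FALSE))
  h <- build_hierarchy(kb)
  expect_equal(h$isa_edges, data.frame(child = "A", parent = "B",
                                       stringsAsFactors = FALSE))
  # subset invariant: every hierarchy edge is a relation with the label
  key <- paste(kb$relations$source, kb$relations$label, kb$relations$target)
  expect_true(all(paste(h$isa_edges$child, "IS_A", h$isa_edges$parent)
                  %in% key))
})

test_that("graph_distance: identity, chains, and unknown codes", {
  kb <- chain_kb(3)
  expect_equal(graph_distance(kb, "A1", "A1"), 0L)
  expect_equal(graph_distance(kb, "A1", "A3", max_hops = 2), 2L)
  expect_equal(graph_distance(kb, "A1", "A3", max_hops = 1), Inf)
  expect_error(graph_distance(kb, "A1", "ZZ"), "unknown")
})

test_that("graph_distance equals the igraph all-pairs oracle on random graphs", {
  skip_if_not_installed("igraph")
  kb <- random_kb(20, 35, seed = 7)
  ora <- igraph_distances(kb)
  codes <- names(kb$concepts)
  for (i in codes) {
    for (j in codes) {
      expect_equal(graph_distance(kb, i, j), unname(ora[i, j]),
                   info = paste(i, j))
    }
  }
})

test_that("undirected graph_distance is symmetric and satisfies the triangle inequality", {
  kb <- random_kb(12, 20, seed = 11)
  codes <- names(kb$concepts)
  d <- outer(codes, codes, Vectorize(function(i, j) graph_distance(kb, i, j)))
  expect_equal(d, t(d))
  for (i in seq_along(codes)) {
    for (j in seq_along(codes)) {
      for (k in seq_along(codes)) {
        expect_lte(d[i, j], d[i, k] + d[k, j])
      }
    }
  }
})

test_that("same content via RRF and toy TSV yields canonically equal KBs", {
  conso <- tempfile(fileext = ".rrf")
  rel <- tempfile(fileext = ".rrf")
  pad <- function(code, str) {
    f <- rep("", 18); f[1] <- code; f[12] <- "VOC"; f[15] <- str; f[18] <- "x"
    paste(f, collapse = "|")
  }
  writeLines(c(pad("C1", "aspirin"), pad("C1", "ASA"), pad("C2", "headache")),
             conso)
  rf <- rep("", 16); rf[1] <- "C1"; rf[4] <- "may_treat"; rf[5] <- "C2"
  rf[16] <- "x"
  writeLines(paste(rf, collapse = "|"), rel)
  kb_rrf <- load_rrf_kb(conso, rel, name = "same")

  toy <- tempfile(fileext = ".tsv")
  writeLines(c("#KB same", "#CONCEPTS", "C1\tVOC\taspirin\tASA\t",
               "C2\tVOC\theadache\t\t", "#RELATIONS",
               "C1\tmay_treat\tC2"), toy)
  kb_toy <- load_toy_kb(toy)
  expect_equal(kb_to_json(kb_rrf), kb_to_json(kb_toy))
})
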