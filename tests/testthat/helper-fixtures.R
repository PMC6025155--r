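# Fixture builders shared across test files. All fixtures are constructed in
# code; nothing is loaded from outside inst/extdata.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent document-frequency counter (oracle; no shared package code).
doc_frequency_oracle <- function(docs) {
  df <- list()
  for (tk in docs) for (w in unique(tk)) df[[w]] <- (df[[w]] %||% 0) + 1
  unlist(df)
}

toy_kb_path <- function() system.file("extdata", "toy_kb.tsv", package = "kitm")

concept_rec <- function(code, name, source = "TEST", syns = character(),
                        sty = "Thing") {
  list(code = code, source = source, preferred_name = name,
       synonyms = syns, semantic_type = sty)
}

# Chain A1 - A2 - ... - An with relations Ai -> A(i+1), all carrying `label`.
chain_kb <- function(n, label = "IS_A") {
  codes <- paste0("A", seq_len(n))
  concepts <- lapply(seq_len(n), function(i)
    concept_rec(codes[i], paste0("chainterm", i)))
  rel <- if (n > 1) data.frame(source = codes[-n], label = label,
                               target = codes[-1],
                               stringsAsFactors = FALSE) else NULL
  knowledge_base("chain", concepts, rel)
}

# Hub H with n leaves L1..Ln, H -> Li.
star_kb <- function(n, label = "IS_A") {
  codes <- c("H", paste0("L", seq_len(n)))
  concepts <- lapply(seq_along(codes), function(i)
    concept_rec(codes[i], paste0("starterm", i)))
  rel <- data.frame(source = codes[-1], label = label, target = "H",
                    stringsAsFactors = FALSE)
  knowledge_base("star", concepts, rel)
}

# Random relation graph over n nodes with ~n_edges distinct directed edges
# and mixed labels; used for oracle comparisons.
random_kb <- function(n, n_edges, seed) {
  set.seed(seed)
  codes <- sprintf("N%03d", seq_len(n))
  concepts <- lapply(seq_len(n), function(i)
    concept_rec(codes[i], sprintf("rndterm%03d", i)))
  pairs <- unique(data.frame(
    s = sample.int(n, n_edges * 2, replace = TRUE),
    t = sample.int(n, n_edges * 2, replace = TRUE)))
  pairs <- pairs[pairs$s != pairs$t, , drop = FALSE]
  pairs <- utils::head(pairs, n_edges)
  rel <- data.frame(source = codes[pairs$s],
                    label = sample(c("rel_a", "rel_b", "rel_c"),
                                   nrow(pairs), replace = TRUE),
                    target = codes[pairs$t], stringsAsFactors = FALSE)
  knowledge_base("random", concepts, rel)
}

# Independent all-pairs shortest-path oracle via igraph (undirected, every
# relation an edge); returns a codes x codes matrix of distances.
igraph_distances <- function(kb, edges = "all", directed = FALSE,
                             hierarchy_label = "IS_A") {
  rel <- kb$relations
  if (edges == "hierarchy")
    rel <- rel[rel$label == hierarchy_label, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    rel[, c("source", "target")], directed = directed,
    vertices = names(kb$concepts))
  igraph::distances(g, mode = if (directed) "out" else "all")
}

# Labeled corpus with perfectly separated topic vocabularies: each label k
# owns `n_words` exclusive words; every doc has one label and draws only
# from its label's words.
separated_docs <- function(n_labels = 3, docs_per_label = 12, n_words = 8,
                           doc_len = 20, seed = 42, all_labels = FALSE) {
  set.seed(seed)
  vocab <- lapply(seq_len(n_labels), function(k)
    sprintf("lab%d_word%02d", k, seq_len(n_words)))
  docs <- list()
  labels <- list()
  i <- 0
  for (k in seq_len(n_labels)) {
    for (d in seq_len(docs_per_label)) {
      i <- i + 1
      id <- sprintf("d%03d", i)
      docs[[id]] <- sample(vocab[[k]], doc_len, replace = TRUE)
      labels[[id]] <- if (all_labels) sprintf("lab%d", seq_len(n_labels))
                      else sprintf("lab%d", k)
    }
  }
  list(docs = docs, labels = labels, vocab = vocab)
}

# Strip the volatile fields from a run manifest for determinism comparisons.
manifest_stable <- function(m) {
  m$timestamp <- NULL
  m
}
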