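#' Synthetic-data configuration
#'
#' Parameters of the toy knowledge-base and corpus generators. The defaults
#' describe a small but realistic drug-review community sample: a 60-concept
#' vocabulary with a depth-3 IS_A tree, 200 posts of about 60 tokens over 5
#' label-aligned topics, and 30% of tokens drawn from knowledge-base
#' synonyms (consumer health text is mostly lay vocabulary with a medical
#' core, so the explicit knowledge rate sits well below one half).
#'
#' @param n_concepts number of knowledge-base concepts.
#' @param n_relations number of non-hierarchical relations added on top of
#'   the IS_A tree.
#' @param hierarchy_depth maximum IS_A path length of the generated tree.
#' @param n_posts number of posts.
#' @param n_topics number of topics (= labels; one topic per label).
#' @param vocab_size total generating vocabulary size (knowledge-base
#'   synonyms plus filler words).
#' @param doc_length_mean mean post length in tokens (Poisson, floored at 5).
#' @param concept_term_fraction fraction of tokens drawn from knowledge-base
#'   synonyms; this makes the corpus-level explicit knowledge rate
#'   controllable.
#' @param label_topic_map named integer vector label -> topic index; default
#'   \code{label_k -> k}.
#' @param dirichlet_alpha document-topic Dirichlet hyperparameter.
#' @param dirichlet_beta topic-word Dirichlet hyperparameter.
#' @param seed integer seed; generation is deterministic given the seed.
#' @return a list of class \code{kitm_synth_config}.
#' @export
synth_config <- function(n_concepts = 60L, n_relations = 40L,
                         hierarchy_depth = 3L, n_posts = 200L,
                         n_topics = 5L, vocab_size = 400L,
                         doc_length_mean = 60L,
                         concept_term_fraction = 0.3,
                         label_topic_map = NULL,
                         dirichlet_alpha = 0.1, dirichlet_beta = 0.01,
                         seed = 1L) {
  stopifnot(n_concepts >= 1, n_relations >= 0, hierarchy_depth >= 1,
            n_posts >= 1, n_topics >= 1, vocab_size >= 1,
            doc_length_mean >= 1,
            concept_term_fraction >= 0, concept_term_fraction <= 1,
            dirichlet_alpha > 0, dirichlet_beta > 0)
  if (is.null(label_topic_map)) {
    label_topic_map <- setNames(seq_len(n_topics),
                                sprintf("label_%d", seq_len(n_topics)))
  }
  if (any(label_topic_map < 1 | label_topic_map > n_topics))
    stop("label_topic_map must index topics 1..n_topics")
  structure(list(n_concepts = as.integer(n_concepts),
                 n_relations = as.integer(n_relations),
                 hierarchy_depth = as.integer(hierarchy_depth),
                 n_posts = as.integer(n_posts),
                 n_topics = as.integer(n_topics),
                 vocab_size = as.integer(vocab_size),
                 doc_length_mean = as.integer(doc_length_mean),
                 concept_term_fraction = concept_term_fraction,
                 label_topic_map = label_topic_map,
                 dirichlet_alpha = dirichlet_alpha,
                 dirichlet_beta = dirichlet_beta,
                 seed = as.integer(seed)),
            class = "kitm_synth_config")
}

rdirichlet1 <- function(n, alpha) {
  x <- stats::rgamma(n, shape = alpha)
  if (sum(x) == 0) x <- rep(1, n)  # guard against all-zero draws at tiny alpha
  x / sum(x)
}

#' Generate a toy knowledge base
#'
#' Builds an acyclic IS_A tree of the configured depth (a backbone chain of
#' length \code{hierarchy_depth} guarantees the maximum path length; the
#' remaining concepts attach to random nodes above the depth limit) plus
#' random non-hierarchical relations. Every concept gets one or two
#' single-word synonyms so that dictionary matching is unambiguous.
#' Deterministic given \code{config$seed}; a single seeded random stream,
#' no hidden global state.
#'
#' @param config a [synth_config()].
#' @return a \code{kitm_kb}.
#' @export
generate_kb <- function(config = synth_config()) {
  n <- config$n_concepts
  if (config$n_relations > n * n)
    stop("infeasible: n_relations exceeds n_concepts^2")
  set.seed(config$seed)
  codes <- sprintf("C%04d", seq_len(n))
  stypes <- c("Drug", "Condition", "Procedure")
  concepts <- lapply(seq_len(n), function(i) {
    name <- sprintf("cterm%04d", i)
    syns <- name
    if (stats::runif(1) < 0.3) syns <- c(syns, sprintf("cterm%04dx", i))
    list(code = codes[i], source = "TOYVOC", preferred_name = name,
         synonyms = syns, semantic_type = sample(stypes, 1))
  })
  # IS_A tree: levels 0..hierarchy_depth, backbone chain first
  depth <- min(config$hierarchy_depth, n - 1L)
  level <- integer(n)
  rel <- list()
  if (depth >= 1) {
    for (i in seq_len(depth)) {
      level[i + 1L] <- i
      rel[[length(rel) + 1L]] <- c(codes[i + 1L], "IS_A", codes[i])
    }
    if (n > depth + 1L) {
      for (i in seq(depth + 2L, n)) {
        eligible <- which(level[seq_len(i - 1L)] < depth)
        parent <- if (length(eligible) == 1) eligible else sample(eligible, 1)
        level[i] <- level[parent] + 1L
        rel[[length(rel) + 1L]] <- c(codes[i], "IS_A", codes[parent])
      }
    }
  }
  # extra non-hierarchical relations
  labels <- c("may_treat", "associated_with", "finding_site")
  seen <- character()
  tries <- 0L
  while (length(seen) < config$n_relations && tries < config$n_relations * 50) {
    tries <- tries + 1L
    st <- sample.int(n, 2)
    key <- paste(st, collapse = "-")
    if (st[1] == st[2] || key %in% seen) next
    seen <- c(seen, key)
    rel[[length(rel) + 1L]] <- c(codes[st[1]], sample(labels, 1), codes[st[2]])
  }
  relations <- if (length(rel)) {
    data.frame(source = vapply(rel, `[`, character(1), 1),
               label = vapply(rel, `[`, character(1), 2),
               target = vapply(rel, `[`, character(1), 3),
               stringsAsFactors = FALSE)
  } else NULL
  knowledge_base("SYNTH", concepts, relations)
}

#' Generate a labeled corpus with known topic structure
#'
#' Follows the Labeled LDA generative story so that model-recovery tests are
#' well-posed: each post receives one to three labels, its topic mixture is
#' a Dirichlet draw supported on its own labels only, and every token picks
#' a topic from that mixture and a word from the topic's word distribution.
#' Each topic's word distribution is a mixture of a Dirichlet draw over the
#' knowledge-base synonym pool (weight \code{concept_term_fraction}) and one
#' over filler words, so the fraction of concept-bearing tokens — hence the
#' explicit knowledge rate — is controlled exactly in expectation.
#'
#' @param config a [synth_config()].
#' @param kb a \code{kitm_kb}, typically from [generate_kb()].
#' @return list with \code{corpus} (a \code{kitm_corpus}) and \code{truth}:
#'   the generating topic-word matrix (\code{topic_word}, rows = labels),
#'   per-document topic mixtures (\code{doc_topic}), token-level topic
#'   assignments (\code{assignments}), the vocabulary split
#'   (\code{kb_terms}, \code{filler_terms}) and the label-topic map.
#' @export
generate_corpus <- function(config = synth_config(), kb = generate_kb(config)) {
  set.seed(config$seed + 1L)
  K <- config$n_topics
  f <- config$concept_term_fraction
  kb_terms <- sort(unique(normalize_term(unlist(
    lapply(kb$concepts, `[[`, "synonyms"), use.names = FALSE))))
  kb_terms <- kb_terms[!grepl(" ", kb_terms)]
  n_filler <- max(config$vocab_size - length(kb_terms), 10L)
  filler_terms <- sprintf("w%04d", seq_len(n_filler))
  vocab <- c(kb_terms, filler_terms)
  nK <- length(kb_terms); nF <- length(filler_terms)
  topic_word <- matrix(0, K, length(vocab),
                       dimnames = list(names(config$label_topic_map)[
                         order(config$label_topic_map)], vocab))
  for (k in seq_len(K)) {
    phi_kb <- rdirichlet1(nK, config$dirichlet_beta)
    phi_fill <- rdirichlet1(nF, config$dirichlet_beta)
    topic_word[k, ] <- c(f * phi_kb, (1 - f) * phi_fill)
  }
  labels_all <- names(config$label_topic_map)
  posts <- vector("list", config$n_posts)
  doc_topic <- vector("list", config$n_posts)
  assignments <- vector("list", config$n_posts)
  for (d in seq_len(config$n_posts)) {
    n_lab <- sample.int(min(3L, length(labels_all)), 1)
    labs <- sort(sample(labels_all, n_lab))
    if (!length(labs)) stop("post generated with empty label set")
    ks <- config$label_topic_map[labs]
    theta <- rdirichlet1(length(ks), config$dirichlet_alpha)
    len <- max(5L, stats::rpois(1, config$doc_length_mean))
    z <- ks[sample.int(length(ks), len, replace = TRUE, prob = theta)]
    w <- vapply(z, function(k) {
      vocab[sample.int(length(vocab), 1, prob = topic_word[k, ])]
    }, character(1))
    id <- sprintf("p%04d", d)
    posts[[d]] <- post(id = id, labels = labs, text = paste(w, collapse = " "),
                       caption = sprintf("synthetic post %d", d))
    doc_topic[[d]] <- setNames(theta, labs)
    assignments[[d]] <- unname(z)
  }
  names(doc_topic) <- vapply(posts, `[[`, character(1), "id")
  names(assignments) <- names(doc_topic)
  list(corpus = corpus(posts, metadata = list(seed = config$seed,
                                              generator = "kitm::generate_corpus")),
       truth = list(topic_word = topic_word, doc_topic = doc_topic,
                    assignments = assignments, kb_terms = kb_terms,
                    filler_terms = filler_terms,
                    label_topic_map = config$label_topic_map))
}
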