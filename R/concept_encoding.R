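#' Discover the knowledge-base domains of labels or terms
#'
#' For each input label, looks up its normalized form in the knowledge-base
#' term index and maps it to the domains of the matching concepts. The
#' domain axis is configurable: by default a concept's domain is its source
#' vocabulary (the standard mapping between a metathesaurus and a domain
#' model), alternatively its semantic type (a medical meaning such as
#' "patient condition"). Labels matching nothing map to an empty set. With
#' single-token input the same operation serves as a per-term domain tagger.
#'
#' @param labels character vector of labels (or terms).
#' @param kb a \code{kitm_kb}.
#' @param domains optional character vector restricting the admissible
#'   domains; matches outside it are discarded.
#' @param axis \code{"source"} (default) or \code{"semantic_type"}.
#' @return named list mapping each label to a character vector of domains
#'   (possibly empty).
#' @export
discover_domains <- function(labels, kb, domains = NULL,
                             axis = c("source", "semantic_type")) {
  axis <- match.arg(axis)
  if (!is.null(domains)) domains <- normalize_term(domains)
  hits <- kb_lookup(kb, labels)
  res <- lapply(hits, function(codes) {
    if (!length(codes)) return(character())
    d <- vapply(kb$concepts[codes], `[[`, character(1), axis)
    d <- unique(normalize_term(d))
    d <- d[nzchar(d)]
    if (!is.null(domains)) d <- intersect(d, domains)
    d
  })
  names(res) <- labels
  res
}

# Small closed-class lexicon + suffix rules. Deliberately coarse: the model
# only needs a stable six-way tag, not linguistic accuracy, and must not
# depend on downloaded tagger models.
.pos_lexicon <- local({
  lex <- list(
    OTHER = c("the", "a", "an", "and", "or", "but", "if", "then", "than",
              "that", "this", "these", "those", "it", "its", "i", "you",
              "he", "she", "we", "they", "me", "him", "her", "us", "them",
              "my", "your", "his", "our", "their", "of", "in", "on", "at",
              "to", "for", "with", "by", "from", "as", "about", "into",
              "off", "out", "up", "down", "over", "under", "not", "no",
              "nor", "so", "because", "while", "when", "where", "who",
              "what", "which", "why", "how", "yes", "ok"),
    VERB = c("is", "are", "was", "were", "be", "been", "being", "am",
             "have", "has", "had", "do", "does", "did", "can", "could",
             "will", "would", "shall", "should", "may", "might", "must",
             "take", "took", "taken", "get", "got", "give", "gave", "go",
             "went", "gone", "stop", "stopped", "start", "started", "use",
             "used", "feel", "felt", "work", "worked", "help", "helped",
             "wish", "hope", "want", "need", "try", "tried", "quit",
             "miss", "missed", "suggest"),
    ADV = c("very", "really", "too", "also", "just", "now", "soon", "again",
            "here", "there", "always", "never", "often", "sometimes",
            "daily", "once", "twice", "ago", "basically"),
    ADJ = c("good", "bad", "low", "high", "new", "old", "same", "more",
            "most", "less", "least", "better", "best", "worse", "worst",
            "generic", "potent", "nonaddictive"))
  tag <- rep(names(lex), lengths(lex))
  setNames(tag, unlist(lex, use.names = FALSE))
})

#' Coarse part-of-speech tagging
#'
#' Assigns each token one of the tags NOUN, VERB, ADJ, ADV, NUM, OTHER
#' using a built-in closed-class lexicon and suffix rules; unknown tokens
#' default to NOUN (in consumer health text the open-class unknowns are
#' overwhelmingly drug and condition nouns). The tagger is deterministic
#' and self-contained; a custom tagger can be swapped in anywhere a
#' \code{(token, pos)} table is accepted.
#'
#' @param tokens character vector of (lowercased) tokens.
#' @return data.frame with columns \code{token}, \code{pos}.
#' @export
tag_pos <- function(tokens) {
  if (!length(tokens)) {
    return(data.frame(token = character(), pos = character(),
                      stringsAsFactors = FALSE))
  }
  pos <- rep(NA_character_, length(tokens))
  pos[grepl("^[0-9]+$", tokens)] <- "NUM"
  known <- is.na(pos) & tokens %in% names(.pos_lexicon)
  pos[known] <- .pos_lexicon[tokens[known]]
  todo <- is.na(pos)
  pos[todo & grepl("ly$", tokens)] <- "ADV"
  todo <- is.na(pos)
  pos[todo & grepl("(ing|ed|ize|ise|ates?)$", tokens) &
        nchar(tokens) > 4] <- "VERB"
  todo <- is.na(pos)
  pos[todo & grepl("(ous|ful|ive|able|ible|ish|less|ic|al)$", tokens) &
        nchar(tokens) > 4] <- "ADJ"
  pos[is.na(pos)] <- "NOUN"
  data.frame(token = tokens, pos = pos, stringsAsFactors = FALSE)
}

#' Encode tokens against a knowledge base
#'
#' Dictionary-based concept recognition: scanning left to right, the
#' longest window of up to \code{window} consecutive tokens whose
#' normalized join matches a knowledge-base synonym is encoded as one term
#' carrying the full set of matching concept quadruples (knowledge-base
#' name, code, semantic type, preferred name) — ambiguity is preserved, no
#' tie-break. Tokens matching nothing are kept with an empty code set and
#' domain \code{"none"}. No word-sense disambiguation or negation handling
#' is attempted.
#'
#' @param tokens character vector of tokens, or a data.frame with columns
#'   \code{token}, \code{pos} (as from [tag_pos()]; plain tokens are tagged
#'   internally).
#' @param kb a \code{kitm_kb}.
#' @param post_id identifier recorded on the result.
#' @param window maximum multi-token match length (default 3).
#' @param axis domain axis, \code{"source"} or \code{"semantic_type"}.
#' @return object of class \code{kitm_encoded}: list with \code{post_id},
#'   \code{terms} (list of term records: \code{term}, \code{pos},
#'   \code{domain}, \code{start} token position, \code{codes} data.frame
#'   with columns \code{kb_name}, \code{code}, \code{semantic_type},
#'   \code{preferred_name}), and the counts \code{n_raw} (tokens before
#'   encoding), \code{n_concepts} (concept-bearing term occurrences) and
#'   \code{n_unique_concepts} (distinct codes).
#' @export
encode_terms <- function(tokens, kb, post_id = "", window = 3L,
                         axis = c("source", "semantic_type")) {
  axis <- match.arg(axis)
  if (is.data.frame(tokens)) {
    toks <- tokens$token
    pos <- tokens$pos
  } else {
    toks <- as.character(tokens)
    pos <- tag_pos(toks)$pos
  }
  n_raw <- length(toks)
  norm <- normalize_term(toks)
  terms <- list()
  i <- 1L
  while (i <= n_raw) {
    matched <- FALSE
    for (j in seq(min(i + window - 1L, n_raw), i)) {
      phrase <- paste(norm[i:j], collapse = " ")
      codes <- kb$term_index[[phrase]]
      if (!is.null(codes)) {
        quad <- data.frame(
          kb_name = kb$name, code = codes,
          semantic_type = vapply(kb$concepts[codes], `[[`, character(1),
                                 "semantic_type"),
          preferred_name = vapply(kb$concepts[codes], `[[`, character(1),
                                  "preferred_name"),
          stringsAsFactors = FALSE, row.names = NULL)
        doms <- vapply(kb$concepts[codes], `[[`, character(1), axis)
        doms <- unique(normalize_term(doms))
        doms <- doms[nzchar(doms)]
        terms[[length(terms) + 1L]] <- list(
          term = paste(toks[i:j], collapse = " "), pos = pos[i],
          domain = if (length(doms)) paste(doms, collapse = ";")
                   else "unspecified",  # matched but axis value missing
          start = i, codes = quad)
        i <- j + 1L
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      terms[[length(terms) + 1L]] <- list(
        term = toks[i], pos = pos[i], domain = "none", start = i,
        codes = data.frame(kb_name = character(), code = character(),
                           semantic_type = character(),
                           preferred_name = character(),
                           stringsAsFactors = FALSE))
      i <- i + 1L
    }
  }
  all_codes <- unlist(lapply(terms, function(t) t$codes$code),
                      use.names = FALSE)
  n_concepts <- sum(vapply(terms, function(t) nrow(t$codes) > 0, logical(1)))
  structure(list(post_id = post_id, terms = terms, n_raw = n_raw,
                 n_concepts = n_concepts,
                 n_unique_concepts = length(unique(all_codes))),
            class = "kitm_encoded")
}

#' @export
print.kitm_encoded <- function(x, ...) {
  cat(sprintf(
    "<kitm_encoded '%s': %d raw terms, %d concept-bearing, %d unique codes>\n",
    x$post_id, x$n_raw, x$n_concepts, x$n_unique_concepts))
  invisible(x)
}

#' Explicit concept codes of an encoded text
#'
#' @param encoded a \code{kitm_encoded}.
#' @return character vector of distinct codes, in order of first appearance.
#' @export
encoded_codes <- function(encoded) {
  unique(unlist(lapply(encoded$terms, function(t) t$codes$code),
                use.names = FALSE))
}
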