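#' Text pipeline configuration
#'
#' Thresholds of the tokenizer/filter chain applied to narrative text before
#' topic modeling. The defaults are the chain's canonical settings: keep
#' terms of at least 3 characters, drop terms occurring in fewer than 4
#' documents, remove the 30 most document-frequent terms as a dynamic
#' stoplist, keep documents with at least 5 surviving terms, and keep labels
#' occurring in at least 10 documents.
#'
#' @param min_term_length minimum token length in characters.
#' @param term_min_doc_count minimum number of documents a term must occur in.
#' @param label_min_doc_count minimum number of documents a label must occur in.
#' @param stoplist_size how many of the most document-frequent terms to drop.
#' @param doc_min_length minimum surviving terms for a document to be kept.
#' @return a list of class \code{kitm_pipeline_config}.
#' @export
pipeline_config <- function(min_term_length = 3L, term_min_doc_count = 4L,
                            label_min_doc_count = 10L, stoplist_size = 30L,
                            doc_min_length = 5L) {
  vals <- c(min_term_length, term_min_doc_count, label_min_doc_count,
            stoplist_size, doc_min_length)
  if (any(vals < 0)) stop("all pipeline thresholds must be >= 0")
  structure(list(min_term_length = as.integer(min_term_length),
                 term_min_doc_count = as.integer(term_min_doc_count),
                 label_min_doc_count = as.integer(label_min_doc_count),
                 stoplist_size = as.integer(stoplist_size),
                 doc_min_length = as.integer(doc_min_length)),
            class = "kitm_pipeline_config")
}

#' Tokenize narrative text
#'
#' Splits on whitespace, punctuation and symbols (Unicode categories P and
#' S), lowercases, and keeps only tokens made purely of letters and digits.
#' Numbers are retained; no stemming, lemmatization or spelling correction
#' is performed. Total function: the empty string yields an empty token
#' vector.
#'
#' @param text character scalar or vector; vectors are tokenized elementwise
#'   and returned as a list.
#' @return character vector of tokens (list of vectors for vector input).
#' @export
#' @examples
#' tokenize("Wow..........is atenolol the answer?")
tokenize <- function(text) {
  tok1 <- function(x) {
    x <- tolower(x)
    parts <- strsplit(x, "[\\p{P}\\p{S}\\s]+", perl = TRUE)[[1]]
    parts <- parts[nzchar(parts)]
    parts[grepl("^[\\p{L}\\p{N}]+$", parts, perl = TRUE)]
  }
  if (length(text) == 1) tok1(text) else lapply(text, tok1)
}

# Document frequency of each distinct term over a named list of token
# vectors: number of documents containing the term at least once.
doc_frequency <- function(docs) {
  if (!length(docs)) return(integer())
  tab <- table(unlist(lapply(docs, unique), use.names = FALSE))
  setNames(as.integer(tab), names(tab))
}

#' Apply the term filter chain
#'
#' Filters run in fixed order: (1) minimum token length; (2) minimum
#' document frequency; (3) dynamic stoplist — the \code{stoplist_size} most
#' document-frequent surviving terms are removed, ties broken
#' lexicographically; (4) documents left with fewer than
#' \code{doc_min_length} terms are dropped and recorded. Document frequency
#' counts documents, not occurrences, and is computed once after the length
#' filter (removing one term never changes another term's document
#' frequency; document dropping happens only afterwards).
#'
#' @param docs named list mapping post id to a token vector (as produced by
#'   [tokenize()]).
#' @param config a [pipeline_config()].
#' @return object of class \code{kitm_tokenized}: list with \code{docs}
#'   (named list of surviving token vectors), \code{vocabulary} (named
#'   integer vector of document frequencies over surviving docs),
#'   \code{stoplist} (terms removed as too common) and \code{dropped_docs}.
#' @export
apply_term_filters <- function(docs, config = pipeline_config()) {
  stopifnot(is.list(docs), !is.null(names(docs)))
  docs <- lapply(docs, function(tok) tok[nchar(tok) >= config$min_term_length])
  df <- doc_frequency(docs)
  keep <- names(df)[df >= config$term_min_doc_count]
  df <- df[keep]
  stoplist <- character()
  if (config$stoplist_size > 0 && length(df)) {
    ord <- order(-df, names(df))
    stoplist <- names(df)[ord][seq_len(min(config$stoplist_size, length(df)))]
  }
  keep <- setdiff(keep, stoplist)
  docs <- lapply(docs, function(tok) tok[tok %in% keep])
  short <- lengths(docs) < config$doc_min_length
  dropped <- names(docs)[short]
  docs <- docs[!short]
  structure(list(docs = docs, vocabulary = doc_frequency(docs),
                 stoplist = stoplist, dropped_docs = dropped),
            class = "kitm_tokenized")
}

#' @export
print.kitm_tokenized <- function(x, ...) {
  cat(sprintf("<kitm_tokenized: %d docs, %d terms, %d dropped docs>\n",
              length(x$docs), length(x$vocabulary), length(x$dropped_docs)))
  invisible(x)
}

#' Apply the label filter chain
#'
#' Label fields are tokenized on whitespace, optionally annotated with
#' knowledge-base domains (domain discovery), counted per document, and
#' labels occurring in fewer than \code{label_min_doc_count} documents are
#' removed. Posts left without any label are excluded from the labeled
#' dataset and reported with a warning.
#'
#' @param corpus a \code{kitm_corpus}.
#' @param config a [pipeline_config()].
#' @param kb optional \code{kitm_kb}; when given, each surviving label is
#'   mapped to its knowledge-base domains via [discover_domains()].
#' @return list with \code{labels} (named list post id -> retained label
#'   vector), \code{label_counts} (named integer document counts of the
#'   retained labels), \code{dropped_posts} (ids excluded for having no
#'   surviving label) and \code{domain_map} (label -> domains, or
#'   \code{NULL} when no \code{kb} given).
#' @export
apply_label_filters <- function(corpus, config = pipeline_config(),
                                kb = NULL) {
  raw <- lapply(corpus$posts, function(p) {
    unique(unlist(strsplit(p$labels, "\\s+"), use.names = FALSE))
  })
  raw <- lapply(raw, function(x) x[nzchar(x)])
  counts <- doc_frequency(raw)
  keep <- names(counts)[counts >= config$label_min_doc_count]
  labels <- lapply(raw, function(x) x[x %in% keep])
  dropped <- names(labels)[lengths(labels) == 0]
  labels <- labels[lengths(labels) > 0]
  if (length(dropped)) {
    warning(length(dropped), " post(s) excluded: no label above the ",
            config$label_min_doc_count, "-document threshold")
  }
  domain_map <- if (!is.null(kb)) discover_domains(keep, kb) else NULL
  list(labels = labels, label_counts = counts[keep],
       dropped_posts = dropped, domain_map = domain_map)
}
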