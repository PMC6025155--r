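#' Construct a post
#'
#' A patient-reported post: an identifier, a set of labels (in drug-review
#' communities typically the drug names the post is filed under), a caption,
#' the narrative text, plus optional background strings, topic annotations
#' and free-form attributes. The \code{topics} field is carried through I/O
#' but never used as model input — topics are the model's output.
#'
#' @param id unique post identifier.
#' @param labels character vector of labels.
#' @param text narrative body (may be empty only when \code{caption} is not).
#' @param caption post caption.
#' @param background,topics character vectors of opaque annotation strings.
#' @param attributes named list of extra fields.
#' @return object of class \code{kitm_post}.
#' @export
post <- function(id, labels = character(), text = "", caption = "",
                 background = character(), topics = character(),
                 attributes = list()) {
  if (!nzchar(text) && !nzchar(caption))
    stop("post '", id, "': text may be empty only if caption is non-empty")
  structure(list(id = as.character(id), background = as.character(background),
                 labels = as.character(labels), topics = as.character(topics),
                 caption = caption, text = text, attributes = attributes),
            class = "kitm_post")
}

#' Construct a corpus
#'
#' @param posts list of [post()] objects; ids must be unique.
#' @param metadata named list of corpus-level metadata.
#' @return object of class \code{kitm_corpus}.
#' @export
corpus <- function(posts, metadata = list()) {
  ids <- vapply(posts, function(p) p$id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate post id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(posts) <- ids
  structure(list(posts = posts, metadata = metadata), class = "kitm_corpus")
}

#' @export
print.kitm_corpus <- function(x, ...) {
  cat(sprintf("<kitm_corpus: %d posts>\n", length(x$posts)))
  invisible(x)
}

#' @export
length.kitm_corpus <- function(x) length(x$posts)

#' Post ids of a corpus
#' @param x a \code{kitm_corpus}.
#' @return character vector of ids in corpus order.
#' @export
corpus_ids <- function(x) vapply(x$posts, function(p) p$id, character(1),
                                 USE.NAMES = FALSE)

default_field_map <- c(id = "id", label = "label", caption = "caption",
                       text = "text", background = "background",
                       topic = "topic")

#' Read a corpus from CSV or JSON-Lines
#'
#' CSV columns are mapped to post fields through \code{field_map}
#' (\code{c(id = "id", label = "label", text = "text", ...)}); multi-valued
#' fields (labels, background, topics) are whitespace-separated in CSV and
#' JSON arrays in JSONL. Text is read as UTF-8 and never normalized or
#' spell-corrected here — cleaning belongs to the text pipeline.
#'
#' @param path input file.
#' @param format \code{"csv"} or \code{"jsonl"}.
#' @param field_map named character vector mapping post fields to column /
#'   key names; must cover \code{id}, \code{label} and \code{text}.
#' @return a \code{kitm_corpus}.
#' @export
read_corpus <- function(path, format = c("csv", "jsonl"),
                        field_map = default_field_map) {
  format <- match.arg(format)
  for (f in c("id", "label", "text")) {
    if (!f %in% names(field_map))
      stop("field_map must map the '", f, "' field")
  }
  fm <- function(field) unname(field_map[field])
  split_ws <- function(x) {
    if (is.null(x) || is.na(x) || !nzchar(x)) character()
    else strsplit(trimws(x), "\\s+")[[1]]
  }
  if (format == "csv") {
    df <- utils::read.csv(path, colClasses = "character",
                          check.names = FALSE, encoding = "UTF-8")
    for (f in c("id", "label", "text")) {
      if (!fm(f) %in% names(df))
        stop("missing mapped column '", fm(f), "' in ", path)
    }
    col <- function(field, i) {
      cn <- fm(field)
      if (!is.na(cn) && cn %in% names(df)) df[[cn]][i] else ""
    }
    posts <- lapply(seq_len(nrow(df)), function(i) {
      post(id = col("id", i), labels = split_ws(col("label", i)),
           caption = col("caption", i), text = col("text", i),
           background = split_ws(col("background", i)),
           topics = split_ws(col("topic", i)))
    })
  } else {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    posts <- lapply(lines, function(ln) {
      rec <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
      get <- function(field, default) {
        v <- rec[[fm(field)]]
        if (is.null(v)) default else v
      }
      labs <- get("label", character())
      if (length(labs) == 1 && grepl("\\s", labs)) labs <- split_ws(labs)
      post(id = get("id", stop("record without id in ", path)),
           labels = as.character(labs),
           caption = as.character(get("caption", "")),
           text = as.character(get("text", "")),
           background = as.character(get("background", character())),
           topics = as.character(get("topic", character())),
           attributes = if (is.null(rec$attributes)) list()
                        else as.list(rec$attributes))
    })
  }
  corpus(posts)
}

#' Write a corpus to CSV or JSON-Lines
#'
#' Inverse of [read_corpus()] under the default field map:
#' \code{read_corpus(write_corpus(x))} reproduces \code{x} (CSV drops the
#' free-form \code{attributes}, which have no column; JSONL keeps them).
#'
#' @param corpus a \code{kitm_corpus}.
#' @param path output file.
#' @param format \code{"csv"} or \code{"jsonl"}.
#' @return \code{path}, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- data.frame(
      id = corpus_ids(corpus),
      label = vapply(corpus$posts, function(p) paste(p$labels, collapse = " "),
                     character(1), USE.NAMES = FALSE),
      caption = vapply(corpus$posts, `[[`, character(1), "caption",
                       USE.NAMES = FALSE),
      text = vapply(corpus$posts, `[[`, character(1), "text",
                    USE.NAMES = FALSE),
      background = vapply(corpus$posts,
                          function(p) paste(p$background, collapse = " "),
                          character(1), USE.NAMES = FALSE),
      topic = vapply(corpus$posts, function(p) paste(p$topics, collapse = " "),
                     character(1), USE.NAMES = FALSE),
      stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    lines <- vapply(corpus$posts, function(p) {
      jsonlite::toJSON(list(id = p$id, label = p$labels, caption = p$caption,
                            text = p$text, background = p$background,
                            topic = p$topics, attributes = p$attributes),
                       auto_unbox = TRUE, digits = NA)
    }, character(1), USE.NAMES = FALSE)
    writeLines(lines, path, useBytes = TRUE)
  }
  invisible(path)
}

#' The packaged example posts
#'
#' Five short drug-review posts (labels Atenolol, Diovan, Tazorac,
#' Trazodone, Wellbutrin) shipped as a CSV fixture; a minimal realistic
#' input for the whole pipeline.
#'
#' @return a \code{kitm_corpus} of 5 posts.
#' @export
example_posts <- function() {
  read_corpus(system.file("extdata", "table2_posts.csv", package = "kitm"),
              format = "csv")
}
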