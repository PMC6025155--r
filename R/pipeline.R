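#' Full-run configuration
#'
#' Bundles everything a reproducible end-to-end run needs: input paths,
#' pipeline thresholds, expansion depth, model hyperparameters and metric
#' modes. Paths are validated here, before any stage runs.
#'
#' @param corpus_path corpus file (CSV or JSONL).
#' @param kb_path toy-TSV knowledge-base file.
#' @param out_dir output directory (created if missing).
#' @param corpus_format \code{"csv"} or \code{"jsonl"}.
#' @param pipeline a [pipeline_config()].
#' @param m expansion layers (0 disables expansion).
#' @param alpha,beta,n_iterations,seed model hyperparameters.
#' @param lkr_m layer counts reported by the metric stage.
#' @param lkr_mode \code{"reachable"} or \code{"path_count"}.
#' @param edges \code{"hierarchy"} or \code{"all"} traversal for expansion.
#' @return a list of class \code{kitm_run_config}.
#' @export
run_config <- function(corpus_path, kb_path, out_dir,
                       corpus_format = c("csv", "jsonl"),
                       pipeline = pipeline_config(), m = 1L,
                       alpha = 0.1, beta = 0.01, n_iterations = 200L,
                       seed = 1L, lkr_m = 1:3,
                       lkr_mode = c("reachable", "path_count"),
                       edges = c("hierarchy", "all")) {
  corpus_format <- match.arg(corpus_format)
  lkr_mode <- match.arg(lkr_mode)
  edges <- match.arg(edges)
  for (p in c(corpus_path, kb_path)) {
    if (!file.exists(p)) stop("input path does not exist: ", p)
  }
  structure(list(corpus_path = corpus_path, kb_path = kb_path,
                 out_dir = out_dir, corpus_format = corpus_format,
                 pipeline = pipeline, m = as.integer(m), alpha = alpha,
                 beta = beta, n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed), lkr_m = lkr_m,
                 lkr_mode = lkr_mode, edges = edges),
            class = "kitm_run_config")
}

#' Run the full pipeline
#'
#' Executes preprocess (tokenize + term filters + label filters), domain
#' discovery, term encoding, latent-knowledge expansion, Labeled LDA
#' training and metric evaluation over one corpus and knowledge base, and
#' writes per-stage artifacts plus a run manifest (inputs, md5 hashes,
#' seed, per-stage record counts) under \code{config$out_dir}. Every
#' stage's record counts are logged, so silent filtering is auditable.
#' Deterministic: the same config and seed reproduce every artifact
#' byte-for-byte (the manifest's timestamp aside).
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return the manifest, invisibly (also written as \code{manifest.json}).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "kitm_run_config"))
  say <- function(...) if (!quiet) message(...)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  kb <- load_toy_kb(config$kb_path)
  crp <- read_corpus(config$corpus_path, format = config$corpus_format)
  say("input: ", length(crp), " posts, KB '", kb$name, "' with ",
      length(kb$concepts), " concepts")

  raw_tokens <- setNames(lapply(crp$posts, function(p) tokenize(p$text)),
                         corpus_ids(crp))
  tk <- apply_term_filters(raw_tokens, config$pipeline)
  say("term filters: ", length(tk$docs), " docs kept, ",
      length(tk$dropped_docs), " dropped, vocabulary ",
      length(tk$vocabulary))
  lb <- suppressWarnings(apply_label_filters(crp, config$pipeline, kb = kb))
  say("label filters: ", length(lb$label_counts), " labels kept, ",
      length(lb$dropped_posts), " posts without surviving labels")

  ids <- intersect(names(tk$docs), names(lb$labels))
  encoded <- lapply(ids, function(i) {
    encode_terms(tk$docs[[i]], kb, post_id = i)
  })
  names(encoded) <- ids
  expanded <- lapply(encoded, expand_text, kb = kb, m = config$m,
                     edges = config$edges)
  say("encoded ", length(encoded), " docs; expansion m = ", config$m)

  model <- NULL
  dataset <- NULL
  if (length(ids)) {
    dataset <- build_dataset(expanded, lb$labels[ids])
    if (length(dataset$docs)) {
      model <- train_cvb0(dataset, alpha = config$alpha, beta = config$beta,
                          n_iterations = config$n_iterations,
                          seed = config$seed)
    }
  }

  reports <- lapply(encoded, metric_report, kb = kb, m = config$lkr_m,
                    edges = config$edges)
  report <- if (length(reports)) do.call(rbind, reports) else NULL

  # --- artifacts -----------------------------------------------------------
  paths <- list()
  write_json <- function(x, file) {
    p <- file.path(config$out_dir, file)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths[[file]] <<- p
  }
  write_json(lapply(tk$docs, identity), "tokenized.json")
  if (!is.null(report)) {
    p <- file.path(config$out_dir, "metrics.csv")
    utils::write.csv(report, p, row.names = FALSE)
    paths[["metrics.csv"]] <- p
  }
  if (!is.null(model)) {
    write_json(list(label_names = model$label_names, vocab = model$vocab,
                    alpha = model$alpha, beta = model$beta,
                    seed = model$seed,
                    topic_word = apply(model$topic_word, 1, identity,
                                       simplify = FALSE),
                    doc_topic = apply(model$doc_topic, 1, identity,
                                      simplify = FALSE),
                    top_terms = top_terms(model, 5)),
               "model.json")
  }

  manifest <- list(
    inputs = list(corpus = config$corpus_path, kb = config$kb_path),
    input_hashes = setNames(as.list(tools::md5sum(c(config$corpus_path,
                                                    config$kb_path))),
                            c("corpus", "kb")),
    seed = config$seed,
    m = config$m,
    thresholds = unclass(config$pipeline),
    counts = list(
      posts_in = length(crp),
      docs_after_term_filters = length(tk$docs),
      docs_dropped_by_length = length(tk$dropped_docs),
      vocabulary = length(tk$vocabulary),
      labels_kept = length(lb$label_counts),
      posts_without_labels = length(lb$dropped_posts),
      docs_modeled = if (is.null(dataset)) 0L else length(dataset$docs),
      topics = if (is.null(model)) 0L else nrow(model$topic_word)),
    artifact_hashes = setNames(as.list(tools::md5sum(unlist(paths))),
                               basename(unlist(paths))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Partition a corpus by mapped topic
#'
#' Assigns each post to the topic of its first label found in
#' \code{topic_map}; posts with no mapped label go to
#' \code{"unclassified"}. The buckets partition the corpus: their union is
#' the input, with no duplication.
#'
#' @param corpus a \code{kitm_corpus}.
#' @param topic_map named character vector, label -> topic.
#' @return named list of \code{kitm_corpus} objects, one per topic.
#' @export
classify_posts <- function(corpus, topic_map) {
  buckets <- list()
  for (p in corpus$posts) {
    hit <- p$labels[p$labels %in% names(topic_map)]
    topic <- if (length(hit)) unname(topic_map[hit[1]]) else "unclassified"
    buckets[[topic]] <- c(buckets[[topic]], list(p))
  }
  lapply(buckets, corpus)
}
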