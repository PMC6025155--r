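#' Build an integer-coded Labeled LDA dataset
#'
#' Pairs each document's token stream with its set of allowed labels and
#' integer-codes both. Topics are identified one-to-one with labels — no
#' background topic — so the label universe of the dataset is the topic
#' space of the model. Documents without any token or any label are
#' excluded and reported.
#'
#' @param docs named list mapping post id to a character token vector, or a
#'   list of \code{kitm_expanded} objects (their \code{expanded_tokens} are
#'   used).
#' @param labels named list mapping post id to a character label vector
#'   (e.g. \code{apply_label_filters()$labels}).
#' @return object of class \code{kitm_dataset}: list with \code{docs} (per
#'   doc: integer \code{tokens}, integer \code{labels}), \code{doc_ids},
#'   \code{vocab}, \code{label_names}, \code{excluded}.
#' @export
build_dataset <- function(docs, labels) {
  if (length(docs) && inherits(docs[[1]], "kitm_expanded")) {
    ids <- vapply(docs, `[[`, character(1), "post_id")
    docs <- setNames(lapply(docs, `[[`, "expanded_tokens"), ids)
  }
  stopifnot(!is.null(names(docs)), !is.null(names(labels)))
  ids <- intersect(names(docs), names(labels))
  keep <- ids[vapply(ids, function(i) {
    length(docs[[i]]) > 0 && length(labels[[i]]) > 0
  }, logical(1))]
  excluded <- setdiff(union(names(docs), names(labels)), keep)
  if (length(excluded)) {
    message(length(excluded),
            " doc(s) excluded from the labeled dataset (no tokens or no labels)")
  }
  vocab <- sort(unique(unlist(docs[keep], use.names = FALSE)))
  label_names <- sort(unique(unlist(labels[keep], use.names = FALSE)))
  dd <- lapply(keep, function(i) {
    list(tokens = match(docs[[i]], vocab),
         labels = sort(match(unique(labels[[i]]), label_names)))
  })
  structure(list(docs = dd, doc_ids = keep, vocab = vocab,
                 label_names = label_names, excluded = excluded),
            class = "kitm_dataset")
}

#' @export
print.kitm_dataset <- function(x, ...) {
  cat(sprintf("<kitm_dataset: %d docs, %d terms, %d labels>\n",
              length(x$docs), length(x$vocab), length(x$label_names)))
  invisible(x)
}

#' Train Labeled LDA with CVB0 inference
#'
#' Zero-order collapsed variational Bayes: every token carries a
#' variational distribution over its document's allowed labels (exactly
#' zero elsewhere — the defining support restriction of Labeled LDA),
#' updated sequentially from collapsed counts that exclude the token's own
#' mass. Initialization is a seeded random draw, so the result is bitwise
#' reproducible given the seed. \code{n_iterations = 0} returns the
#' initialized model, which already satisfies all distribution invariants.
#'
#' @param dataset a \code{kitm_dataset}.
#' @param alpha document-topic Dirichlet hyperparameter (default 0.1).
#' @param beta topic-word Dirichlet hyperparameter (default 0.01).
#' @param n_iterations number of full CVB0 sweeps (default 200).
#' @param seed integer seed for the variational initialization.
#' @return object of class \code{kitm_model}: list with \code{topic_word}
#'   (K x V matrix, rows sum to 1), \code{doc_topic} (D x K matrix, rows
#'   sum to 1 with support only on each doc's labels), \code{alpha},
#'   \code{beta}, \code{n_iterations}, \code{seed}, \code{vocab},
#'   \code{label_names}, \code{doc_ids}.
#' @export
train_cvb0 <- function(dataset, alpha = 0.1, beta = 0.01,
                       n_iterations = 200L, seed = 1L) {
  stopifnot(inherits(dataset, "kitm_dataset"), length(dataset$docs) > 0,
            alpha > 0, beta > 0, n_iterations >= 0)
  K <- length(dataset$label_names)
  V <- length(dataset$vocab)
  D <- length(dataset$docs)
  doc_id <- integer(0); word_id <- integer(0)
  for (d in seq_len(D)) {
    nt <- length(dataset$docs[[d]]$tokens)
    doc_id <- c(doc_id, rep(d, nt))
    word_id <- c(word_id, dataset$docs[[d]]$tokens)
  }
  n_tok <- length(word_id)
  allowed <- lapply(dataset$docs, `[[`, "labels")
  set.seed(seed)
  gamma <- matrix(0, n_tok, K)
  for (i in seq_len(n_tok)) {
    a <- allowed[[doc_id[i]]]
    g <- stats::runif(length(a))
    gamma[i, a] <- g / sum(g)
  }
  fit <- cvb0_train(gamma, doc_id - 1L, word_id - 1L,
                    lapply(allowed, function(a) a - 1L),
                    D, V, K, alpha, beta, as.integer(n_iterations))
  topic_word <- t(fit$Nwk) + beta                      # K x V
  topic_word <- topic_word / rowSums(topic_word)
  dimnames(topic_word) <- list(dataset$label_names, dataset$vocab)
  doc_topic <- matrix(0, D, K,
                      dimnames = list(dataset$doc_ids, dataset$label_names))
  for (d in seq_len(D)) {
    a <- allowed[[d]]
    th <- fit$Ndk[d, a] + alpha
    doc_topic[d, a] <- th / sum(th)
  }
  structure(list(topic_word = topic_word, doc_topic = doc_topic,
                 alpha = alpha, beta = beta,
                 n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed), vocab = dataset$vocab,
                 label_names = dataset$label_names,
                 doc_ids = dataset$doc_ids),
            class = "kitm_model")
}

#' @export
print.kitm_model <- function(x, ...) {
  cat(sprintf("<kitm_model: %d topics, %d terms, %d docs, %d iterations>\n",
              nrow(x$topic_word), ncol(x$topic_word), nrow(x$doc_topic),
              x$n_iterations))
  invisible(x)
}

#' Fold-in inference for a new document
#'
#' CVB0 updates with the topic-word distributions frozen: each token's
#' variational distribution over the allowed labels is proportional to
#' \code{topic_word[k, w] * (N_dk^{-i} + alpha)}. An empty token list
#' yields the uniform distribution over the allowed labels.
#'
#' @param model a \code{kitm_model}.
#' @param tokens character vector of tokens or integer vocabulary ids;
#'   out-of-vocabulary tokens are dropped.
#' @param allowed_labels character vector of label names (or integer label
#'   ids) the document may use.
#' @param n_iterations fold-in sweeps (default 50).
#' @return named numeric vector over all model labels, summing to 1, with
#'   support only on \code{allowed_labels}.
#' @export
infer_doc <- function(model, tokens, allowed_labels, n_iterations = 50L) {
  K <- nrow(model$topic_word)
  a <- if (is.character(allowed_labels))
    match(allowed_labels, model$label_names) else as.integer(allowed_labels)
  a <- sort(unique(a[!is.na(a)]))
  if (!length(a)) stop("no allowed label is known to the model")
  w <- if (is.character(tokens)) match(tokens, model$vocab)
       else as.integer(tokens)
  w <- w[!is.na(w)]
  theta <- setNames(numeric(K), model$label_names)
  if (!length(w)) {
    theta[a] <- 1 / length(a)
    return(theta)
  }
  phi <- model$topic_word[a, w, drop = FALSE]   # |a| x n
  n <- length(w)
  gam <- matrix(1 / length(a), length(a), n)
  Nk <- rowSums(gam)
  for (it in seq_len(n_iterations)) {
    for (i in seq_len(n)) {
      Nk <- Nk - gam[, i]
      g <- phi[, i] * (Nk + model$alpha)
      g <- g / sum(g)
      gam[, i] <- g
      Nk <- Nk + g
    }
  }
  theta[a] <- (Nk + model$alpha) / (n + length(a) * model$alpha)
  theta[a] <- theta[a] / sum(theta[a])
  theta
}

#' Held-out perplexity
#'
#' Perplexity is the exponentiated negative mean per-token log predictive
#' probability, \code{base^(-1/N * sum(log_base q(x_i)))} with base 2 by
#' default (the value is base-invariant). \code{q(x_i)} is the mixture
#' \code{sum_k theta_dk * phi_k[x_i]}. Under the default document-completion
#' protocol the first half of each held-out document folds in (estimates
#' theta via [infer_doc()]) and the second half is scored, so scored tokens
#' never inform their own theta; \code{method = "full"} folds in and scores
#' all tokens (training-set perplexity). Out-of-vocabulary tokens are
#' dropped and counted.
#'
#' @param model a \code{kitm_model}.
#' @param heldout a \code{kitm_dataset} whose label names appear in the
#'   model.
#' @param base logarithm base (default 2).
#' @param method \code{"completion"} (default) or \code{"full"}.
#' @return object of class \code{kitm_perplexity}: list with \code{value},
#'   \code{n_tokens}, \code{base}, \code{n_oov}.
#' @export
perplexity <- function(model, heldout, base = 2,
                       method = c("completion", "full")) {
  method <- match.arg(method)
  stopifnot(inherits(heldout, "kitm_dataset"))
  loglik <- 0
  N <- 0L
  n_oov <- 0L
  for (d in seq_along(heldout$docs)) {
    toks <- heldout$vocab[heldout$docs[[d]]$tokens]
    labs <- heldout$label_names[heldout$docs[[d]]$labels]
    w <- match(toks, model$vocab)
    n_oov <- n_oov + sum(is.na(w))
    w <- w[!is.na(w)]
    if (!length(w)) next
    if (method == "completion") {
      n_in <- ceiling(length(w) / 2)
      w_in <- w[seq_len(n_in)]
      w_score <- w[setdiff(seq_along(w), seq_len(n_in))]
    } else {
      w_in <- w
      w_score <- w
    }
    if (!length(w_score)) next
    theta <- infer_doc(model, w_in, labs)
    q <- as.numeric(theta %*% model$topic_word[, w_score, drop = FALSE])
    loglik <- loglik + sum(log(q))
    N <- N + length(w_score)
  }
  if (n_oov > 0) {
    message(n_oov, " out-of-vocabulary token(s) dropped from perplexity")
  }
  if (N == 0) stop("no scorable tokens left after out-of-vocabulary dropping")
  # base^(-mean log_base q) == exp(-mean ln q) for any base
  structure(list(value = exp(-loglik / N), n_tokens = N, base = base,
                 n_oov = n_oov),
            class = "kitm_perplexity")
}

#' @export
print.kitm_perplexity <- function(x, ...) {
  cat(sprintf("<perplexity %.3f over %d tokens (base %g)>\n",
              x$value, x$n_tokens, x$base))
  invisible(x)
}

#' Top terms per topic
#'
#' The \code{k} highest-probability vocabulary terms of each topic, ties
#' broken lexicographically. \code{k} larger than the vocabulary returns
#' the full ranking.
#'
#' @param model a \code{kitm_model}.
#' @param k terms per topic (default 5).
#' @return named list (one element per topic/label) of character vectors.
#' @export
top_terms <- function(model, k = 5L) {
  vocab <- colnames(model$topic_word)
  k <- min(k, length(vocab))
  out <- lapply(seq_len(nrow(model$topic_word)), function(t) {
    p <- model$topic_word[t, ]
    vocab[order(-p, vocab)][seq_len(k)]
  })
  names(out) <- rownames(model$topic_word)
  out
}
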