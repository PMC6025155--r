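#' Explicit knowledge rate (EKR)
#'
#' The fraction of a post's terms that carry knowledge-base concepts:
#' \code{n_k / n_raw}, where \code{n_k} counts concept-bearing term
#' occurrences (a concept mentioned three times counts three times) and
#' \code{n_raw} the terms before encoding. Set \code{unique = TRUE} to
#' count distinct concept codes instead of occurrences. Returns 0 for an
#' empty text by convention.
#'
#' @param encoded a \code{kitm_encoded}.
#' @param unique count distinct codes rather than occurrences.
#' @return a number in \code{[0, 1]}.
#' @export
ekr <- function(encoded, unique = FALSE) {
  if (encoded$n_raw == 0) return(0)
  n_k <- if (unique) encoded$n_unique_concepts else encoded$n_concepts
  n_k / encoded$n_raw
}

#' Latent knowledge rate (LKR)
#'
#' Relative growth of a post's concept set after \code{m} layers of
#' knowledge-base expansion: \code{(k_r - k_d) / k_d}, where \code{k_d} is
#' the number of distinct explicit concepts. Two readings of \code{k_r} are
#' implemented. The default, \code{mode = "reachable"}, counts the distinct
#' concepts reachable within \code{m} hierarchy layers from the explicit
#' set, including the explicit concepts themselves, and is non-decreasing
#' in \code{m}. \code{mode = "path_count"} is the literal nested-sum
#' reading — for each explicit concept, the number of length-\code{m} walks
#' in the relation graph — kept as an explicitly labelled alternative.
#'
#' @param encoded a \code{kitm_encoded}, or a character vector of explicit
#'   concept codes.
#' @param kb a \code{kitm_kb}.
#' @param m number of search layers (>= 1).
#' @param mode \code{"reachable"} (default) or \code{"path_count"}.
#' @param edges,directed,hierarchy_label traversal options as in
#'   [discover_latent()].
#' @return a non-negative number; error when the post has no explicit
#'   concepts (the metric is undefined at \code{k_d = 0}).
#' @export
lkr <- function(encoded, kb, m, mode = c("reachable", "path_count"),
                edges = c("hierarchy", "all"), directed = FALSE,
                hierarchy_label = "IS_A") {
  mode <- match.arg(mode)
  edges <- match.arg(edges)
  if (m < 1) stop("m must be >= 1")
  codes <- if (inherits(encoded, "kitm_encoded")) encoded_codes(encoded)
           else unique(as.character(encoded))
  codes <- codes[codes %in% names(kb$concepts)]
  k_d <- length(codes)
  if (k_d == 0) stop("LKR undefined: post has no explicit concepts (k_d = 0)")
  if (mode == "reachable") {
    latent <- character()
    for (z in seq_len(m)) {
      lat <- discover_latent(codes, kb, z, edges = edges, directed = directed,
                             hierarchy_label = hierarchy_label)
      latent <- union(latent, setdiff(lat$triples$t, codes))
    }
    k_r <- k_d + length(latent)
  } else {
    A <- kb_adjacency_matrix(kb, edges, directed, hierarchy_label)
    P <- A
    if (m > 1) for (z in seq(2L, m)) P <- P %*% A
    k_r <- sum(P[codes, , drop = FALSE])
  }
  (k_r - k_d) / k_d
}

# Dense 0/1 adjacency matrix over concept codes; walks of length m are then
# row sums of the m-th matrix power.
kb_adjacency_matrix <- function(kb, edges = "all", directed = FALSE,
                                hierarchy_label = "IS_A") {
  codes <- names(kb$concepts)
  A <- matrix(0, length(codes), length(codes),
              dimnames = list(codes, codes))
  rel <- kb$relations
  if (edges == "hierarchy")
    rel <- rel[rel$label == hierarchy_label, , drop = FALSE]
  if (nrow(rel)) {
    A[cbind(rel$source, rel$target)] <- 1
    if (!directed) A[cbind(rel$target, rel$source)] <- 1
  }
  A
}

#' Knowledge correlation rate (KCR)
#'
#' The fraction of extracted relation triples corroborated by the
#' knowledge base: a triple counts as found when its endpoint concepts are
#' related in the knowledge base — connected by any relation label within
#' \code{hops} hops (default 1). When every extracted triple is a
#' knowledge-base relation the value is 1. An empty triple set returns 1 by
#' convention (vacuous truth) with a message.
#'
#' @param triples data.frame with columns \code{source_code} and
#'   \code{target_code} (e.g. from [extract_relation_items()]).
#' @param kb a \code{kitm_kb}.
#' @param hops corroboration radius in the relation graph (default 1).
#' @return a number in \code{[0, 1]}.
#' @export
kcr <- function(triples, kb, hops = 1L) {
  n <- nrow(triples)
  if (n == 0) {
    message("KCR of an empty triple set is 1 by convention")
    return(1)
  }
  codes <- names(kb$concepts)
  found <- vapply(seq_len(n), function(i) {
    s <- triples$source_code[i]
    t <- triples$target_code[i]
    if (!(s %in% codes) || !(t %in% codes)) return(FALSE)
    is.finite(graph_distance(kb, s, t, max_hops = hops))
  }, logical(1))
  sum(found) / n
}

#' Per-post metric report
#'
#' Computes EKR, LKR at each requested layer count, and KCR for one encoded
#' post, together with the underlying counts.
#'
#' @param encoded a \code{kitm_encoded}.
#' @param kb a \code{kitm_kb}.
#' @param m integer vector of layer counts for LKR (default \code{1:3}).
#' @param window adjacency window for relation-item extraction.
#' @param edges,hierarchy_label traversal options.
#' @return a one-row data.frame: \code{post_id}, \code{n_raw}, \code{n_k},
#'   \code{k_d}, \code{ekr}, \code{ekr_unique}, one \code{lkr_m<z>} column
#'   per layer (NA when undefined), \code{kcr}, \code{n_items}.
#' @export
metric_report <- function(encoded, kb, m = 1:3, window = 4L,
                          edges = "hierarchy", hierarchy_label = "IS_A") {
  items <- extract_relation_items(encoded, kb, window = window)
  k_d <- encoded$n_unique_concepts
  row <- data.frame(post_id = encoded$post_id, n_raw = encoded$n_raw,
                    n_k = encoded$n_concepts, k_d = k_d,
                    ekr = ekr(encoded), ekr_unique = ekr(encoded, unique = TRUE),
                    stringsAsFactors = FALSE)
  for (z in m) {
    row[[paste0("lkr_m", z)]] <- if (k_d > 0)
      lkr(encoded, kb, z, edges = edges, hierarchy_label = hierarchy_label)
    else NA_real_
  }
  row$kcr <- if (nrow(items)) kcr(items, kb) else NA_real_
  row$n_items <- nrow(items)
  row
}
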