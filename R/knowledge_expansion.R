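#' Extract descriptive and semantic relation items from encoded text
#'
#' Descriptive items capture the surface structure: one item for every
#' ordered pair of concept-bearing terms whose token positions are at most
#' \code{window} apart, with relation label \code{"adjacent"}. Semantic
#' items are the subset of those pairs whose code pair is backed by a
#' knowledge-base relation (in either stored direction); they carry the
#' knowledge-base relation label. Items are emitted in order of appearance
#' in the text and carry their token positions as provenance.
#'
#' @param encoded a \code{kitm_encoded}.
#' @param kb a \code{kitm_kb}.
#' @param window maximum token distance between the two terms (default 4).
#' @return data.frame with columns \code{kind} (\code{descriptive} /
#'   \code{semantic}), \code{source_code}, \code{relation_label},
#'   \code{target_code}, \code{post_id}, \code{pos_source},
#'   \code{pos_target}.
#' @export
extract_relation_items <- function(encoded, kb, window = 4L) {
  empty <- data.frame(kind = character(), source_code = character(),
                      relation_label = character(), target_code = character(),
                      post_id = character(), pos_source = integer(),
                      pos_target = integer(), stringsAsFactors = FALSE)
  bearing <- Filter(function(t) nrow(t$codes) > 0, encoded$terms)
  if (length(bearing) < 2) return(empty)
  rel_key <- paste(kb$relations$source, kb$relations$target, sep = "\r")
  rows <- list()
  for (a in seq_len(length(bearing) - 1L)) {
    for (b in seq((a + 1L), length(bearing))) {
      ta <- bearing[[a]]; tb <- bearing[[b]]
      if (tb$start - ta$start > window) break
      for (cs in ta$codes$code) {
        for (ct in tb$codes$code) {
          rows[[length(rows) + 1L]] <- data.frame(
            kind = "descriptive", source_code = cs,
            relation_label = "adjacent", target_code = ct,
            post_id = encoded$post_id, pos_source = ta$start,
            pos_target = tb$start, stringsAsFactors = FALSE)
          hit <- c(which(rel_key == paste(cs, ct, sep = "\r")),
                   which(rel_key == paste(ct, cs, sep = "\r")))
          for (h in hit) {
            rows[[length(rows) + 1L]] <- data.frame(
              kind = "semantic", source_code = kb$relations$source[h],
              relation_label = kb$relations$label[h],
              target_code = kb$relations$target[h],
              post_id = encoded$post_id, pos_source = ta$start,
              pos_target = tb$start, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Discover latent concepts at an exact graph distance
#'
#' For every anchor concept \code{s0}, finds all knowledge-base concepts
#' \code{t} whose shortest-path distance from \code{s0} is exactly \code{z}
#' (the z-th search layer), and emits triples \code{(s0, r, t)} where
#' \code{r} is the label of the final edge of a shortest path; when
#' different shortest paths end in differently labelled edges, one triple
#' per label is kept (set semantics, no tie-break). Anchors not present in
#' the knowledge base are skipped with a message. By default the search is
#' restricted to the hierarchy (IS_A) edges; \code{edges = "all"} traverses
#' every relation type.
#'
#' @param rels0 anchors: a character vector of concept codes, or a
#'   data.frame with a \code{source_code} column (e.g. the output of
#'   [extract_relation_items()]).
#' @param kb a \code{kitm_kb}.
#' @param z layer number (positive integer).
#' @param edges \code{"hierarchy"} (default) or \code{"all"}.
#' @param directed traverse relations in stored direction only.
#' @param hierarchy_label label selecting hierarchy edges.
#' @return object of class \code{kitm_latent}: list with \code{layer} and
#'   \code{triples} (data.frame \code{s0}, \code{relation_label}, \code{t}).
#' @export
discover_latent <- function(rels0, kb, z, edges = c("hierarchy", "all"),
                            directed = FALSE, hierarchy_label = "IS_A") {
  edges <- match.arg(edges)
  if (z < 1) stop("z must be a positive integer")
  anchors <- if (is.data.frame(rels0)) unique(rels0$source_code)
             else unique(as.character(rels0))
  known <- anchors[anchors %in% names(kb$concepts)]
  skipped <- setdiff(anchors, known)
  if (length(skipped)) {
    message("skipping anchor(s) not in the knowledge base: ",
            paste(skipped, collapse = ", "))
  }
  adj <- kb_adjacency(kb, edges, directed, hierarchy_label)
  rows <- list()
  for (s0 in known) {
    dist <- bfs_layers(adj, s0, max_hops = z)
    layer_nodes <- ls(dist)[vapply(ls(dist), function(v) dist[[v]] == z,
                                   logical(1))]
    for (t in layer_nodes) {
      # final-edge labels: edges from any predecessor at distance z-1
      labs <- character()
      for (p in ls(dist)) {
        if (dist[[p]] != z - 1L) next
        nb <- adj[[p]]
        labs <- c(labs, nb$label[nb$to == t])
      }
      for (r in sort(unique(labs))) {
        rows[[length(rows) + 1L]] <- data.frame(
          s0 = s0, relation_label = r, t = t, stringsAsFactors = FALSE)
      }
    }
  }
  triples <- if (length(rows)) do.call(rbind, rows)
             else data.frame(s0 = character(), relation_label = character(),
                             t = character(), stringsAsFactors = FALSE)
  triples <- unique(triples[order(triples$s0, triples$t,
                                  triples$relation_label), , drop = FALSE])
  rownames(triples) <- NULL
  structure(list(layer = as.integer(z), triples = triples),
            class = "kitm_latent")
}

#' Expand an encoded text with latent knowledge-base concepts
#'
#' Implements bag-of-words text expansion: the explicit concepts of a post
#' are augmented, layer by layer up to \code{m}, with every knowledge-base
#' concept at exact shortest-path distance \code{z} from some explicit
#' concept (via [discover_latent()]). Explicit codes are never added to
#' their own latent sets. The expanded token stream is the original term
#' stream plus the normalized preferred name of each latent concept, once
#' per layer occurrence — appended, not interleaved, since the downstream
#' topic model is order-free.
#'
#' @param encoded a \code{kitm_encoded}.
#' @param kb a \code{kitm_kb}.
#' @param m number of search layers (\code{m = 0} returns the text
#'   unchanged).
#' @param edges,directed,hierarchy_label passed to [discover_latent()].
#' @return object of class \code{kitm_expanded}: list with \code{post_id},
#'   \code{explicit_terms} (codes), \code{latent_terms} (list of per-layer
#'   code vectors), \code{expanded_tokens}.
#' @export
expand_text <- function(encoded, kb, m, edges = c("hierarchy", "all"),
                        directed = FALSE, hierarchy_label = "IS_A") {
  edges <- match.arg(edges)
  if (m < 0) stop("m must be >= 0")
  explicit <- encoded_codes(encoded)
  base_tokens <- vapply(encoded$terms, `[[`, character(1), "term")
  latent <- list()
  extra <- character()
  if (m >= 1 && length(explicit)) {
    for (z in seq_len(m)) {
      lat <- discover_latent(explicit, kb, z, edges = edges,
                             directed = directed,
                             hierarchy_label = hierarchy_label)
      codes_z <- setdiff(unique(lat$triples$t), explicit)
      latent[[z]] <- codes_z
      extra <- c(extra,
                 normalize_term(vapply(kb$concepts[codes_z], `[[`,
                                       character(1), "preferred_name")))
    }
  } else if (m >= 1) {
    latent <- rep(list(character()), m)
  }
  structure(list(post_id = encoded$post_id, explicit_terms = explicit,
                 latent_terms = latent,
                 expanded_tokens = c(base_tokens, unname(extra))),
            class = "kitm_expanded")
}
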