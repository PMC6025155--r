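#' @useDynLib kitm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats setNames
NULL

#' Normalize a term string
#'
#' Lowercases, replaces punctuation and symbols with spaces, and collapses
#' whitespace. This is the single normal form in which free text and
#' knowledge-base synonyms meet: the term index and the tokenizer both use
#' it, so a surface form in a post matches a synonym iff their normal forms
#' are equal.
#'
#' @param x character vector of terms.
#' @return character vector of normalized terms.
#' @export
#' @examples
#' normalize_term("Retin-A  Micro") # "retin a micro"
normalize_term <- function(x) {
  x <- tolower(x)
  x <- gsub("[\\p{P}\\p{S}]+", " ", x, perl = TRUE)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

#' Knowledge-base reader configuration
#'
#' Column positions (1-based) for the pipe-delimited concept and relation
#' files, plus traversal options. Defaults follow the MRCONSO / MRREL
#' conventions of UMLS-style distributions: concept id in column 1, source
#' vocabulary in column 12, term string in column 15; relation files carry
#' the first concept in column 1, the relation label in column 4 and the
#' second concept in column 5.
#'
#' @param code_col,source_col,string_col columns of the concept file holding
#'   the concept code, source vocabulary and term string.
#' @param sty_col optional column holding a semantic type (\code{NA} if the
#'   file has none).
#' @param rel_source_col,rel_label_col,rel_target_col columns of the relation
#'   file holding source code, relation label and target code.
#' @param hierarchy_label relation label that defines the concept hierarchy.
#' @param directed_traversal if \code{FALSE} (default) graph queries treat
#'   relations as undirected edges; relation files of real vocabularies
#'   store both directions, toy files may not.
#' @return a list of class \code{kitm_kb_config}.
#' @export
kb_config <- function(code_col = 1L, source_col = 12L, string_col = 15L,
                      sty_col = NA_integer_,
                      rel_source_col = 1L, rel_label_col = 4L,
                      rel_target_col = 5L,
                      hierarchy_label = "IS_A",
                      directed_traversal = FALSE) {
  structure(list(code_col = code_col, source_col = source_col,
                 string_col = string_col, sty_col = sty_col,
                 rel_source_col = rel_source_col,
                 rel_label_col = rel_label_col,
                 rel_target_col = rel_target_col,
                 hierarchy_label = hierarchy_label,
                 directed_traversal = directed_traversal),
            class = "kitm_kb_config")
}

#' Construct a knowledge base
#'
#' The in-memory container for a medical terminology: a set of concepts
#' (code, source vocabulary, preferred name, synonyms, semantic type), a
#' table of typed directed relations between codes, and a term index mapping
#' every normalized synonym to the codes that carry it.
#'
#' @param name knowledge-base name.
#' @param concepts a list of concept records; each record is a list with
#'   fields \code{code}, \code{source}, \code{preferred_name},
#'   \code{synonyms} (character vector containing the preferred name),
#'   \code{semantic_type}, and optionally \code{attributes} (named list)
#'   and \code{definitions} (character vector).
#' @param relations data.frame with character columns \code{source},
#'   \code{label}, \code{target}; duplicated rows are dropped.
#' @return object of class \code{kitm_kb}.
#' @export
knowledge_base <- function(name, concepts, relations = NULL) {
  if (is.null(relations)) {
    relations <- data.frame(source = character(), label = character(),
                            target = character(), stringsAsFactors = FALSE)
  }
  codes <- vapply(concepts, function(cc) cc$code, character(1))
  if (any(codes == "")) stop("concept codes must be non-empty")
  if (anyDuplicated(codes)) {
    stop("duplicate concept code(s): ",
         paste(unique(codes[duplicated(codes)]), collapse = ", "))
  }
  concepts <- lapply(concepts, function(cc) {
    cc$synonyms <- unique(c(cc$preferred_name, cc$synonyms))
    if (is.null(cc$semantic_type)) cc$semantic_type <- ""
    if (is.null(cc$attributes)) cc$attributes <- list()
    if (is.null(cc$definitions)) cc$definitions <- character()
    cc
  })
  names(concepts) <- codes
  relations <- unique(relations[, c("source", "label", "target")])
  rownames(relations) <- NULL
  dangling <- setdiff(unique(c(relations$source, relations$target)), codes)
  if (length(dangling)) {
    stop("relation endpoint(s) not present as concepts: ",
         paste(dangling, collapse = ", "))
  }
  kb <- structure(list(name = name, concepts = concepts,
                       relations = relations, term_index = NULL),
                  class = "kitm_kb")
  kb$term_index <- build_term_index(kb)
  kb
}

build_term_index <- function(kb) {
  idx <- new.env(parent = emptyenv())
  for (cc in kb$concepts) {
    for (s in unique(normalize_term(cc$synonyms))) {
      if (!nzchar(s)) next
      idx[[s]] <- unique(c(idx[[s]], cc$code))
    }
  }
  idx
}

#' Look up a normalized term in a knowledge base
#'
#' @param kb a \code{kitm_kb}.
#' @param term character vector of terms (normalized internally).
#' @return list of character vectors of matching codes (empty when no match).
#' @export
kb_lookup <- function(kb, term) {
  lapply(normalize_term(term), function(t) {
    hit <- kb$term_index[[t]]
    if (is.null(hit)) character() else hit
  })
}

#' @export
print.kitm_kb <- function(x, ...) {
  cat(sprintf("<kitm_kb '%s': %d concepts, %d relations, %d indexed terms>\n",
              x$name, length(x$concepts), nrow(x$relations),
              length(ls(x$term_index))))
  invisible(x)
}

read_pipe_file <- function(path, n_fields_min) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "|", fixed = TRUE)
  bad <- which(lengths(fields) < n_fields_min)
  if (length(bad)) {
    stop(sprintf("malformed line %d in %s: expected at least %d fields, got %d",
                 bad[1], path, n_fields_min, lengths(fields)[bad[1]]))
  }
  fields
}

#' Read a knowledge base from pipe-delimited concept/relation files
#'
#' Reads the RRF dialect: one record per line, fields separated by \code{|}.
#' All rows of the concept file sharing a code are merged into one concept
#' whose synonym set is the union of their strings (first string seen
#' becomes the preferred name). Relations are deduplicated. Which columns
#' carry the code, string, source and relation label is configurable; the
#' defaults follow the MRCONSO / MRREL layout.
#'
#' @param conso_path path to the concept (MRCONSO-style) file.
#' @param rel_path path to the relation (MRREL-style) file, or \code{NULL}
#'   for a relation-free knowledge base.
#' @param config a [kb_config()].
#' @param name knowledge-base name.
#' @return a \code{kitm_kb}.
#' @export
load_rrf_kb <- function(conso_path, rel_path = NULL, config = kb_config(),
                        name = "RRF") {
  nmin <- max(config$code_col, config$source_col, config$string_col,
              if (!is.na(config$sty_col)) config$sty_col else 0L)
  rows <- read_pipe_file(conso_path, nmin)
  concepts <- list()
  for (f in rows) {
    code <- f[[config$code_col]]
    str <- f[[config$string_col]]
    src <- f[[config$source_col]]
    sty <- if (!is.na(config$sty_col)) f[[config$sty_col]] else ""
    if (is.null(concepts[[code]])) {
      concepts[[code]] <- list(code = code, source = src,
                               preferred_name = str, synonyms = str,
                               semantic_type = sty)
    } else {
      concepts[[code]]$synonyms <- unique(c(concepts[[code]]$synonyms, str))
      if (nzchar(sty) && !nzchar(concepts[[code]]$semantic_type))
        concepts[[code]]$semantic_type <- sty
    }
  }
  relations <- NULL
  if (!is.null(rel_path)) {
    rmin <- max(config$rel_source_col, config$rel_label_col,
                config$rel_target_col)
    rrows <- read_pipe_file(rel_path, rmin)
    relations <- data.frame(
      source = vapply(rrows, `[[`, character(1), config$rel_source_col),
      label = vapply(rrows, `[[`, character(1), config$rel_label_col),
      target = vapply(rrows, `[[`, character(1), config$rel_target_col),
      stringsAsFactors = FALSE)
  }
  knowledge_base(name, unname(concepts), relations)
}

#' Read a knowledge base from the toy TSV dialect
#'
#' A self-contained plain-text format for small knowledge bases:
#' \preformatted{
#'   #KB <name>
#'   #CONCEPTS
#'   code <TAB> source <TAB> preferred_name <TAB> syn1;syn2;... <TAB> semantic_type
#'   #RELATIONS
#'   source_code <TAB> label <TAB> target_code
#' }
#' Lines starting with \code{//} and blank lines are ignored; the synonym
#' field may be empty. If the file declares hierarchy (IS_A) relations they
#' are checked for cycles at load time.
#'
#' @param path path to the TSV file.
#' @param hierarchy_label relation label defining the hierarchy (checked for
#'   acyclicity).
#' @return a \code{kitm_kb}.
#' @export
load_toy_kb <- function(path, hierarchy_label = "IS_A") {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines, which = "right")
  lines <- lines[nzchar(lines) & !startsWith(lines, "//")]
  name <- "toy"
  section <- ""
  concepts <- list()
  rel_rows <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, "#KB")) { name <- trimws(sub("^#KB", "", ln)); next }
    if (ln == "#CONCEPTS") { section <- "concepts"; next }
    if (ln == "#RELATIONS") { section <- "relations"; next }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (section == "concepts") {
      if (length(f) < 3) stop(sprintf("malformed concept line %d in %s", i, path))
      code <- f[1]
      if (!is.null(concepts[[code]])) stop("duplicate concept code: ", code)
      syns <- if (length(f) >= 4 && nzchar(f[4]))
        strsplit(f[4], ";", fixed = TRUE)[[1]] else character()
      concepts[[code]] <- list(
        code = code, source = f[2], preferred_name = f[3], synonyms = syns,
        semantic_type = if (length(f) >= 5) f[5] else "")
    } else if (section == "relations") {
      if (length(f) != 3) stop(sprintf("malformed relation line %d in %s", i, path))
      rel_rows[[length(rel_rows) + 1L]] <- f
    } else {
      stop(sprintf("line %d in %s outside any section", i, path))
    }
  }
  relations <- if (length(rel_rows)) {
    data.frame(source = vapply(rel_rows, `[`, character(1), 1),
               label = vapply(rel_rows, `[`, character(1), 2),
               target = vapply(rel_rows, `[`, character(1), 3),
               stringsAsFactors = FALSE)
  } else NULL
  kb <- knowledge_base(name, unname(concepts), relations)
  build_hierarchy(kb, hierarchy_label)  # validates acyclicity, error on cycle
  kb
}

#' Extract the concept hierarchy from a knowledge base
#'
#' The hierarchy is the subgraph of relations carrying the hierarchy label
#' (IS_A by default): an edge (child, parent) for every relation
#' \code{child IS_A parent}. The result must be acyclic — layer counting in
#' latent-knowledge expansion diverges on cycles, so cyclic input is
#' rejected with one offending cycle reported.
#'
#' @param kb a \code{kitm_kb}.
#' @param hierarchy_label relation label to select (default \code{"IS_A"}).
#' @return object of class \code{kitm_hierarchy}: list with \code{kb_name}
#'   and \code{isa_edges} (data.frame \code{child}, \code{parent}).
#' @export
build_hierarchy <- function(kb, hierarchy_label = "IS_A") {
  rel <- kb$relations[kb$relations$label == hierarchy_label, , drop = FALSE]
  edges <- data.frame(child = rel$source, parent = rel$target,
                      stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  cyc <- find_cycle(edges$child, edges$parent)
  if (!is.null(cyc)) {
    stop("cyclic ", hierarchy_label, " hierarchy: ",
         paste(cyc, collapse = " -> "))
  }
  structure(list(kb_name = kb$name, isa_edges = edges),
            class = "kitm_hierarchy")
}

# Depth-first cycle detection on a directed edge list; returns one cycle as
# a code vector, or NULL when acyclic.
find_cycle <- function(from, to) {
  nodes <- unique(c(from, to))
  adj <- split(to, factor(from, levels = nodes))
  state <- setNames(rep(0L, length(nodes)), nodes)  # 0 new, 1 open, 2 done
  path <- character()
  found <- NULL
  visit <- function(v) {
    if (!is.null(found)) return()
    state[[v]] <<- 1L
    path <<- c(path, v)
    for (w in adj[[v]]) {
      if (state[[w]] == 1L) {
        found <<- c(path[which(path == w)[1]:length(path)], w)
        return()
      }
      if (state[[w]] == 0L) visit(w)
      if (!is.null(found)) return()
    }
    state[[v]] <<- 2L
    path <<- path[-length(path)]
  }
  for (v in nodes) if (state[[v]] == 0L) visit(v)
  found
}

# Adjacency list over relation edges. edges = "all" uses every relation,
# "hierarchy" only those with the given hierarchy label. Undirected unless
# directed = TRUE.
kb_adjacency <- function(kb, edges = c("all", "hierarchy"), directed = FALSE,
                         hierarchy_label = "IS_A") {
  edges <- match.arg(edges)
  rel <- kb$relations
  if (edges == "hierarchy")
    rel <- rel[rel$label == hierarchy_label, , drop = FALSE]
  from <- rel$source; to <- rel$target; lab <- rel$label
  if (!directed) {
    tmp <- from
    from <- c(from, to); to <- c(to, tmp); lab <- c(lab, lab)
  }
  codes <- names(kb$concepts)
  adj <- split(data.frame(to = to, label = lab, stringsAsFactors = FALSE),
               factor(from, levels = codes))
  adj
}

#' Shortest relation-path distance between two concepts
#'
#' Breadth-first search over the relation graph. By default every relation
#' type contributes an edge and traversal is undirected (relation files of
#' real vocabularies store both directions; toy files may not).
#'
#' @param kb a \code{kitm_kb}.
#' @param from_code,to_code concept codes (must exist in \code{kb}).
#' @param max_hops search horizon; paths longer than this count as
#'   unreachable.
#' @param edges \code{"all"} (default) or \code{"hierarchy"} to restrict to
#'   hierarchy edges.
#' @param directed traverse relations in their stored direction only.
#' @param hierarchy_label label selecting hierarchy edges.
#' @return integer path length, or \code{Inf} when no path within
#'   \code{max_hops} exists.
#' @export
graph_distance <- function(kb, from_code, to_code, max_hops = Inf,
                           edges = "all", directed = FALSE,
                           hierarchy_label = "IS_A") {
  for (code in c(from_code, to_code)) {
    if (is.null(kb$concepts[[code]])) stop("unknown concept code: ", code)
  }
  if (from_code == to_code) return(0L)
  adj <- kb_adjacency(kb, edges, directed, hierarchy_label)
  dist <- bfs_layers(adj, from_code, max_hops, stop_at = to_code)
  d <- dist[[to_code]]
  if (is.null(d)) Inf else d
}

# BFS from `start` over adjacency list `adj`; returns an environment mapping
# code -> distance for all nodes within max_hops. Stops early when stop_at
# is reached.
bfs_layers <- function(adj, start, max_hops = Inf, stop_at = NULL) {
  dist <- new.env(parent = emptyenv())
  dist[[start]] <- 0L
  frontier <- start
  d <- 0L
  while (length(frontier) && d < max_hops) {
    d <- d + 1L
    nxt <- character()
    for (v in frontier) {
      nb <- adj[[v]]$to
      for (w in nb) {
        if (is.null(dist[[w]])) {
          dist[[w]] <- d
          nxt <- c(nxt, w)
          if (!is.null(stop_at) && w == stop_at) return(dist)
        }
      }
    }
    frontier <- unique(nxt)
  }
  dist
}

#' Serialize a knowledge base to canonical JSON
#'
#' Concepts sorted by code, synonyms sorted, relations sorted
#' lexicographically; two knowledge bases with the same content serialize
#' identically regardless of load order or input dialect.
#'
#' @param kb a \code{kitm_kb}.
#' @param path optional file path; when given the JSON is written there.
#' @return the JSON string, invisibly when \code{path} is given.
#' @export
kb_to_json <- function(kb, path = NULL) {
  codes <- sort(names(kb$concepts))
  concepts <- lapply(kb$concepts[codes], function(cc) {
    list(code = cc$code, source = cc$source,
         preferred_name = cc$preferred_name,
         synonyms = sort(unique(cc$synonyms)),
         semantic_type = cc$semantic_type)
  })
  rel <- kb$relations
  rel <- rel[order(rel$source, rel$label, rel$target), , drop = FALSE]
  rownames(rel) <- NULL
  out <- jsonlite::toJSON(list(name = kb$name, concepts = unname(concepts),
                               relations = rel),
                          auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}
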