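#' Construct a phenotype ontology graph
#'
#' An ontology is a rooted directed acyclic graph of terms connected by
#' `is_a` edges (child to parent; multiple parentage allowed). This is the
#' in-memory representation used by all closure queries, organ-system
#' assignment and phenotype counting.
#'
#' @param terms Character vector of term IDs.
#' @param parents Named list mapping each term ID to a character vector of
#'   its parent term IDs (the root maps to `character(0)`).
#' @param labels Optional named character vector of human-readable labels.
#' @param root Term ID of the designated root. If `NULL`, the unique term
#'   with no parents is used.
#' @return An object of class `ontology`.
#' @export
ontology <- function(terms, parents, labels = NULL, root = NULL) {
  terms <- as.character(terms)
  if (anyDuplicated(terms)) stop_data("duplicate term IDs in ontology")
  parents <- parents[terms]
  parents[vapply(parents, is.null, logical(1))] <- list(character(0))
  names(parents) <- terms
  unknown <- setdiff(unlist(parents, use.names = FALSE), terms)
  if (length(unknown))
    stop_data("is_a edges point to unknown terms: ",
              paste(utils::head(unknown, 5), collapse = ", "))
  if (is.null(root)) {
    r <- terms[lengths(parents) == 0L]
    if (length(r) != 1L)
      stop_data("ontology must have exactly one parentless root (found ",
                length(r), "); pass `root` explicitly")
    root <- r
  }
  # children adjacency, the representation closures traverse
  children <- rep(list(character(0)), length(terms))
  names(children) <- terms
  for (t in terms) for (p in parents[[t]])
    children[[p]] <- c(children[[p]], t)

  g <- structure(list(terms = terms, parents = parents, children = children,
                      labels = labels, root = root),
                 class = "ontology")
  assert_acyclic(g)
  g
}

assert_acyclic <- function(g) {
  # Kahn's algorithm on child -> parent edges
  indeg <- lengths(g$parents)
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  indeg_env <- as.list(indeg)
  while (length(queue)) {
    t <- queue[[1]]; queue <- queue[-1]; seen <- seen + 1L
    for (ch in g$children[[t]]) {
      indeg_env[[ch]] <- indeg_env[[ch]] - 1L
      if (indeg_env[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen != length(g$terms)) stop_data("ontology graph contains a cycle")
  invisible(g)
}

#' @export
print.ontology <- function(x, ...) {
  cat("Ontology:", length(x$terms), "terms,",
      sum(lengths(x$parents)), "is_a edges, root", x$root, "\n")
  invisible(x)
}

#' Read an ontology from an OBO file
#'
#' Minimal reader for the OBO flat-file dialect used by the Human Phenotype
#' Ontology: `[Term]` stanzas with `id`, `name`, and `is_a` tags. Obsolete
#' terms and all non-`is_a` relationships are ignored.
#'
#' @param path Path to a `.obo` file.
#' @param root Optional root term ID (default: the unique parentless term).
#' @return An [ontology] object.
#' @export
read_obo <- function(path, root = NULL) {
  lines <- readLines(path, warn = FALSE)
  ids <- character(0); labels <- character(0); parents <- list()
  cur <- NULL; cur_parents <- character(0); cur_label <- NA_character_
  obsolete <- FALSE; in_term <- FALSE
  flush <- function() {
    if (!is.null(cur) && !obsolete) {
      ids[[length(ids) + 1L]] <<- cur
      labels[[length(labels) + 1L]] <<- cur_label
      parents[[cur]] <<- unique(cur_parents)
    }
  }
  for (l in lines) {
    l <- sub("!.*$", "", l)
    l <- trimws(l)
    if (l == "[Term]") { flush(); in_term <- TRUE; cur <- NULL
      cur_parents <- character(0); cur_label <- NA_character_; obsolete <- FALSE
      next }
    if (grepl("^\\[", l)) { flush(); in_term <- FALSE; cur <- NULL; next }
    if (!in_term || !nzchar(l)) next
    if (grepl("^id:", l)) cur <- trimws(sub("^id:", "", l))
    else if (grepl("^name:", l)) cur_label <- trimws(sub("^name:", "", l))
    else if (grepl("^is_a:", l)) {
      tgt <- trimws(sub("^is_a:", "", l))
      cur_parents <- c(cur_parents, strsplit(tgt, "\\s+")[[1]][1])
    } else if (grepl("^is_obsolete:\\s*true", l)) obsolete <- TRUE
  }
  flush()
  # drop dangling edges to terms outside the file (e.g. pruned subsets)
  parents <- lapply(parents, function(p) intersect(p, ids))
  names(labels) <- ids
  ontology(ids, parents, labels = labels, root = root)
}

#' Term plus all of its transitive descendants
#'
#' Implements the "term and its daughter nodes" search used when counting
#' probands with an abnormality of an organ or organ system. Returns a set:
#' under multiple parentage a term appears once.
#'
#' @param graph An [ontology].
#' @param term A term ID present in `graph`.
#' @return Character vector: `term` and every transitive descendant.
#' @export
descendant_closure <- function(graph, term) {
  stopifnot(inherits(graph, "ontology"))
  if (!term %in% graph$terms) stop_data("unknown term: ", term)
  seen <- new.env(parent = emptyenv())
  stack <- term
  out <- character(0)
  while (length(stack)) {
    t <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    if (!is.null(seen[[t]])) next
    seen[[t]] <- TRUE
    out <- c(out, t)
    stack <- c(stack, graph$children[[t]])
  }
  sort(out)
}

#' Assign every term to at most one organ system
#'
#' Builds the many-to-one term-to-system map used to count distinct affected
#' organ systems without redundancy: a term descending from several system
#' roots is assigned to the root with the smallest descendant closure (the
#' most specific system), with remaining ties broken by lexicographic root
#' ID. A priority list can override the tie-break.
#'
#' @param graph An [ontology].
#' @param system_roots Character vector of system root term IDs (e.g. the
#'   top-level "Abnormality of ..." terms).
#' @param priority Optional character vector; when a term falls under several
#'   roots, the earliest root in `priority` wins before the closure-size rule
#'   applies.
#' @return An object of class `organ_system_map`: a named character vector
#'   mapping term ID to its assigned system root (terms under no root are
#'   absent).
#' @export
assign_organ_systems <- function(graph, system_roots, priority = NULL) {
  stopifnot(inherits(graph, "ontology"))
  missing_roots <- setdiff(system_roots, graph$terms)
  if (length(missing_roots))
    stop_config("system roots not in ontology: ",
                paste(missing_roots, collapse = ", "))
  closures <- lapply(system_roots, function(r) descendant_closure(graph, r))
  names(closures) <- system_roots
  sizes <- lengths(closures)

  candidates <- new.env(parent = emptyenv())
  for (r in system_roots)
    for (t in closures[[r]])
      candidates[[t]] <- c(candidates[[t]], r)

  terms <- ls(candidates)
  assignment <- vapply(terms, function(t) {
    cand <- candidates[[t]]
    if (!is.null(priority)) {
      hit <- priority[priority %in% cand]
      if (length(hit)) return(hit[[1]])
    }
    cand <- cand[order(sizes[cand], cand)]
    cand[[1]]
  }, character(1))
  structure(assignment, class = "organ_system_map",
            system_roots = system_roots)
}

#' Number of distinct affected organ systems for one proband
#'
#' A proband's HPO terms are mapped through an [assign_organ_systems] map and
#' the distinct assigned system roots are counted, so a term and its
#' same-system ancestor contribute once. Terms absent from the map (unknown
#' or outside every system) are ignored with a warning for unknown terms.
#'
#' @param proband_terms Character vector of term IDs annotated to a proband.
#' @param map An `organ_system_map`.
#' @param graph Optional [ontology]; when supplied, terms absent from the
#'   ontology trigger a warning (they are ignored either way).
#' @return Integer count of distinct systems.
#' @export
count_affected_systems <- function(proband_terms, map, graph = NULL) {
  stopifnot(inherits(map, "organ_system_map"))
  proband_terms <- unique(as.character(proband_terms))
  if (!is.null(graph)) {
    unknown <- setdiff(proband_terms, graph$terms)
    if (length(unknown))
      warning("ignoring terms not in ontology: ",
              paste(unknown, collapse = ", "))
  }
  length(unique(unname(map[intersect(proband_terms, names(map))])))
}

#' Does a proband carry a phenotype term or any of its descendants?
#'
#' The closure-query predicate behind per-term prevalence counts: true iff
#' the proband's annotations intersect the descendant closure of the query
#' term.
#'
#' @param proband_terms Character vector of annotated term IDs.
#' @param graph An [ontology].
#' @param query_term Term ID to query.
#' @return Logical scalar.
#' @export
has_phenotype <- function(proband_terms, graph, query_term) {
  length(intersect(proband_terms, descendant_closure(graph, query_term))) > 0L
}
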