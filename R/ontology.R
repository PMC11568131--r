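# GO ontology handling: OBO parsing restricted to is-a/part-of, ancestor
# queries, true-path-rule propagation, information accretion, vocabulary
# selection.

OBO_NAMESPACES <- c(molecular_function = "MFO",
                    biological_process = "BPO",
                    cellular_component = "CCO")

#' Construct a GO ontology object
#'
#' Internal constructor shared by [parse_obo()] and the synthetic generator.
#' Validates acyclicity, drops cross-aspect edges, and indexes parents and
#' children for fast traversal.
#'
#' @param terms character vector of canonical term identifiers.
#' @param edges data.frame with columns `child`, `parent`, `relation`
#'   (`"is_a"` or `"part_of"`).
#' @param aspect named character vector mapping each term to MFO/BPO/CCO.
#' @param alt named character vector mapping alternate ids to canonical ids.
#' @param name optional named character vector of human-readable term names.
#' @return an object of class `go_ontology`.
#' @noRd
new_ontology <- function(terms, edges, aspect, alt = character(), name = NULL) {
  terms <- as.character(terms)
  if (anyDuplicated(terms))
    stop("duplicated term identifiers in ontology", call. = FALSE)
  missing_aspect <- setdiff(terms, names(aspect))
  if (length(missing_aspect))
    stop("terms without an aspect: ", paste(missing_aspect, collapse = ", "),
         call. = FALSE)

  dangling <- setdiff(unique(c(edges$child, edges$parent)), terms)
  if (length(dangling))
    stop("edges reference undefined term(s): ",
         paste(dangling, collapse = ", "), call. = FALSE)

  # relationships that cross aspects are dropped; propagation never leaves
  # a sub-ontology
  if (nrow(edges)) {
    keep <- aspect[edges$child] == aspect[edges$parent]
    edges <- edges[keep, , drop = FALSE]
    rownames(edges) <- NULL
  }

  g <- igraph::graph_from_data_frame(
    edges[, c("child", "parent")],
    directed = TRUE,
    vertices = data.frame(name = terms, stringsAsFactors = FALSE)
  )
  if (!igraph::is_dag(g))
    stop("ontology edge relation contains a cycle", call. = FALSE)

  parents <- split(edges$parent, factor(edges$child, levels = terms))
  children <- split(edges$child, factor(edges$parent, levels = terms))

  roots <- terms[lengths(parents) == 0L]
  obj <- structure(list(
    terms = terms,
    edges = edges,
    aspect = aspect[terms],
    parents = parents,
    children = children,
    roots = roots,
    alt = alt,
    name = name,
    graph = g
  ), class = "go_ontology")
  obj
}

#' Parse a GO ontology from an OBO 1.2 flat file
#'
#' Reads `[Term]` stanzas, keeping only the "is_a" and
#' "relationship: part_of" relations.  Obsolete terms are skipped and
#' `alt_id` lines are recorded so alternate identifiers resolve to their
#' canonical term.  Relationship edges whose endpoints belong to different
#' aspects (namespaces) are dropped, so annotation propagation never leaves
#' a sub-ontology.
#'
#' @param path path to an OBO 1.2 file.
#' @return an object of class `go_ontology` with elements `terms`, `edges`
#'   (child, parent, relation), `aspect` (named MFO/BPO/CCO vector),
#'   `parents`, `children`, `roots`, and `alt` (alternate-id map).
#' @examples
#' obo <- system.file("extdata", "toy_ontology.obo", package = "gofuse")
#' ont <- parse_obo(obo)
#' ont$roots
#' @seealso [go_ancestors()], [propagate_annotations()], [compute_ia()]
#' @export
parse_obo <- function(path) {
  if (!file.exists(path)) stop("OBO file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)

  stanza_at <- grep("^\\[", lines)
  is_term <- lines[stanza_at] == "[Term]"
  ends <- c(stanza_at[-1] - 1L, length(lines))

  ids <- character()
  aspects <- character()
  names_ <- character()
  alt <- character()
  edge_child <- character(); edge_parent <- character(); edge_rel <- character()

  for (k in seq_along(stanza_at)) {
    if (!is_term[k]) next
    body <- lines[seq(stanza_at[k] + 1L, ends[k])]
    tag_val <- function(tag) {
      v <- body[startsWith(body, paste0(tag, ": "))]
      sub("\\s*!.*$", "", substring(v, nchar(tag) + 3L))
    }
    if (any(tag_val("is_obsolete") == "true")) next
    id <- tag_val("id")
    if (length(id) != 1L || !nzchar(id))
      stop(sprintf("malformed [Term] stanza at line %d: missing id",
                   stanza_at[k]), call. = FALSE)
    ns <- tag_val("namespace")
    if (length(ns) != 1L || is.na(OBO_NAMESPACES[ns]))
      stop(sprintf("term %s: missing or unknown namespace", id), call. = FALSE)

    ids <- c(ids, id)
    aspects[id] <- OBO_NAMESPACES[[ns]]
    nm <- tag_val("name")
    if (length(nm) == 1L) names_[id] <- nm
    for (a in tag_val("alt_id")) alt[a] <- id

    for (p in tag_val("is_a")) {
      edge_child <- c(edge_child, id)
      edge_parent <- c(edge_parent, trimws(p))
      edge_rel <- c(edge_rel, "is_a")
    }
    rel <- tag_val("relationship")
    po <- grep("^part_of\\s+", rel, value = TRUE)
    for (p in sub("^part_of\\s+", "", po)) {
      edge_child <- c(edge_child, id)
      edge_parent <- c(edge_parent, trimws(p))
      edge_rel <- c(edge_rel, "part_of")
    }
  }

  edges <- data.frame(child = edge_child, parent = edge_parent,
                      relation = edge_rel, stringsAsFactors = FALSE)
  # edges to obsolete (skipped) terms would show up as dangling parents
  new_ontology(ids, edges, aspects, alt = alt, name = names_)
}

#' @export
print.go_ontology <- function(x, ...) {
  cat(sprintf("GO ontology: %d terms, %d is-a/part-of edges\n",
              length(x$terms), nrow(x$edges)))
  tab <- table(x$aspect)
  cat("  aspects:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  cat("  roots:", paste(x$roots, collapse = ", "), "\n")
  invisible(x)
}

#' Resolve a (possibly alternate) term identifier
#' @noRd
resolve_term <- function(ontology, term) {
  hit <- term %in% ontology$terms
  out <- term
  if (!all(hit)) {
    via_alt <- ontology$alt[term[!hit]]
    if (anyNA(via_alt))
      stop("unknown GO term(s): ",
           paste(term[!hit][is.na(via_alt)], collapse = ", "), call. = FALSE)
    out[!hit] <- via_alt
  }
  out
}

#' Ancestors of a GO term
#'
#' All terms reachable from `term` by following is-a/part-of edges towards
#' the root, excluding the term itself.  Alternate identifiers are resolved
#' first.
#'
#' @param ontology a `go_ontology`.
#' @param term a single term identifier (canonical or alternate).
#' @return character vector of ancestor identifiers (possibly empty).
#' @export
go_ancestors <- function(ontology, term) {
  term <- resolve_term(ontology, term)
  anc <- igraph::subcomponent(ontology$graph, term, mode = "out")
  setdiff(names(anc), term)
}

#' Propagate annotations to the root (true-path rule)
#'
#' Expands each protein's annotated term set to include every ancestor
#' reachable via is-a/part-of edges.  The operation is idempotent: applying
#' it to already-propagated annotations returns the same set.
#'
#' @param table data.frame with columns `protein` and `term` (additional
#'   columns are ignored); term ids may be alternates.
#' @param ontology a `go_ontology`.
#' @return a data.frame of class `go_propagated` with columns `protein`,
#'   `term`, `aspect`, one row per unique (protein, term) pair.
#' @export
propagate_annotations <- function(table, ontology) {
  stopifnot(is.data.frame(table), all(c("protein", "term") %in% names(table)))
  if (!nrow(table)) {
    out <- data.frame(protein = character(), term = character(),
                      aspect = character(), stringsAsFactors = FALSE)
    class(out) <- c("go_propagated", "data.frame")
    return(out)
  }
  terms_raw <- as.character(table$term)
  ok <- terms_raw %in% ontology$terms | terms_raw %in% names(ontology$alt)
  if (!all(ok)) {
    bad <- which(!ok)[1L]
    stop(sprintf("protein %s is annotated with unresolvable term %s",
                 table$protein[bad], terms_raw[bad]), call. = FALSE)
  }
  terms_res <- resolve_term(ontology, terms_raw)

  uniq <- unique(terms_res)
  anc <- lapply(uniq, function(t) c(t, go_ancestors(ontology, t)))
  names(anc) <- uniq

  prot <- rep(as.character(table$protein), lengths(anc[terms_res]))
  term <- unlist(anc[terms_res], use.names = FALSE)
  keep <- !duplicated(paste(prot, term, sep = "\r"))
  out <- data.frame(protein = prot[keep], term = term[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$protein, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out$aspect <- unname(ontology$aspect[out$term])
  class(out) <- c("go_propagated", "data.frame")
  out
}

#' Check that an annotation table is ancestor-closed
#' @noRd
is_propagated <- function(propagated, ontology) {
  sets <- split(propagated$term, propagated$protein)
  for (s in sets) {
    pars <- unique(unlist(ontology$parents[s], use.names = FALSE))
    if (!all(pars %in% s)) return(FALSE)
  }
  TRUE
}

#' Information accretion of GO terms
#'
#' For a term q with parent set Pa(q), the information accretion is
#' \deqn{IA(q) = \log_2\frac{1 + |\{i : Pa(q) \subseteq T_i\}|}{1 + |\{i : q \in T_i\}|}}
#' where T_i is the (propagated) term set of protein i and the counts are
#' taken within the term's aspect.  For a multi-parent term the numerator
#' counts proteins carrying *all* parents; for an aspect root it is the
#' total number of annotated proteins of that aspect, so a root propagated
#' to every protein has IA = 0.  Propagation guarantees IA >= 0.
#'
#' @param propagated a `go_propagated` table (see
#'   [propagate_annotations()]); passing unpropagated annotations is an
#'   error because the carrier counts would be inconsistent.
#' @param ontology a `go_ontology`.
#' @param aspect optional single aspect (MFO/BPO/CCO); default computes all.
#' @return named numeric vector of IA values in bits, over every ontology
#'   term of the requested aspect(s).
#' @export
compute_ia <- function(propagated, ontology, aspect = NULL) {
  stopifnot(inherits(propagated, "go_propagated") ||
              all(c("protein", "term") %in% names(propagated)))
  if (!is_propagated(propagated, ontology))
    stop(paste("annotations are not ancestor-closed;",
               "run propagate_annotations() first"), call. = FALSE)
  aspects <- if (is.null(aspect)) GO_ASPECTS else check_aspect(aspect)

  term_aspect <- ontology$aspect
  prop_aspect <- term_aspect[propagated$term]

  out <- numeric(0)
  for (a in aspects) {
    terms_a <- ontology$terms[term_aspect == a]
    if (!length(terms_a)) next
    sub <- propagated[prop_aspect == a, , drop = FALSE]
    carriers <- lapply(split(sub$protein, factor(sub$term, levels = terms_a)),
                       unique)
    n_universe <- length(unique(sub$protein))
    n_q <- lengths(carriers)
    n_parents <- vapply(terms_a, function(t) {
      pa <- ontology$parents[[t]]
      if (!length(pa)) return(n_universe)  # aspect root
      common <- carriers[[pa[1L]]]
      for (p in pa[-1L]) common <- intersect(common, carriers[[p]])
      length(common)
    }, numeric(1))
    ia <- log2((1 + n_parents) / (1 + n_q[terms_a]))
    names(ia) <- terms_a
    out <- c(out, ia)
  }
  out
}

#' Select the prediction vocabulary for one aspect
#'
#' Keeps the terms of the aspect carried by at least `min_count` training
#' proteins after propagation.  Defaults follow common practice for GO
#' benchmarks: 50 training proteins for BPO terms and 10 for MFO and CCO.
#' Terms are ordered lexicographically so column indices are reproducible.
#'
#' @param propagated a `go_propagated` table of training annotations.
#' @param aspect one of MFO/BPO/CCO.
#' @param min_count minimum number of carrier proteins; `NULL` uses the
#'   per-aspect default.
#' @return object of class `go_vocabulary`: list with `aspect`, `terms`
#'   (ordered), `index` (term -> 1-based column), `min_count`.
#' @export
select_vocabulary <- function(propagated, aspect, min_count = NULL) {
  check_aspect(aspect)
  if (is.null(min_count)) min_count <- if (aspect == "BPO") 50L else 10L
  if (min_count < 1L) stop("`min_count` must be >= 1", call. = FALSE)
  sub <- propagated[propagated$aspect == aspect, , drop = FALSE]
  counts <- tapply(sub$protein, sub$term, function(p) length(unique(p)))
  sel <- sort(names(counts)[counts >= min_count])
  if (!length(sel))
    warning(sprintf("no %s term reaches min_count = %d; empty vocabulary",
                    aspect, min_count), call. = FALSE)
  structure(list(aspect = aspect, terms = sel,
                 index = stats::setNames(seq_along(sel), sel),
                 min_count = as.integer(min_count)),
            class = "go_vocabulary")
}

#' @export
print.go_vocabulary <- function(x, ...) {
  cat(sprintf("GO vocabulary: %d %s terms (min_count = %d)\n",
              length(x$terms), x$aspect, x$min_count))
  invisible(x)
}

#' Binary label matrix over a vocabulary
#'
#' @param propagated a `go_propagated` table.
#' @param vocabulary a `go_vocabulary`.
#' @param proteins optional character vector fixing row order; defaults to
#'   the sorted proteins present in `propagated`.
#' @return binary matrix proteins x vocabulary terms with dimnames.
#' @export
label_matrix <- function(propagated, vocabulary, proteins = NULL) {
  if (is.null(proteins))
    proteins <- sort(unique(propagated$protein))
  m <- matrix(0, length(proteins), length(vocabulary$terms),
              dimnames = list(proteins, vocabulary$terms))
  sub <- propagated[propagated$term %in% vocabulary$terms &
                      propagated$protein %in% proteins, , drop = FALSE]
  if (nrow(sub)) m[cbind(sub$protein, sub$term)] <- 1
  m
}

#' Write an ontology as an OBO 1.2 flat file
#'
#' Emits one `[Term]` stanza per term with id, name, namespace, is_a and
#' `relationship: part_of` lines, so generated ontologies round-trip
#' through [parse_obo()].
#'
#' @param ontology a `go_ontology`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(ontology, path) {
  ns <- stats::setNames(names(OBO_NAMESPACES), OBO_NAMESPACES)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (t in ontology$terms) {
    nm <- ontology$name[t]
    if (is.null(nm) || is.na(nm)) nm <- t
    lines <- c("[Term]",
               paste0("id: ", t),
               paste0("name: ", nm),
               paste0("namespace: ", ns[[ontology$aspect[[t]]]]))
    e <- ontology$edges[ontology$edges$child == t, , drop = FALSE]
    for (i in seq_len(nrow(e))) {
      lines <- c(lines, if (e$relation[i] == "is_a")
        paste0("is_a: ", e$parent[i])
        else paste0("relationship: part_of ", e$parent[i]))
    }
    alts <- names(ontology$alt)[ontology$alt == t]
    lines <- c(lines, paste0("alt_id: ", alts))
    writeLines(c(lines, ""), con)
  }
  invisible(path)
}
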