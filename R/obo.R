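#' Parse an OBO-format ontology into an is_a DAG
#'
#' Reads OBO 1.2-style text and builds a directed acyclic graph over the
#' `[Term]` stanzas. Only the tags `id`, `name`, `namespace`, `is_a`, `xref`,
#' `is_obsolete` and `replaced_by` are honoured; every other tag and every
#' non-`[Term]` stanza is ignored silently. Obsolete terms are retained and
#' flagged, but their `is_a` parents are dropped so they never take part in
#' closure computations.
#'
#' @param x Path to an OBO file, or a character vector of OBO lines.
#' @return An object of class `ontology_graph`: a list with
#'   \describe{
#'     \item{terms}{data.frame with columns `id`, `name`, `namespace`,
#'       `obsolete`, `replaced_by`.}
#'     \item{edges}{data.frame of is_a pairs with columns `child`, `parent`.}
#'     \item{xrefs}{named list, term id -> character vector of xref CURIEs.}
#'     \item{graph}{an igraph object with edges directed child -> parent.}
#'   }
#' @details A parent reference pointing outside the ontology raises a warning
#'   and the edge is dropped. A cyclic `is_a` relation is a hard error naming
#'   one member of the cycle.
#' @export
parse_obo <- function(x) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- trimws(lines)

  # stanza boundaries: lines like [Term], [Typedef], ...
  stanza_starts <- grep("^\\[.*\\]$", lines)
  term_stanzas <- list()
  if (length(stanza_starts)) {
    bounds <- c(stanza_starts, length(lines) + 1L)
    for (i in seq_along(stanza_starts)) {
      if (lines[stanza_starts[i]] != "[Term]") next
      body <- lines[seq(stanza_starts[i] + 1L, bounds[i + 1L] - 1L)]
      term_stanzas[[length(term_stanzas) + 1L]] <- body[nzchar(body)]
    }
  }

  tag_values <- function(body, tag) {
    pat <- paste0("^", tag, ":\\s*")
    vals <- sub(pat, "", body[grepl(pat, body)])
    sub("\\s*!.*$", "", vals)  # strip trailing OBO comments
  }

  ids <- character(0); names_ <- character(0); nss <- character(0)
  obsolete <- logical(0); replaced <- character(0)
  parents <- list(); xrefs <- list()
  for (body in term_stanzas) {
    id <- tag_values(body, "id")[1]
    if (is.na(id) || !nzchar(id)) next
    if (id %in% ids) stop("duplicate term id in OBO input: ", id)
    ids <- c(ids, id)
    nm <- tag_values(body, "name")[1]
    names_ <- c(names_, if (is.na(nm)) "" else nm)
    ns <- tag_values(body, "namespace")[1]
    nss <- c(nss, if (is.na(ns)) "" else ns)
    obs <- identical(tolower(tag_values(body, "is_obsolete")[1]), "true")
    obsolete <- c(obsolete, isTRUE(obs))
    rb <- tag_values(body, "replaced_by")[1]
    replaced <- c(replaced, if (is.na(rb)) NA_character_ else rb)
    parents[[id]] <- if (isTRUE(obs)) character(0) else tag_values(body, "is_a")
    # xref values may carry a description after the CURIE; keep first token
    xr <- tag_values(body, "xref")
    xrefs[[id]] <- sub("\\s.*$", "", xr)
  }

  terms <- data.frame(
    id = ids, name = names_, namespace = nss,
    obsolete = obsolete, replaced_by = replaced,
    stringsAsFactors = FALSE
  )

  child <- rep(ids, lengths(parents[ids]))
  parent <- unlist(parents[ids], use.names = FALSE)
  if (is.null(parent)) parent <- character(0)
  dangling <- !(parent %in% ids)
  if (any(dangling)) {
    warning("dropping ", sum(dangling), " is_a edge(s) with dangling parent: ",
            paste(unique(parent[dangling]), collapse = ", "))
    child <- child[!dangling]; parent <- parent[!dangling]
  }
  edges <- data.frame(child = child, parent = parent, stringsAsFactors = FALSE)

  g <- igraph::graph_from_data_frame(
    edges, directed = TRUE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE)
  )
  if (!igraph::is_dag(g)) {
    on_cycle <- vapply(ids, function(v) {
      nb <- igraph::neighbors(g, v, mode = "out")$name
      length(nb) > 0L &&
        any(vapply(nb, function(n)
          v %in% igraph::subcomponent(g, n, mode = "out")$name, logical(1)))
    }, logical(1))
    stop("cyclic is_a relation detected involving term ", ids[on_cycle][1])
  }

  structure(
    list(terms = terms, edges = edges, xrefs = xrefs, graph = g),
    class = "ontology_graph"
  )
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat("<ontology_graph> ", nrow(x$terms), " terms, ",
      nrow(x$edges), " is_a edges, ",
      sum(x$terms$obsolete), " obsolete\n", sep = "")
  invisible(x)
}

#' Serialize an ontology graph back to OBO text
#'
#' Emits one `[Term]` stanza per term with the tags the parser honours, so
#' that `parse_obo(write_obo(g))` reproduces the term and edge set exactly.
#'
#' @param graph An `ontology_graph`.
#' @param path Optional file path; when `NULL` the OBO lines are returned.
#' @return Invisibly, the character vector of OBO lines.
#' @export
write_obo <- function(graph, path = NULL) {
  stopifnot(inherits(graph, "ontology_graph"))
  out <- c("format-version: 1.2", "")
  by_child <- split(graph$edges$parent, graph$edges$child)
  for (i in seq_len(nrow(graph$terms))) {
    t <- graph$terms[i, ]
    stanza <- c("[Term]", paste0("id: ", t$id))
    if (nzchar(t$name)) stanza <- c(stanza, paste0("name: ", t$name))
    if (nzchar(t$namespace)) stanza <- c(stanza, paste0("namespace: ", t$namespace))
    for (p in by_child[[t$id]]) stanza <- c(stanza, paste0("is_a: ", p))
    for (xr in graph$xrefs[[t$id]]) stanza <- c(stanza, paste0("xref: ", xr))
    if (t$obsolete) stanza <- c(stanza, "is_obsolete: true")
    if (!is.na(t$replaced_by)) stanza <- c(stanza, paste0("replaced_by: ", t$replaced_by))
    out <- c(out, stanza, "")
  }
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

#' Dump an ontology graph as a debug TSV
#'
#' One row per term: `term_id`, `name`, `parent_ids` (pipe-joined).
#'
#' @param graph An `ontology_graph`.
#' @param path Output file path.
#' @export
write_ontology_tsv <- function(graph, path) {
  stopifnot(inherits(graph, "ontology_graph"))
  by_child <- split(graph$edges$parent, graph$edges$child)
  df <- data.frame(
    term_id = graph$terms$id, name = graph$terms$name,
    parent_ids = vapply(graph$terms$id, function(id)
      paste(by_child[[id]], collapse = "|"), character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Descendants of a term under transitive is_a
#'
#' All terms from which `root` is reachable by following is_a edges, excluding
#' `root` itself. Callers that need self-inclusion (e.g. the enzyme filter on
#' catalytic activity) union the root back in.
#'
#' @param graph An `ontology_graph`.
#' @param root A term id present in the graph.
#' @return Character vector of descendant term ids (possibly empty).
#' @export
descendants <- function(graph, root) {
  stopifnot(inherits(graph, "ontology_graph"))
  if (!root %in% graph$terms$id) stop("unknown term: ", root)
  reach <- igraph::subcomponent(graph$graph, root, mode = "in")$name
  setdiff(reach, root)
}

#' Build a disease identifier map from a disease ontology
#'
#' Indexes every non-obsolete term of a MONDO-like ontology by its canonical
#' id, its OMIM/Orphanet cross-references and its (case-folded) name, so raw
#' disease keys from heterogeneous sources can be resolved onto one canonical
#' namespace. Obsolete terms carrying `replaced_by` forward to their
#' replacement; obsolete terms without one resolve to nothing.
#'
#' @param ontology An `ontology_graph` for the disease ontology.
#' @return An object of class `disease_id_map` with the per-disease table
#'   (`canonical_id`, `name`, `omim_ids`, `orphanet_ids`, `rare`) and the
#'   lookup indexes used by [resolve_disease_id()].
#' @export
build_disease_map <- function(ontology) {
  stopifnot(inherits(ontology, "ontology_graph"))
  live <- ontology$terms[!ontology$terms$obsolete, , drop = FALSE]
  omim <- lapply(ontology$xrefs[live$id], function(x) x[startsWith(x, "OMIM:")])
  orph <- lapply(ontology$xrefs[live$id], function(x) x[startsWith(x, "Orphanet:")])
  entries <- data.frame(
    canonical_id = live$id, name = live$name,
    rare = lengths(orph) > 0, stringsAsFactors = FALSE
  )
  entries$omim_ids <- unname(omim)
  entries$orphanet_ids <- unname(orph)

  xref_keys <- c(unlist(omim, use.names = FALSE), unlist(orph, use.names = FALSE))
  xref_vals <- c(rep(live$id, lengths(omim)), rep(live$id, lengths(orph)))
  by_xref <- split(xref_vals, xref_keys)
  by_name <- split(live$id, tolower(live$name))

  fwd <- ontology$terms[ontology$terms$obsolete & !is.na(ontology$terms$replaced_by), ]
  forward <- stats::setNames(fwd$replaced_by, fwd$id)

  structure(
    list(entries = entries, by_xref = by_xref, by_name = by_name,
         forward = forward),
    class = "disease_id_map"
  )
}

#' Resolve a raw disease identifier onto the canonical namespace
#'
#' Resolution order: already-canonical id (including obsolete ids forwarded
#' through `replaced_by`), then exact cross-reference match (OMIM/Orphanet),
#' then exact case-insensitive name match. Anything else returns `NA`, the
#' unresolved marker; such records are kept in rejects reports but excluded
#' from canonical statistics.
#'
#' @param raw_id A CURIE (e.g. `"OMIM:166710"`) or a disease name.
#' @param map A `disease_id_map` from [build_disease_map()].
#' @return The canonical CURIE, or `NA_character_` if unresolved.
#' @details A raw id whose cross-reference maps to two canonical diseases is
#'   an ambiguity error listing both candidates.
#' @export
resolve_disease_id <- function(raw_id, map) {
  stopifnot(inherits(map, "disease_id_map"))
  if (is.na(raw_id) || !nzchar(raw_id)) return(NA_character_)
  if (raw_id %in% names(map$forward)) raw_id <- unname(map$forward[[raw_id]])
  if (raw_id %in% map$entries$canonical_id) return(raw_id)
  hit <- map$by_xref[[raw_id]]
  if (!is.null(hit)) {
    hit <- unique(hit)
    if (length(hit) > 1L) {
      stop("ambiguous disease id ", raw_id, ": matches ",
           paste(hit, collapse = " and "))
    }
    return(hit)
  }
  hit <- map$by_name[[tolower(raw_id)]]
  if (!is.null(hit)) {
    hit <- unique(hit)
    if (length(hit) > 1L) {
      stop("ambiguous disease name ", raw_id, ": matches ",
           paste(hit, collapse = " and "))
    }
    return(hit)
  }
  NA_character_
}
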