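#' Load a Reactome-style pathway hierarchy
#'
#' Builds a multi-rooted pathway DAG from the two Reactome flat files: the
#' pathway list (`id TAB name TAB species`, no header) and the parent-child
#' relation file (`parent_id TAB child_id`, no header). Only rows of the
#' requested species enter the forest. Roots whose names match
#' `excluded_root_names` are recorded as excluded: they stay in the structure
#' but are dropped from root-level statistics ([roots_of()],
#' [expand_to_roots()]).
#'
#' @param pathway_table Path to the pathway list TSV.
#' @param relation_table Path to the relation TSV.
#' @param excluded_root_names Character vector of root names to exclude from
#'   root-level statistics; defaults to `c("Disease", "Drug ADME")`.
#' @param species Species label to keep (default `"Homo sapiens"`).
#' @return An object of class `pathway_forest`: list with `events` (data.frame
#'   `id`, `name`, `kind`), `parents`/`children` (named lists), `roots`,
#'   `excluded_roots`, `node_roots` (per-event reachable root ids) and the
#'   child -> parent igraph.
#' @details A relation mentioning an id absent from the pathway list (or of
#'   another species) raises a warning and is skipped; a cycle is a hard error.
#' @export
load_forest <- function(pathway_table, relation_table,
                        excluded_root_names = c("Disease", "Drug ADME"),
                        species = "Homo sapiens") {
  pw <- utils::read.delim(pathway_table, header = FALSE, sep = "\t",
                          quote = "", stringsAsFactors = FALSE,
                          col.names = c("id", "name", "species"))
  pw <- pw[pw$species == species, , drop = FALSE]
  if (anyDuplicated(pw$id)) stop("duplicate pathway ids in pathway table")
  rel <- utils::read.delim(relation_table, header = FALSE, sep = "\t",
                           quote = "", stringsAsFactors = FALSE,
                           col.names = c("parent", "child"))
  known <- rel$parent %in% pw$id & rel$child %in% pw$id
  if (any(!known)) {
    warning("skipping ", sum(!known),
            " relation(s) referencing pathways outside the ",
            species, " pathway list")
    rel <- rel[known, , drop = FALSE]
  }
  rel <- unique(rel)

  g <- igraph::graph_from_data_frame(
    data.frame(from = rel$child, to = rel$parent, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = pw$id, stringsAsFactors = FALSE)
  )
  if (!igraph::is_dag(g)) stop("cycle detected in pathway hierarchy")

  parents <- split(rel$parent, factor(rel$child, levels = pw$id))
  children <- split(rel$child, factor(rel$parent, levels = pw$id))
  has_parent <- lengths(parents) > 0
  has_child <- lengths(children) > 0
  kind <- ifelse(!has_parent, "root",
                 ifelse(!has_child, "leaf", "internal"))
  # an isolated node has neither parents nor children and classifies as root

  events <- data.frame(id = pw$id, name = pw$name, kind = kind,
                       stringsAsFactors = FALSE)
  roots <- events$id[events$kind == "root"]
  excluded <- roots[pw$name[match(roots, pw$id)] %in% excluded_root_names]

  # per-event reachable roots (self-inclusive ancestor closure meets roots)
  node_roots <- lapply(pw$id, function(id) {
    anc <- igraph::subcomponent(g, id, mode = "out")$name
    intersect(anc, roots)
  })
  names(node_roots) <- pw$id

  structure(
    list(events = events, parents = parents, children = children,
         roots = roots, excluded_roots = excluded,
         node_roots = node_roots, graph = g),
    class = "pathway_forest"
  )
}

#' @export
print.pathway_forest <- function(x, ...) {
  k <- table(factor(x$events$kind, levels = c("root", "internal", "leaf")))
  cat("<pathway_forest> ", nrow(x$events), " events: ",
      k[["root"]], " roots (", length(x$excluded_roots), " excluded), ",
      k[["internal"]], " internal, ", k[["leaf"]], " leaves\n", sep = "")
  invisible(x)
}

#' Node kind of a pathway event
#'
#' `root` (no parents, including fully isolated nodes), `leaf` (parents but no
#' children) or `internal` (both). The three kinds partition the event set.
#'
#' @param forest A `pathway_forest`.
#' @param id A pathway id present in the forest.
#' @return One of `"root"`, `"internal"`, `"leaf"`.
#' @export
node_kind <- function(forest, id) {
  stopifnot(inherits(forest, "pathway_forest"))
  i <- match(id, forest$events$id)
  if (is.na(i)) stop("unknown pathway id: ", id)
  forest$events$kind[i]
}

#' Expand a pathway set upward to the hierarchy roots
#'
#' Returns the annotated set together with every ancestor of each member
#' (union over multiple parents, no duplicates). Excluded roots, and events
#' all of whose reachable roots are excluded, are removed from the result.
#'
#' @param forest A `pathway_forest`.
#' @param annotated Character vector of pathway ids, a subset of the forest.
#' @return Character vector (sorted) of the leaf-to-root expansion.
#' @export
expand_to_roots <- function(forest, annotated) {
  stopifnot(inherits(forest, "pathway_forest"))
  annotated <- unique(annotated)
  bad <- setdiff(annotated, forest$events$id)
  if (length(bad)) stop("annotated pathways not in forest: ",
                        paste(bad, collapse = ", "))
  if (!length(annotated)) return(character(0))
  closure <- unique(unlist(lapply(annotated, function(id)
    igraph::subcomponent(forest$graph, id, mode = "out")$name
  ), use.names = FALSE))
  keep <- vapply(closure, function(id) {
    r <- forest$node_roots[[id]]
    length(setdiff(r, forest$excluded_roots)) > 0
  }, logical(1))
  sort(closure[keep])
}

#' Non-excluded hierarchy roots reached by a pathway set
#'
#' The leaf-to-root expansion of `annotated` intersected with the non-excluded
#' roots. An annotation reachable only under an excluded root yields nothing.
#'
#' @inheritParams expand_to_roots
#' @return Character vector (sorted) of root ids.
#' @export
roots_of <- function(forest, annotated) {
  intersect(expand_to_roots(forest, annotated),
            setdiff(forest$roots, forest$excluded_roots))
}

#' Load protein-to-pathway annotations (UniProt2Reactome dialect)
#'
#' Six tab-separated columns without header: accession, pathway id, URL,
#' pathway name, evidence code, species. Only columns 1, 2 and 6 are consumed.
#' Rows of other species or referencing pathways absent from the forest are
#' dropped.
#'
#' @param path Path to the annotation TSV.
#' @param forest A `pathway_forest` used to restrict to known pathways.
#' @param species Species label to keep.
#' @return Named list: accession -> character vector of distinct pathway ids.
#' @export
load_protein_pathways <- function(path, forest, species = "Homo sapiens") {
  stopifnot(inherits(forest, "pathway_forest"))
  tab <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 6) stop("protein-to-pathway file needs 6 columns")
  tab <- tab[tab[[6]] == species & tab[[2]] %in% forest$events$id,
             c(1, 2), drop = FALSE]
  names(tab) <- c("accession", "pathway_id")
  tab <- unique(tab)
  lapply(split(tab$pathway_id, tab$accession), sort)
}

#' Load protein-to-reaction annotations
#'
#' Same flat-file dialect as [load_protein_pathways()] but carrying reaction
#' identifiers, which the pipeline treats as opaque ids and only counts.
#'
#' @param path Path to the annotation TSV.
#' @param species Species label to keep.
#' @return Named list: accession -> character vector of distinct reaction ids.
#' @export
load_protein_reactions <- function(path, species = "Homo sapiens") {
  tab <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 6) stop("protein-to-reaction file needs 6 columns")
  tab <- unique(tab[tab[[6]] == species, c(1, 2), drop = FALSE])
  names(tab) <- c("accession", "reaction_id")
  lapply(split(tab$reaction_id, tab$accession), sort)
}
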