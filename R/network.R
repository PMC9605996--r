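#' Map diseases onto non-excluded pathway roots
#'
#' Each disease's root set is the union of [roots_of()] over the annotated
#' pathways of all its enzymes. Diseases reaching no non-excluded root are
#' omitted (with a message giving their number).
#'
#' @param union Union-set data.frame restricted to enzymes (`accession`,
#'   `disease_id`).
#' @param annotations Named list accession -> annotated pathway ids.
#' @param forest A `pathway_forest`.
#' @return Named list: disease id -> sorted character vector of root ids.
#' @export
map_diseases_to_roots <- function(union, annotations, forest) {
  by_dis <- split(union$accession, union$disease_id)
  res <- lapply(by_dis, function(enzymes) {
    pw <- unique(unlist(annotations[enzymes], use.names = FALSE))
    if (!length(pw)) return(character(0))
    roots_of(forest, pw)
  })
  empty <- lengths(res) == 0
  if (any(empty)) {
    message(sum(empty), " disease(s) reach no non-excluded root; omitted")
  }
  res[!empty][order(names(res[!empty]))]
}

#' Map enzymes onto non-excluded pathway roots
#'
#' @param annotations Named list accession -> annotated pathway ids.
#' @param forest A `pathway_forest`.
#' @return Named list: accession -> sorted root ids (enzymes reaching no
#'   non-excluded root omitted).
#' @export
map_enzymes_to_roots <- function(annotations, forest) {
  res <- lapply(annotations, function(pw) roots_of(forest, pw))
  res <- res[lengths(res) > 0]
  res[order(names(res))]
}

#' Build the root co-occurrence network
#'
#' Nodes are pathway roots weighted by the number of diseases mapping to them
#' (multi-root diseases count on every root they reach). A disease whose root
#' set has n >= 2 members contributes one count to each of its n(n-1)/2
#' unordered root pairs; edges of weight zero are absent. Ordering is
#' deterministic (lexicographic root ids).
#'
#' @param root_map Named list disease -> root ids, from
#'   [map_diseases_to_roots()].
#' @return An object of class `root_network`: list with `nodes` (data.frame
#'   `root`, `disease_count`) and `edges` (data.frame `root_a`, `root_b`,
#'   `shared_diseases`, with `root_a < root_b`).
#' @export
build_root_network <- function(root_map) {
  roots <- sort(unique(unlist(root_map, use.names = FALSE)))
  node_counts <- vapply(roots, function(r)
    sum(vapply(root_map, function(s) r %in% s, logical(1))), integer(1))
  nodes <- data.frame(root = roots, disease_count = unname(node_counts),
                      stringsAsFactors = FALSE)

  pair_keys <- unlist(lapply(root_map, function(s) {
    if (length(s) < 2L) return(character(0))
    s <- sort(s)
    cmb <- utils::combn(s, 2L)
    paste(cmb[1, ], cmb[2, ], sep = "\r")
  }), use.names = FALSE)
  if (length(pair_keys)) {
    tab <- table(pair_keys)
    parts <- do.call(rbind, strsplit(names(tab), "\r", fixed = TRUE))
    edges <- data.frame(root_a = parts[, 1], root_b = parts[, 2],
                        shared_diseases = as.integer(tab),
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$root_a, edges$root_b), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(root_a = character(0), root_b = character(0),
                        shared_diseases = integer(0), stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges), class = "root_network")
}

#' @export
print.root_network <- function(x, ...) {
  n <- nrow(x$nodes)
  cat("<root_network> ", n, " roots, ", nrow(x$edges),
      " realized edges (bound ", n * (n - 1L) / 2, ")\n", sep = "")
  invisible(x)
}

#' Distribution histogram over pipeline entities
#'
#' Ordered bucket -> count table for one of the three standard distributions:
#' diseases by number of associated enzymes, enzymes by number of reached
#' roots, diseases by number of reached roots. Counts sum to the number of
#' counted entities.
#'
#' @param key One of `"enzymes-per-disease"`, `"roots-per-enzyme"`,
#'   `"roots-per-disease"`.
#' @param union Union-set data.frame (needed for `"enzymes-per-disease"`).
#' @param enzyme_roots Named list accession -> roots (for
#'   `"roots-per-enzyme"`).
#' @param disease_roots Named list disease -> roots (for
#'   `"roots-per-disease"`).
#' @return data.frame `bucket`, `count`, ordered by bucket.
#' @export
pipeline_histogram <- function(key, union = NULL, enzyme_roots = NULL,
                               disease_roots = NULL) {
  values <- switch(
    key,
    "enzymes-per-disease" = {
      stopifnot(!is.null(union))
      as.integer(table(union$disease_id))
    },
    "roots-per-enzyme" = {
      stopifnot(!is.null(enzyme_roots))
      lengths(enzyme_roots)
    },
    "roots-per-disease" = {
      stopifnot(!is.null(disease_roots))
      lengths(disease_roots)
    },
    stop("unknown histogram key: ", key)
  )
  if (!length(values)) {
    return(data.frame(bucket = integer(0), count = integer(0)))
  }
  tab <- table(values)
  data.frame(bucket = as.integer(names(tab)), count = as.integer(tab))
}

#' Percentage helper used by the reporting tables
#'
#' `100 * numerator / denominator` rounded to one decimal, the convention of
#' the per-root univocality column.
#'
#' @param numerator,denominator Non-negative numbers, `denominator > 0`.
#' @return Numeric scalar.
#' @export
percentage <- function(numerator, denominator) {
  stopifnot(denominator > 0)
  round(100 * numerator / denominator, 1)
}

#' Per-root disease distribution table
#'
#' For every root: all diseases mapping to it, diseases mapping univocally
#' (single-root diseases), and the univocal percentage. Rows with zero
#' diseases are omitted; ordering is by `all_diseases` descending with
#' lexicographic root ties.
#'
#' @param root_map Named list disease -> root ids.
#' @return data.frame `root`, `all_diseases`, `single_root_diseases`,
#'   `pct_univocal`.
#' @export
per_root_table <- function(root_map) {
  roots <- sort(unique(unlist(root_map, use.names = FALSE)))
  single <- root_map[lengths(root_map) == 1L]
  all_counts <- vapply(roots, function(r)
    sum(vapply(root_map, function(s) r %in% s, logical(1))), integer(1))
  single_counts <- vapply(roots, function(r)
    sum(vapply(single, function(s) identical(s, r), logical(1))), integer(1))
  keep <- all_counts > 0
  out <- data.frame(
    root = roots[keep],
    all_diseases = unname(all_counts[keep]),
    single_root_diseases = unname(single_counts[keep]),
    stringsAsFactors = FALSE
  )
  out$pct_univocal <- vapply(seq_len(nrow(out)), function(i)
    percentage(out$single_root_diseases[i], out$all_diseases[i]), numeric(1))
  out <- out[order(-out$all_diseases, out$root), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a root network to GraphML
#'
#' Node attributes `name` (human-readable root name when a forest is given)
#' and `disease_count`; edge attribute `shared_diseases`. Vertex and edge
#' order are deterministic, so repeated exports are byte-identical.
#'
#' @param network A `root_network`.
#' @param path Output file path.
#' @param forest Optional `pathway_forest` supplying root names.
#' @export
write_network_graphml <- function(network, path, forest = NULL) {
  stopifnot(inherits(network, "root_network"))
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = network$edges$root_a, to = network$edges$root_b,
                   shared_diseases = network$edges$shared_diseases,
                   stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = network$nodes$root, stringsAsFactors = FALSE)
  )
  label <- network$nodes$root
  if (!is.null(forest)) {
    i <- match(network$nodes$root, forest$events$id)
    label <- ifelse(is.na(i), network$nodes$root, forest$events$name[i])
  }
  igraph::V(g)$label <- label
  igraph::V(g)$disease_count <- network$nodes$disease_count
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export a root network as SIF plus attribute tables
#'
#' Writes `<stem>.sif` (`root_a shares root_b` lines), `<stem>_nodes.tsv` and
#' `<stem>_edges.tsv` for downstream network tools.
#'
#' @param network A `root_network`.
#' @param stem Output path stem (without extension).
#' @export
write_network_tables <- function(network, stem) {
  stopifnot(inherits(network, "root_network"))
  writeLines(
    if (nrow(network$edges)) {
      paste(network$edges$root_a, "shares", network$edges$root_b)
    } else character(0),
    paste0(stem, ".sif")
  )
  utils::write.table(network$nodes, paste0(stem, "_nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(network$edges, paste0(stem, "_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(stem)
}
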