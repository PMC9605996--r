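# Independent brute-force oracles and fixture builders shared by the suite.

# Boolean transitive reachability by repeated matrix multiplication: R[i, j]
# is TRUE iff j is reachable from i following the directed edges. Entirely
# independent of the igraph-based traversal in the package.
reachability_matrix <- function(nodes, from, to) {
  n <- length(nodes)
  A <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  if (length(from)) A[cbind(match(from, nodes), match(to, nodes))] <- TRUE
  R <- A
  repeat {
    R2 <- R | (R %*% A > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  R
}

# descendants oracle: terms from which `root` is reachable via child->parent
# edges, excluding root itself
oracle_descendants <- function(nodes, child, parent, root) {
  R <- reachability_matrix(nodes, child, parent)
  setdiff(nodes[R[, root]], root)
}

# ancestor-closure oracle: annotated set plus everything reachable upward
oracle_expand <- function(nodes, child, parent, annotated) {
  R <- reachability_matrix(nodes, child, parent)
  up <- nodes[colSums(R[annotated, nodes, drop = FALSE]) > 0]
  sort(union(annotated, up))
}

# random DAG on n nodes: edges only from higher to lower index, so acyclic
# by construction
random_dag <- function(n, p = 0.15) {
  nodes <- sprintf("T%03d", seq_len(n))
  from <- character(0); to <- character(0)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (stats::runif(1) < p) {
        from <- c(from, nodes[i]); to <- c(to, nodes[j])
      }
    }
  }
  list(nodes = nodes, child = from, parent = to)
}

# serialize a child->parent DAG as OBO text
dag_as_obo <- function(dag) {
  by_child <- split(dag$parent, dag$child)
  stanzas <- unlist(lapply(dag$nodes, function(id) {
    p <- by_child[[id]]
    c("[Term]", paste0("id: ", id),
      paste0("name: name of ", id),
      if (length(p)) paste0("is_a: ", p) else character(0), "")
  }))
  c("format-version: 1.2", "", stanzas)
}

# write a child->parent DAG as pathway list + relation TSVs, return a forest
dag_as_forest <- function(dag, dir = tempfile("forest"),
                          excluded_root_names = character(0)) {
  dir.create(dir, showWarnings = FALSE)
  pw <- file.path(dir, "pathways.tsv")
  rel <- file.path(dir, "relations.tsv")
  writeLines(paste(dag$nodes, paste("name of", dag$nodes), "Homo sapiens",
                   sep = "\t"), pw)
  writeLines(if (length(dag$child)) {
    paste(dag$parent, dag$child, sep = "\t")
  } else character(0), rel)
  load_forest(pw, rel, excluded_root_names = excluded_root_names)
}

# minimal OBO builder for targeted fixtures
make_obo <- function(ids, parents = list(), names = NULL, xrefs = list(),
                     obsolete = character(0), replaced_by = list(),
                     namespace = NULL) {
  if (is.null(names)) names <- paste("name of", ids)
  tagged <- function(tag, vals) {
    if (length(vals)) paste0(tag, ": ", vals) else character(0)
  }
  stanzas <- unlist(lapply(seq_along(ids), function(i) {
    id <- ids[i]
    c("[Term]", paste0("id: ", id), paste0("name: ", names[i]),
      if (!is.null(namespace)) paste0("namespace: ", namespace),
      tagged("is_a", parents[[id]]),
      tagged("xref", xrefs[[id]]),
      if (id %in% obsolete) "is_obsolete: true",
      tagged("replaced_by", replaced_by[[id]]),
      "")
  }))
  c("format-version: 1.2", "", stanzas)
}

# tiny source TSV writer
write_source_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
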