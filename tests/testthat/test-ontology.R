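test_that("parse_obo handles empty documents and simple stanzas", {
  g <- parse_obo(c("format-version: 1.2", ""))
  expect_s3_class(g, "ontology_graph")
  expect_equal(nrow(g$terms), 0)

  g <- parse_obo(c("[Term]", "id: GO:0003824", "name: catalytic activity"))
  expect_equal(g$terms$id, "GO:0003824")
  expect_equal(g$terms$name, "catalytic activity")
})

test_that("parse_obo builds a 5-term chain with 4 acyclic edges", {
  ids <- LETTERS[1:5]
  parents <- stats::setNames(as.list(c(NA, LETTERS[1:4])), ids)
  parents$A <- character(0)
  g <- parse_obo(make_obo(ids, parents))
  expect_equal(nrow(g$terms), 5)
  expect_equal(nrow(g$edges), 4)
  expect_true(igraph::is_dag(g$graph))
  expect_setequal(descendants(g, "A"), c("B", "C", "D", "E"))
})

test_that("parse_obo rejects cycles and drops dangling parents with warning", {
  cyc <- make_obo(c("A", "B"), list(A = "B", B = "A"))
  expect_error(parse_obo(cyc), "cyclic is_a")

  dang <- make_obo(c("A", "B"), list(A = character(0), B = c("A", "GHOST")))
  expect_warning(g <- parse_obo(dang), "dangling")
  expect_equal(nrow(g$edges), 1)
})

test_that("obsolete terms are flagged and contribute no closure edges", {
  obo <- make_obo(c("A", "B", "C"),
                  list(A = character(0), B = "A", C = "A"),
                  obsolete = "C", replaced_by = list(C = "B"))
  g <- parse_obo(obo)
  expect_true(g$terms$obsolete[g$terms$id == "C"])
  expect_setequal(descendants(g, "A"), "B")
})

test_that("descendants excludes the root, handles leaves and diamonds", {
  dag <- list(nodes = c("A", "B", "C", "D"),
              child = c("B", "C", "D", "D"), parent = c("A", "A", "B", "C"))
  g <- parse_obo(dag_as_obo(dag))
  expect_setequal(descendants(g, "A"), c("B", "C", "D"))
  expect_length(descendants(g, "D"), 0)
  expect_false("A" %in% descendants(g, "A"))
  expect_error(descendants(g, "NOPE"), "unknown")
})

test_that("descendancy matches the brute-force reachability oracle", {
  set.seed(101)
  for (rep in 1:25) {
    dag <- random_dag(sample(5:50, 1), p = stats::runif(1, 0.03, 0.3))
    g <- parse_obo(dag_as_obo(dag))
    for (root in sample(dag$nodes, min(5, length(dag$nodes)))) {
      expect_setequal(descendants(g, root),
                      oracle_descendants(dag$nodes, dag$child, dag$parent,
                                         root))
      expect_false(root %in% descendants(g, root))
    }
  }
})

test_that("OBO round-trip through write_obo preserves terms and edges", {
  set.seed(7)
  dag <- random_dag(20, 0.2)
  xr <- stats::setNames(lapply(seq_along(dag$nodes), function(i)
    if (i %% 3 == 0) sprintf("OMIM:%06d", i) else character(0)), dag$nodes)
  g1 <- parse_obo(make_obo(dag$nodes, split(dag$parent, dag$child),
                           xrefs = xr, obsolete = dag$nodes[1]))
  g2 <- parse_obo(write_obo(g1))
  expect_equal(g1$terms, g2$terms)
  o <- function(e) e[order(e$child, e$parent), ]
  expect_equal(o(g1$edges), o(g2$edges), ignore_attr = TRUE)
  expect_equal(g1$xrefs[order(names(g1$xrefs))],
               g2$xrefs[order(names(g2$xrefs))])
})

test_that("disease resolution: xref wins, name is case-insensitive fallback", {
  obo <- make_obo(
    c("MONDO:0000001", "MONDO:0000002", "MONDO:0000003"),
    names = c("Osteoporosis", "thrombocytopenia 6", "old entry"),
    xrefs = list("MONDO:0000001" = c("OMIM:166710", "Orphanet:85193"),
                 "MONDO:0000002" = "OMIM:616937"),
    obsolete = "MONDO:0000003",
    replaced_by = list("MONDO:0000003" = "MONDO:0000002"),
    namespace = "disease"
  )
  map <- build_disease_map(parse_obo(obo))
  expect_equal(resolve_disease_id("OMIM:166710", map), "MONDO:0000001")
  expect_equal(resolve_disease_id("MONDO:0000001", map), "MONDO:0000001")
  expect_equal(resolve_disease_id("osteoporosis", map), "MONDO:0000001")
  # obsolete id forwards through replaced_by
  expect_equal(resolve_disease_id("MONDO:0000003", map), "MONDO:0000002")
  expect_true(is.na(resolve_disease_id("OMIM:999999", map)))
  # rare flag mirrors Orphanet xref presence
  expect_equal(map$entries$rare[map$entries$canonical_id == "MONDO:0000001"],
               TRUE)
  expect_equal(map$entries$rare[map$entries$canonical_id == "MONDO:0000002"],
               FALSE)
})

test_that("an xref shared by two diseases is an ambiguity error naming both", {
  obo <- make_obo(c("MONDO:0000010", "MONDO:0000011"),
                  xrefs = list("MONDO:0000010" = "OMIM:123456",
                               "MONDO:0000011" = "OMIM:123456"))
  map <- build_disease_map(parse_obo(obo))
  expect_error(resolve_disease_id("OMIM:123456", map),
               "MONDO:0000010.*MONDO:0000011")
})
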