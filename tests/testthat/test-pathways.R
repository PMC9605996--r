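test_that("a single pathway with no relations is a root; kinds partition", {
  f <- dag_as_forest(list(nodes = "P1", child = character(0),
                          parent = character(0)))
  expect_equal(node_kind(f, "P1"), "root")

  # 3 roots, 5 internal, 8 leaves, hand-built
  dag <- list(
    nodes = c(paste0("R", 1:3), paste0("I", 1:5), paste0("L", 1:8)),
    child = c("I1", "I2", "I3", "I4", "I5",
              "L1", "L2", "L3", "L4", "L5", "L6", "L7", "L8"),
    parent = c("R1", "R1", "R2", "R3", "I1",
               "I1", "I2", "I2", "I3", "I4", "I5", "I5", "R3")
  )
  f <- dag_as_forest(dag)
  kinds <- table(f$events$kind)
  expect_equal(kinds[["root"]], 3)
  expect_equal(kinds[["internal"]], 5)
  expect_equal(kinds[["leaf"]], 8)
  expect_equal(sum(kinds), nrow(f$events))
  # each node has exactly one kind
  for (id in dag$nodes) expect_true(node_kind(f, id) %in%
                                      c("root", "internal", "leaf"))
  expect_error(node_kind(f, "NOPE"), "unknown")
})

test_that("excluding two of 29 roots by name leaves 27 usable roots", {
  nodes <- sprintf("R%02d", 1:29)
  dir <- tempfile(); dir.create(dir)
  pw <- file.path(dir, "p.tsv"); rel <- file.path(dir, "r.tsv")
  nm <- c(paste("Root", 1:27), "Disease", "Drug ADME")
  writeLines(paste(nodes, nm, "Homo sapiens", sep = "\t"), pw)
  writeLines(character(0), rel)
  f <- load_forest(pw, rel)
  expect_length(f$roots, 29)
  expect_length(f$excluded_roots, 2)
  expect_length(setdiff(f$roots, f$excluded_roots), 27)
})

test_that("relations to unknown or other-species pathways are skipped", {
  dir <- tempfile(); dir.create(dir)
  pw <- file.path(dir, "p.tsv"); rel <- file.path(dir, "r.tsv")
  writeLines(c("A\troot a\tHomo sapiens", "B\tleaf b\tHomo sapiens",
               "M\tmouse node\tMus musculus"), pw)
  writeLines(c("A\tB", "A\tM", "GHOST\tB"), rel)
  expect_warning(f <- load_forest(pw, rel), "skipping 2")
  expect_equal(nrow(f$events), 2)
  expect_equal(node_kind(f, "B"), "leaf")
})

test_that("expansion reaches roots through chains and diamonds", {
  chain <- dag_as_forest(list(nodes = c("R", "I", "L"),
                              child = c("I", "L"), parent = c("R", "I")))
  expect_equal(expand_to_roots(chain, "L"), c("I", "L", "R"))
  expect_equal(expand_to_roots(chain, "R"), "R")
  expect_equal(roots_of(chain, "L"), "R")

  diamond <- dag_as_forest(list(nodes = c("R", "P1", "P2", "L"),
                                child = c("P1", "P2", "L", "L"),
                                parent = c("R", "R", "P1", "P2")))
  expect_equal(expand_to_roots(diamond, "L"), c("L", "P1", "P2", "R"))
  expect_equal(roots_of(diamond, "L"), "R")
})

test_that("events reachable only under excluded roots vanish from results", {
  dag <- list(nodes = c("RD", "LD", "ROK", "LOK", "LBOTH"),
              child = c("LD", "LOK", "LBOTH", "LBOTH"),
              parent = c("RD", "ROK", "RD", "ROK"))
  dir <- tempfile(); dir.create(dir)
  pw <- file.path(dir, "p.tsv"); rel <- file.path(dir, "r.tsv")
  writeLines(paste(dag$nodes,
                   c("Disease", "disease leaf", "Root ok", "ok leaf",
                     "shared leaf"),
                   "Homo sapiens", sep = "\t"), pw)
  writeLines(paste(dag$parent, dag$child, sep = "\t"), rel)
  f <- load_forest(pw, rel)
  expect_equal(f$excluded_roots, "RD")
  expect_length(roots_of(f, "LD"), 0)
  expect_length(expand_to_roots(f, "LD"), 0)
  # an event under both an excluded and a kept root keeps the kept root
  expect_equal(roots_of(f, "LBOTH"), "ROK")
  expect_setequal(expand_to_roots(f, "LBOTH"), c("LBOTH", "ROK"))
})

test_that("expansion equals the brute-force ancestor closure on random DAGs", {
  set.seed(202)
  for (rep in 1:20) {
    dag <- random_dag(sample(5:40, 1), p = stats::runif(1, 0.05, 0.25))
    f <- dag_as_forest(dag)
    ann <- sample(dag$nodes, sample.int(min(5, length(dag$nodes)), 1))
    got <- expand_to_roots(f, ann)
    expect_equal(got, oracle_expand(dag$nodes, dag$child, dag$parent, ann))
    # superset and idempotence
    expect_true(all(ann %in% got))
    expect_equal(expand_to_roots(f, got), got)
    # every event reaches at least one root
    for (id in sample(dag$nodes, 3)) {
      expect_gte(length(roots_of(f, id)), 1)
    }
  }
})

test_that("protein annotation files keep only known pathways of the species", {
  f <- dag_as_forest(list(nodes = c("R", "L"), child = "L", parent = "R"))
  path <- tempfile(fileext = ".tsv")
  writeLines(c("P1\tL\turl\tleaf\tTAS\tHomo sapiens",
               "P1\tL\turl\tleaf\tTAS\tHomo sapiens",
               "P2\tGHOST\turl\tx\tTAS\tHomo sapiens",
               "P3\tL\turl\tleaf\tTAS\tMus musculus"), path)
  ann <- load_protein_pathways(path, f)
  expect_equal(ann, list(P1 = "L"))
})
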