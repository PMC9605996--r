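small_spec <- function(seed = 1L, ...) {
  generator_spec(seed = seed, n_roots = 8L, branching = 2L,
                 counts = c(monogenic_A = 5L, monogenic_B = 6L,
                            polygenic_A = 2L, polygenic_B = 3L,
                            excluded = 2L), ...)
}

test_that("identical specs and seeds produce byte-identical bundles", {
  b1 <- generate_dataset(small_spec(seed = 11), tempfile("gena"))
  b2 <- generate_dataset(small_spec(seed = 11), tempfile("genb"))
  for (f in setdiff(names(b1$files), "manifest")) {
    expect_identical(readLines(b1$files[[f]]), readLines(b2$files[[f]]),
                     label = paste("file", f))
  }
  expect_identical(b1$manifest, b2$manifest)
  # a different seed changes the bundle
  b3 <- generate_dataset(small_spec(seed = 12), tempfile("genc"))
  expect_false(identical(b1$manifest, b3$manifest))
})

test_that("the manifest is internally consistent", {
  b <- generate_dataset(small_spec(seed = 3), tempfile("gen"))
  m <- b$manifest
  expect_equal(sum(unlist(m$category_counts)), m$n_diseases)
  expect_equal(sum(unlist(m$association_type_counts)), m$n_enzymes)
  expect_equal(sum(m$hist_enzymes_per_disease$count), m$n_diseases)
  # pair-count conservation holds inside the manifest itself
  buckets <- m$hist_roots_per_disease
  expect_equal(sum(choose(buckets$bucket, 2) * buckets$count),
               sum(m$network_edges$shared_diseases))
})

test_that("somatic rows are pure noise: the union never sees them", {
  b <- generate_dataset(small_spec(seed = 5, p_somatic = 1.0),
                        tempfile("gen"))
  s <- suppressWarnings(run_pipeline(bundle_config(b), quiet = TRUE))
  expect_equal(s$summary$n_union, b$manifest$n_union)
  expect_gte(b$manifest$n_somatic_rows, 1)
})

test_that("an infeasible spec errors before writing anything", {
  spec <- generator_spec(n_roots = 3L, depth = 1L, branching = 1L,
                         counts = c(monogenic_A = 1L, monogenic_B = 2L,
                                    polygenic_A = 0L, polygenic_B = 0L,
                                    excluded = 0L))
  dir <- tempfile("infeasible")
  expect_error(generate_dataset(spec, dir), "infeasible")
  expect_length(list.files(dir), 0)
})

test_that("the planted category counts are recovered exactly", {
  b <- generate_dataset(
    generator_spec(seed = 42, n_roots = 8L, branching = 2L,
                   counts = c(monogenic_A = 3L, monogenic_B = 2L,
                              polygenic_A = 1L, polygenic_B = 1L,
                              excluded = 1L)),
    tempfile("gen"))
  s <- suppressWarnings(run_pipeline(bundle_config(b), quiet = TRUE))
  expect_equal(unlist(s$summary$disease_categories),
               unlist(b$manifest$category_counts))
})

test_that("mini world motifs carry their expected labels", {
  b <- mini_paper_world(tempfile("mini"))
  s <- suppressWarnings(run_pipeline(bundle_config(b), quiet = TRUE))
  ty <- s$association_types
  # the pleiotropic kinase has two diseases -> non-univocal
  expect_equal(ty$association_type[ty$accession == "P-SRC"], "non_univocal")
  # the three proteasome-like subunits each reach 12 roots
  h <- s$hist_roots_per_enzyme
  expect_equal(h$count[h$bucket == 12], 3)
  # the shared-leaf diseases are polygenic type A
  glycine <- s$categories[grepl("MONDO:090000[678]", s$categories$disease_id), ]
  expect_equal(glycine$category, rep("polygenic_A", 3))
  # hand-verified manifest reproduced in full
  m <- b$manifest
  expect_equal(unlist(s$summary$disease_categories),
               unlist(m$category_counts))
  expect_equal(s$summary$n_enzymes, m$n_enzymes)
  expect_equal(as.integer(unlist(
    s$summary$association_types[c("biunivocal", "univocal", "non_univocal")])),
    unlist(m$association_type_counts, use.names = FALSE))
  expect_equal(s$network$nodes, m$network_nodes)
  expect_equal(s$network$edges, m$network_edges, ignore_attr = TRUE)
})
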