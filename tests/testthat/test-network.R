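test_that("single-root diseases give nodes and zero edges", {
  net <- build_root_network(list(d1 = "R1", d2 = "R2", d3 = "R1"))
  expect_equal(net$nodes$disease_count, c(2L, 1L))
  expect_equal(nrow(net$edges), 0)
})

test_that("a 3-root disease yields its three pairs, each of weight 1", {
  net <- build_root_network(list(d1 = c("b", "a", "c")))
  expect_equal(net$edges$root_a, c("a", "a", "b"))
  expect_equal(net$edges$root_b, c("b", "c", "c"))
  expect_equal(net$edges$shared_diseases, rep(1L, 3))
})

test_that("a disease on all 27 roots realizes the full 351-edge bound", {
  roots <- sprintf("R%02d", 1:27)
  net <- build_root_network(list(d = roots))
  expect_equal(nrow(net$edges), 27 * 26 / 2)
  expect_equal(nrow(net$edges), 351)
})

test_that("pair counts are conserved and edges bounded on random maps", {
  set.seed(404)
  roots <- sprintf("R%02d", 1:12)
  for (rep in 1:25) {
    n_dis <- sample(3:40, 1)
    map <- lapply(seq_len(n_dis), function(i)
      sample(roots, sample.int(6, 1)))
    names(map) <- paste0("d", seq_len(n_dis))
    net <- build_root_network(map)
    # conservation: sum over diseases of C(n, 2) equals total edge weight
    expect_equal(sum(choose(lengths(map), 2)),
                 sum(net$edges$shared_diseases))
    # every edge weight bounded by its endpoint node weights
    if (nrow(net$edges)) {
      wa <- net$nodes$disease_count[match(net$edges$root_a, net$nodes$root)]
      wb <- net$nodes$disease_count[match(net$edges$root_b, net$nodes$root)]
      expect_true(all(net$edges$shared_diseases <= pmin(wa, wb)))
    }
    r <- nrow(net$nodes)
    expect_lte(nrow(net$edges), r * (r - 1) / 2)
    # node weights count every disease containing the root
    expect_equal(sum(net$nodes$disease_count), sum(lengths(map)))
  }
})

test_that("histograms cover observed values and conserve totals", {
  u <- data.frame(accession = c("e1", "e2", "e3", "e3"),
                  disease_id = c("d1", "d1", "d2", "d3"))
  h <- pipeline_histogram("enzymes-per-disease", union = u)
  expect_equal(h$bucket, c(1L, 2L))
  expect_equal(h$count, c(2L, 1L))
  expect_equal(sum(h$count), length(unique(u$disease_id)))

  h1 <- pipeline_histogram("roots-per-disease",
                           disease_roots = list(d1 = "R1"))
  expect_equal(h1, data.frame(bucket = 1L, count = 1L))
  h0 <- pipeline_histogram("roots-per-enzyme", enzyme_roots = list())
  expect_equal(nrow(h0), 0)
  expect_error(pipeline_histogram("nope"), "unknown histogram key")
})

test_that("per-root table reports univocal fractions with guarded rounding", {
  # 560 single-root diseases on M, 429 multi-root ones -> 56.6% univocal
  map <- c(lapply(1:560, function(i) "M"),
           lapply(1:429, function(i) c("M", "X")))
  names(map) <- paste0("d", seq_along(map))
  tab <- per_root_table(map)
  m <- tab[tab$root == "M", ]
  expect_equal(m$all_diseases, 989)
  expect_equal(m$single_root_diseases, 560)
  expect_equal(m$pct_univocal, 56.6)
  # a root present only in multi-root diseases has pct 0
  x <- tab[tab$root == "X", ]
  expect_equal(x$single_root_diseases, 0)
  expect_equal(x$pct_univocal, 0)
  # rows sorted by all_diseases descending
  expect_equal(tab$root, c("M", "X"))
  # one root, one univocal disease -> 100%
  expect_equal(per_root_table(list(d = "R"))$pct_univocal, 100)
  # single-root diseases summed over roots = number of univocal diseases
  expect_equal(sum(tab$single_root_diseases),
               sum(lengths(map) == 1))
})

test_that("network exports are written and byte-stable", {
  net <- build_root_network(list(d1 = c("R1", "R2"), d2 = "R1"))
  g1 <- tempfile(fileext = ".graphml"); g2 <- tempfile(fileext = ".graphml")
  write_network_graphml(net, g1)
  write_network_graphml(net, g2)
  expect_identical(readLines(g1), readLines(g2))
  stem <- tempfile()
  write_network_tables(net, stem)
  expect_equal(readLines(paste0(stem, ".sif")), "R1 shares R2")
  nodes <- utils::read.delim(paste0(stem, "_nodes.tsv"))
  expect_equal(nodes$disease_count, c(2L, 1L))
})
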