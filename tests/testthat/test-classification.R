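pairs_df <- function(...) {
  v <- c(...)
  if (is.null(v)) v <- character(0)
  m <- matrix(v, ncol = 2, byrow = TRUE)
  data.frame(accession = as.character(m[, 1]),
             disease_id = as.character(m[, 2]), stringsAsFactors = FALSE)
}

test_that("association types follow the degree definitions", {
  # lone pair -> biunivocal
  t1 <- label_association_types(pairs_df("e1", "d1"))
  expect_equal(t1$association_type, "biunivocal")
  # two enzymes on one disease -> both univocal
  t2 <- label_association_types(pairs_df("e1", "d1", "e2", "d1"))
  expect_equal(t2$association_type, c("univocal", "univocal"))
  # an enzyme with two diseases is non-univocal regardless of disease degree
  t3 <- label_association_types(pairs_df("e1", "d1", "e1", "d2", "e2", "d2"))
  expect_equal(t3$association_type[t3$accession == "e1"], "non_univocal")
  # enzymes absent from the union are excluded with a warning
  expect_warning(label_association_types(pairs_df("e1", "d1"),
                                         enzymes = c("e1", "ghost")),
                 "no disease association")
})

test_that("association-type labels partition any random enzyme set", {
  set.seed(33)
  for (rep in 1:10) {
    n <- sample(5:30, 1)
    u <- unique(data.frame(
      accession = sample(paste0("e", 1:10), n, replace = TRUE),
      disease_id = sample(paste0("d", 1:10), n, replace = TRUE)))
    types <- label_association_types(u)
    expect_setequal(types$accession, unique(u$accession))
    expect_equal(sum(table(types$association_type)),
                 length(unique(u$accession)))
  }
})

test_that("disease categories follow the leaf-pathway footprint rule", {
  ann <- list(e1 = "L1", e2 = paste0("L", 1:55), e3 = "L9", e4 = "L9",
              e5 = c("L1", "L2"))
  expect_equal(categorize_disease("d", "e1", ann)$category, "monogenic_A")
  # one enzyme spread over 55 leaves: still one gene, many pathways
  expect_equal(categorize_disease("d", "e2", ann)$category, "monogenic_B")
  # two enzymes confined to one shared leaf
  expect_equal(categorize_disease("d", c("e3", "e4"), ann)$category,
               "polygenic_A")
  expect_equal(categorize_disease("d", c("e1", "e5"), ann)$category,
               "polygenic_B")
  # no annotated enzyme at all -> excluded
  expect_equal(categorize_disease("d", "ghost", ann)$category, "excluded")
  # partial annotation categorizes on the annotated enzymes only
  mixed <- categorize_disease("d", c("e1", "ghost"), ann)
  expect_equal(mixed$category, "polygenic_A")
  expect_equal(mixed$n_leaf_pathways, 1)
})

test_that("category report counts partition the disease set", {
  u <- pairs_df("e1", "d1", "e2", "d2", "e2", "d3", "e3", "d4", "e4", "d4",
                "e5", "d5")
  ann <- list(e1 = "L1", e2 = c("L1", "L2"), e3 = "L3", e4 = "L3")
  cats <- categorize_diseases(u, ann)
  rep <- category_report(cats)
  expect_equal(sum(rep$counts), rep$total)
  expect_equal(rep$total, 5)
  expect_equal(unname(rep$counts["monogenic_A"]), 1)   # d1
  expect_equal(unname(rep$counts["monogenic_B"]), 2)   # d2, d3
  expect_equal(unname(rep$counts["polygenic_A"]), 1)   # d4
  expect_equal(unname(rep$counts["excluded"]), 1)      # d5 (e5 unannotated)
  expect_equal(rep$n_monogenic + rep$n_polygenic, rep$total)
  # monogenic split is consistent with the enzyme counts
  expect_equal(rep$n_monogenic, sum(cats$n_enzymes == 1))
})

test_that("degenerate category reports", {
  # all enzymes unannotated -> everything excluded
  u <- pairs_df("e1", "d1", "e2", "d2")
  rep <- category_report(categorize_diseases(u, list()))
  expect_equal(unname(rep$counts["excluded"]), 2)
  # single biunivocal pair with one pathway -> (1, 0, 0, 0, 0)
  rep1 <- category_report(categorize_diseases(pairs_df("e1", "d1"),
                                              list(e1 = "L1")))
  expect_equal(unname(rep1$counts), c(1L, 0L, 0L, 0L, 0L))
  # empty union
  rep0 <- category_report(categorize_diseases(
    pairs_df()[0, , drop = FALSE], list()))
  expect_equal(rep0$total, 0)
})
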