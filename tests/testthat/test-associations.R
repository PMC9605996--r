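dummy_map <- function() {
  obo <- make_obo(
    c("MONDO:0000001", "MONDO:0000002", "MONDO:0000003"),
    names = c("disease one", "disease two", "disease three"),
    xrefs = list("MONDO:0000001" = "OMIM:100001",
                 "MONDO:0000002" = "OMIM:100002",
                 "MONDO:0000003" = "OMIM:100003")
  )
  build_disease_map(parse_obo(obo))
}

dummy_genes <- function() {
  data.frame(accession = c("P1", "P2"), symbol = c("AAA", "BBB"),
             stringsAsFactors = FALSE) |>
    (\(d) { d$synonyms <- list("AAA1", c("BBB1", "BBB2")); d })()
}

test_that("load_source maps columns, flags somatic, drops blank gene keys", {
  p <- write_source_tsv(data.frame(
    g = c("P1", "P2", "", "P1"), d = paste0("OMIM:10000", 1:4),
    o = c("germline", "somatic", "germline", "germline")))
  cols <- list(gene = "g", disease = "d", somatic = "o",
               somatic_true = "somatic")
  expect_message(recs <- load_source(p, "uniprot", cols), "1 row")
  expect_equal(nrow(recs), 3)
  expect_equal(sum(recs$somatic), 1)
  expect_equal(recs$source, rep("uniprot", 3))

  empty <- write_source_tsv(data.frame(g = character(0), d = character(0)))
  expect_equal(nrow(load_source(empty, "other",
                                list(gene = "g", disease = "d"))), 0)
  expect_error(load_source(p, "clinvar", list(gene = "nope", disease = "d")),
               "absent")
})

test_that("exclude_somatic keeps exactly the germline records", {
  recs <- data.frame(source = "uniprot", gene_key = letters[1:7],
                     disease_key = "x",
                     somatic = c(rep(FALSE, 5), TRUE, TRUE))
  expect_message(kept <- exclude_somatic(recs), "2 somatic")
  expect_equal(nrow(kept), 5)
  expect_equal(nrow(exclude_somatic(kept)), 5)          # all-germline identity
  all_som <- transform(recs, somatic = TRUE)
  expect_equal(nrow(suppressMessages(exclude_somatic(all_som))), 0)
})

test_that("merge_union deduplicates across sources and keeps provenance", {
  idx <- build_gene_index(dummy_genes())
  map <- dummy_map()
  u <- function(src, g, d) data.frame(source = src, gene_key = g,
                                      disease_key = d, somatic = FALSE)
  res <- merge_union(list(
    u("uniprot", "P1", "OMIM:100001"),
    u("monarch", "AAA", "MONDO:0000001"),     # same pair via symbol + id
    u("clinvar", "BBB1", "disease two")       # synonym + name
  ), idx, map)
  expect_equal(nrow(res$union), 2)
  first <- res$union[res$union$accession == "P1", ]
  expect_equal(first$sources, "monarch;uniprot")
  expect_equal(res$union$disease_id, c("MONDO:0000001", "MONDO:0000002"))
  expect_equal(nrow(res$rejects), 0)
})

test_that("unresolvable and ambiguous keys land in the rejects report", {
  genes <- dummy_genes()
  genes$symbol[2] <- "AAA"           # AAA now names two accessions
  idx <- build_gene_index(genes)
  map <- dummy_map()
  res <- merge_union(data.frame(
    source = "monarch",
    gene_key = c("AAA", "GHOST", "P1", "P1"),
    disease_key = c("OMIM:100001", "OMIM:100001", "no such disease",
                    "OMIM:100003"),
    somatic = FALSE
  ), idx, map)
  expect_equal(sort(res$rejects$reason),
               c("ambiguous_gene", "unresolved_disease", "unresolved_gene"))
  expect_equal(nrow(res$union), 1)
  # traceability: every input row is either merged or rejected
  expect_equal(res$n_input, 4)
  expect_equal(nrow(res$rejects) + 1, res$n_input)
})

test_that("merging is order-independent and bounded by input size", {
  idx <- build_gene_index(dummy_genes())
  map <- dummy_map()
  srcs <- list(
    data.frame(source = "uniprot", gene_key = c("P1", "P1", "P2", "P2"),
               disease_key = c("OMIM:100001", "OMIM:100002", "OMIM:100001",
                               "OMIM:100003"), somatic = FALSE),
    data.frame(source = "monarch", gene_key = c("AAA", "BBB", "BBB"),
               disease_key = c("MONDO:0000001", "MONDO:0000001",
                               "MONDO:0000002"), somatic = FALSE),
    data.frame(source = "clinvar", gene_key = c("AAA1", "BBB1", "BBB2"),
               disease_key = c("disease three", "DISEASE ONE", "disease two"),
               somatic = FALSE)
  )
  a <- merge_union(srcs, idx, map)
  b <- merge_union(rev(srcs), idx, map)
  expect_identical(a$union, b$union)
  expect_lte(nrow(a$union), sum(vapply(srcs, nrow, integer(1))))
  # 4 + 3 + 3 raw pairs; set union over resolved (accession, disease) pairs
  # leaves 6 distinct associations (4 cross-source duplicates collapse)
  expect_equal(nrow(a$union), 6)
})
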