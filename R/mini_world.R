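#' A hand-built miniature world with a hand-verified manifest
#'
#' A fixed, fully deterministic fixture bundle mirroring the structural motifs
#' of the real disease-enzyme-pathway landscape: one pleiotropic kinase
#' annotated to 8 leaf pathways under 6 roots with two diseases (the SRC
#' motif), three proteasome-like subunits sharing 12 leaves under 12 roots
#' (one biunivocal disease each), two glycine-degradation enzymes sharing one
#' leaf across three diseases (the polygenic type-A motif), one GO-only
#' enzyme, one multiclass enzyme annotated only under the excluded "Disease"
#' root, two unannotated enzymes carrying excluded diseases, one non-enzyme
#' gene, plus one somatic row and one cross-source duplicate for the ingest
#' layer to clean up.
#'
#' @param dir Output directory (created).
#' @return As [generate_dataset()]: list with `dir`, `files`, `sources` and
#'   the hand-verified `manifest`.
#' @export
mini_paper_world <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  species <- "Homo sapiens"

  root_names <- c("Metabolism", "Signal transduction", "Immune system",
                  "Gene expression", "Cell cycle", "Developmental biology",
                  "Hemostasis", "Programmed cell death",
                  "Transport of small molecules", "DNA replication",
                  "Metabolism of proteins", "Cellular responses to stimuli",
                  "Autophagy", "Disease", "Drug ADME")
  root_ids <- sprintf("R-MINI-%04d", seq_along(root_names))
  shared_leaf <- function(k) sprintf("R-MINI-%04d", 300 + k)  # one per root
  second_leaf <- function(k) sprintf("R-MINI-%04d", 400 + k)

  pathways <- data.frame(id = root_ids, name = root_names,
                         stringsAsFactors = FALSE)
  relations <- data.frame(parent = character(0), child = character(0),
                          stringsAsFactors = FALSE)
  add_event <- function(id, name, parent) {
    pathways <<- rbind(pathways, data.frame(id = id, name = name))
    relations <<- rbind(relations, data.frame(parent = parent, child = id))
  }
  add_event("R-MINI-0100", "Amino acid metabolism", root_ids[1])
  add_event("R-MINI-0201", "Glycine degradation", "R-MINI-0100")
  add_event("R-MINI-0202", "Serine biosynthesis", "R-MINI-0100")
  for (k in 2:13) add_event(shared_leaf(k),
                            paste("Shared leaf of", root_names[k]),
                            root_ids[k])
  for (k in 2:7) add_event(second_leaf(k),
                           paste("Second leaf of", root_names[k]),
                           root_ids[k])
  add_event("R-MINI-0314", "Leaf under Disease", root_ids[14])
  add_event("R-MINI-0315", "Leaf under Drug ADME", root_ids[15])

  genes <- list(
    accession = c("P-SRC", "P-PSB8", "P-PSB9", "P-PSB10", "P-GLDC", "P-AMT",
                  "P-MONOA", "P-DISONLY", "P-UNANN1", "P-UNANN2", "P-NONENZ"),
    symbol = c("SRC1", "PSB8", "PSB9", "PSB10", "GLDC", "AMT",
               "MONOA", "DISONLY", "UNANN1", "UNANN2", "NONENZ"),
    synonyms = list("SRCA", "PSB8A", "PSB9A", "PSB10A", "GLDCA", "AMTA",
                    "MONOAA", "DISONLYA", "UNANN1A", "UNANN2A", "NONENZA"),
    ec = list("2.7.10.2", "3.4.25.1", "3.4.25.1", "3.4.25.1", "1.4.4.2",
              "2.1.2.10", character(0), c("1.1.1.1", "2.3.1.1"),
              "6.1.1.1", "7.1.1.1", character(0)),
    go = list("GO:0016301", character(0), character(0), character(0),
              character(0), character(0), "GO:0016787", character(0),
              character(0), character(0), "GO:0005488")
  )

  dis <- data.frame(
    id = sprintf("MONDO:%07d", 900000 + 1:14),
    name = c("mini osteoporosis", "mini thrombocytopenia",
             "mini autoinflammatory syndrome 1",
             "mini autoinflammatory syndrome 3",
             "mini autoinflammatory syndrome 5",
             "mini glycine encephalopathy atypical",
             "mini glycine encephalopathy neonatal",
             "mini glycine encephalopathy infantile",
             "mini single pathway disease",
             "mini disease-root-only disease",
             "mini excluded monogenic disease",
             "mini excluded polygenic disease",
             "mini non-enzyme disease", "mini somatic-only cancer"),
    omim = sprintf("OMIM:%06d", 910000 + 1:14),
    orphanet = c(sprintf("Orphanet:%d", 90000 + 1:8), "", "",
                 "Orphanet:90011", "", "", ""),
    stringsAsFactors = FALSE
  )
  did <- stats::setNames(dis$id, c("OSTEO", "THROMBO", "PRAAS1", "PRAAS3",
                                   "PRAAS5", "GLY1", "GLY2", "GLY3", "MONOA",
                                   "DISONLY", "EXMONO", "EXPOLY", "NONENZ",
                                   "SOMA"))

  annotations <- list(
    "P-SRC" = c(shared_leaf(2), shared_leaf(3), second_leaf(2:7)),
    "P-PSB8" = shared_leaf(2:13),
    "P-PSB9" = shared_leaf(2:13),
    "P-PSB10" = shared_leaf(2:13),
    "P-GLDC" = "R-MINI-0201",
    "P-AMT" = "R-MINI-0201",
    "P-MONOA" = "R-MINI-0202",
    "P-DISONLY" = "R-MINI-0314"
  )
  reactions <- list(
    "P-SRC" = c("R-RXN-SRC1", "R-RXN-SRC2", "R-RXN-SRC3"),
    "P-PSB8" = c("R-RXN-PROT1", "R-RXN-PROT2"),
    "P-PSB9" = c("R-RXN-PROT1", "R-RXN-PROT2"),
    "P-PSB10" = c("R-RXN-PROT1", "R-RXN-PROT2"),
    "P-GLDC" = "R-RXN-GLY1", "P-AMT" = "R-RXN-GLY2",
    "P-MONOA" = "R-RXN-MONO1", "P-DISONLY" = "R-RXN-DIS1"
  )

  # source rows: uniprot keys by accession+OMIM, monarch by symbol+MONDO,
  # clinvar by synonym+uppercased name; one duplicate, one somatic row
  omim_of <- stats::setNames(dis$omim, dis$id)
  name_of <- stats::setNames(dis$name, dis$id)
  row_of <- function(source, acc, d, somatic = FALSE) {
    sym <- genes$symbol[match(acc, genes$accession)]
    syn <- genes$synonyms[[match(acc, genes$accession)]][1]
    key <- switch(source, uniprot = acc, monarch = sym, clinvar = syn)
    dkey <- switch(source, uniprot = unname(omim_of[[d]]), monarch = d,
                   clinvar = toupper(unname(name_of[[d]])))
    data.frame(source = source, gene_key = key, disease_key = dkey,
               somatic_flag = somatic, stringsAsFactors = FALSE)
  }
  rows <- rbind(
    row_of("uniprot", "P-SRC", did[["OSTEO"]]),
    row_of("uniprot", "P-SRC", did[["THROMBO"]]),
    row_of("uniprot", "P-PSB8", did[["PRAAS1"]]),
    row_of("uniprot", "P-GLDC", did[["GLY1"]]),
    row_of("uniprot", "P-GLDC", did[["GLY2"]]),
    row_of("uniprot", "P-MONOA", did[["MONOA"]]),
    row_of("uniprot", "P-UNANN1", did[["EXMONO"]]),
    row_of("uniprot", "P-SRC", did[["SOMA"]], somatic = TRUE),
    row_of("monarch", "P-PSB9", did[["PRAAS3"]]),
    row_of("monarch", "P-AMT", did[["GLY1"]]),
    row_of("monarch", "P-AMT", did[["GLY2"]]),
    row_of("monarch", "P-GLDC", did[["GLY3"]]),
    row_of("monarch", "P-DISONLY", did[["DISONLY"]]),
    row_of("monarch", "P-UNANN1", did[["EXPOLY"]]),
    row_of("monarch", "P-SRC", did[["OSTEO"]]),   # cross-source duplicate
    row_of("clinvar", "P-PSB10", did[["PRAAS5"]]),
    row_of("clinvar", "P-AMT", did[["GLY3"]]),
    row_of("clinvar", "P-UNANN2", did[["EXPOLY"]]),
    row_of("clinvar", "P-NONENZ", did[["NONENZ"]])
  )

  ## hand-verified expectations -------------------------------------------
  roots6 <- root_ids[2:7]; roots12 <- root_ids[2:13]
  nodes <- data.frame(
    root = root_ids[1:13],
    disease_count = c(4L, rep(5L, 6), rep(3L, 6)),
    stringsAsFactors = FALSE
  )
  pair_df <- function(roots, w) {
    cmb <- utils::combn(sort(roots), 2L)
    data.frame(root_a = cmb[1, ], root_b = cmb[2, ], shared_diseases = w,
               stringsAsFactors = FALSE)
  }
  e12 <- pair_df(roots12, 3L)                  # the three PRAAS-like diseases
  in6 <- e12$root_a %in% roots6 & e12$root_b %in% roots6
  e12$shared_diseases[in6] <- 5L               # plus the two SRC-like diseases
  edges <- e12[order(e12$root_a, e12$root_b), , drop = FALSE]
  rownames(edges) <- NULL

  manifest <- list(
    n_union = 17L, n_enzymes = 10L, n_enzyme_associations = 16L,
    n_diseases = 12L,
    category_counts = list(monogenic_A = 2L, monogenic_B = 5L,
                           polygenic_A = 3L, polygenic_B = 0L,
                           excluded = 2L),
    association_type_counts = list(biunivocal = 5L, univocal = 1L,
                                   non_univocal = 4L),
    enzyme_class_counts = list(EC1 = 1L, EC2 = 2L, EC3 = 3L, EC4 = 0L,
                               EC5 = 0L, EC6 = 1L, EC7 = 1L, Multiclass = 1L,
                               WithoutEC = 1L),
    hist_enzymes_per_disease = data.frame(bucket = c(1L, 2L),
                                          count = c(8L, 4L)),
    hist_roots_per_enzyme = data.frame(bucket = c(1L, 6L, 12L),
                                       count = c(3L, 1L, 3L)),
    hist_roots_per_disease = data.frame(bucket = c(1L, 6L, 12L),
                                        count = c(4L, 2L, 3L)),
    network_nodes = nodes, network_edges = edges,
    n_rare = 9L, n_somatic_rows = 1L
  )

  ## write the bundle -------------------------------------------------------
  files <- write_pathway_files(dir, pathways, relations, species)
  go_path <- file.path(dir, "go_mf.obo"); write_toy_go_obo(go_path)
  dis_path <- file.path(dir, "diseases.obo")
  write_disease_obo(dis_path, dis)
  gene_path <- write_gene_records(file.path(dir, "gene_records.tsv"), genes)
  ann_acc <- rep(names(annotations), lengths(annotations))
  ann_pw <- unlist(annotations, use.names = FALSE)
  ann_path <- write_annotation_file(
    file.path(dir, "protein2pathway.tsv"), ann_acc, ann_pw,
    pathways$name[match(ann_pw, pathways$id)], species)
  rx_acc <- rep(names(reactions), lengths(reactions))
  rx_id <- unlist(reactions, use.names = FALSE)
  rx_path <- write_annotation_file(
    file.path(dir, "protein2reaction.tsv"), rx_acc, rx_id,
    paste("reaction", rx_id), species)
  src_paths <- write_source_files(dir, rows)
  cmap <- source_column_maps()
  sources <- list(
    uniprot = list(path = unname(src_paths[["uniprot"]]), columns = cmap$uniprot),
    monarch = list(path = unname(src_paths[["monarch"]]), columns = cmap$monarch),
    clinvar = list(path = unname(src_paths[["clinvar"]]), columns = cmap$clinvar)
  )
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  list(dir = dir,
       files = c(files, go_obo = go_path, disease_obo = dis_path,
                 gene_records = gene_path, protein_pathways = ann_path,
                 protein_reactions = rx_path, src_paths,
                 manifest = manifest_path),
       sources = sources, manifest = manifest)
}
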