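#' Specification for the synthetic dataset generator
#'
#' Defines the structure of a complete toy input bundle: pathway hierarchy
#' shape, planted disease-category counts, EC class mix, and the noise the
#' ingest layer must survive (somatic rows, cross-source duplicates). The
#' generator plants category membership constructively, so the returned
#' manifest is exact, not statistical.
#'
#' @param seed Integer random seed; identical specs and seeds give
#'   byte-identical bundles.
#' @param n_roots Number of hierarchy roots, two of which are named
#'   `"Disease"` and `"Drug ADME"` to exercise root exclusion.
#' @param depth Levels below each root (the last level is the leaves).
#' @param branching Children per non-leaf node.
#' @param counts Named integer vector of planted disease-category counts over
#'   `monogenic_A`, `monogenic_B`, `polygenic_A`, `polygenic_B`, `excluded`.
#' @param ec_class_weights Sampling weights for EC level-1 classes 1-7.
#' @param p_multiclass Probability an EC-bearing enzyme carries two level-1
#'   classes.
#' @param p_go_only Probability an enzyme has no EC number and qualifies only
#'   through a catalytic-activity GO descendant (the Without-EC class).
#' @param p_shared_enzyme Fraction of monogenic diseases paired to share one
#'   enzyme (plants non-univocal enzymes without disturbing categories).
#' @param p_extra_excluded_leaf Probability a type-B enzyme gets an extra
#'   leaf under the excluded `"Disease"` root (exercises exclusion).
#' @param n_nonenzyme_genes Genes with neither EC nor catalytic GO, each with
#'   one own disease; they must fall out at the enzyme filter.
#' @param p_somatic Somatic rows injected, as a fraction of germline pairs.
#' @param p_duplicate Fraction of germline pairs duplicated into a second
#'   source.
#' @param p_orphanet Fraction of diseases given an Orphanet xref (rare).
#' @return A validated `generator_spec` list.
#' @export
generator_spec <- function(seed = 1L, n_roots = 29L, depth = 2L,
                           branching = 3L,
                           counts = c(monogenic_A = 30L, monogenic_B = 40L,
                                      polygenic_A = 3L, polygenic_B = 10L,
                                      excluded = 9L),
                           ec_class_weights = c(208, 544, 445, 52, 34, 63, 56),
                           p_multiclass = 0.05, p_go_only = 0.1,
                           p_shared_enzyme = 0.2,
                           p_extra_excluded_leaf = 0.15,
                           n_nonenzyme_genes = 5L,
                           p_somatic = 0.1, p_duplicate = 0.25,
                           p_orphanet = 0.75) {
  lv <- disease_category_levels()
  stopifnot(all(lv %in% names(counts)), all(counts >= 0),
            n_roots >= 3L, depth >= 1L, branching >= 1L,
            length(ec_class_weights) == 7L, all(ec_class_weights >= 0))
  probs <- c(p_multiclass, p_go_only, p_shared_enzyme, p_extra_excluded_leaf,
             p_somatic, p_duplicate, p_orphanet)
  stopifnot(all(probs >= 0 & probs <= 1))
  structure(
    list(seed = as.integer(seed), n_roots = as.integer(n_roots),
         depth = as.integer(depth), branching = as.integer(branching),
         counts = counts[lv], ec_class_weights = ec_class_weights,
         p_multiclass = p_multiclass, p_go_only = p_go_only,
         p_shared_enzyme = p_shared_enzyme,
         p_extra_excluded_leaf = p_extra_excluded_leaf,
         n_nonenzyme_genes = as.integer(n_nonenzyme_genes),
         p_somatic = p_somatic, p_duplicate = p_duplicate,
         p_orphanet = p_orphanet),
    class = "generator_spec"
  )
}

# GO toy molecular-function subtree used by every generated bundle
toy_go_terms <- function() {
  list(
    c(id = "GO:0003824", name = "catalytic activity", parent = NA),
    c(id = "GO:0016491", name = "oxidoreductase activity", parent = "GO:0003824"),
    c(id = "GO:0016740", name = "transferase activity", parent = "GO:0003824"),
    c(id = "GO:0016787", name = "hydrolase activity", parent = "GO:0003824"),
    c(id = "GO:0016829", name = "lyase activity", parent = "GO:0003824"),
    c(id = "GO:0016853", name = "isomerase activity", parent = "GO:0003824"),
    c(id = "GO:0016874", name = "ligase activity", parent = "GO:0003824"),
    c(id = "GO:0022804", name = "active transmembrane transporter activity",
      parent = "GO:0003824"),
    c(id = "GO:0016301", name = "kinase activity", parent = "GO:0016740"),
    c(id = "GO:0005488", name = "binding", parent = NA)
  )
}

write_toy_go_obo <- function(path) {
  out <- c("format-version: 1.2", "")
  for (t in toy_go_terms()) {
    stanza <- c("[Term]", paste0("id: ", t[["id"]]),
                paste0("name: ", t[["name"]]),
                "namespace: molecular_function")
    if (!is.na(t[["parent"]])) stanza <- c(stanza, paste0("is_a: ", t[["parent"]]))
    out <- c(out, stanza, "")
  }
  writeLines(out, path)
}

catalytic_leaf_pool <- function() {
  c("GO:0016491", "GO:0016740", "GO:0016787", "GO:0016829", "GO:0016853",
    "GO:0016874", "GO:0022804", "GO:0016301")
}

write_disease_obo <- function(path, diseases) {
  out <- c("format-version: 1.2", "")
  for (i in seq_len(nrow(diseases))) {
    d <- diseases[i, ]
    stanza <- c("[Term]", paste0("id: ", d$id), paste0("name: ", d$name),
                "namespace: disease", paste0("xref: ", d$omim))
    if (nzchar(d$orphanet)) stanza <- c(stanza, paste0("xref: ", d$orphanet))
    out <- c(out, stanza, "")
  }
  writeLines(out, path)
}

write_pathway_files <- function(dir, pathways, relations, species) {
  pw_path <- file.path(dir, "pathways.tsv")
  rel_path <- file.path(dir, "pathway_relations.tsv")
  utils::write.table(
    data.frame(pathways$id, pathways$name, species),
    pw_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(relations, rel_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  c(pathway_table = pw_path, relation_table = rel_path)
}

write_annotation_file <- function(path, accession, event_id, event_names,
                                  species) {
  df <- data.frame(
    accession, event_id,
    url = paste0("https://example.org/", event_id),
    name = event_names, evidence = "TAS", species = species,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  path
}

write_gene_records <- function(path, genes) {
  df <- data.frame(
    accession = genes$accession, symbol = genes$symbol,
    synonyms = vapply(genes$synonyms, paste, character(1), collapse = ";"),
    ec_numbers = vapply(genes$ec, paste, character(1), collapse = ";"),
    go_mf_terms = vapply(genes$go, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Column maps of the three synthetic source dialects
#'
#' @return Named list usable as the `columns` entries of a
#'   [pipeline_config()] `sources` argument.
#' @export
source_column_maps <- function() {
  list(
    uniprot = list(gene = "accession", disease = "disease_id",
                   somatic = "origin", somatic_true = "somatic"),
    monarch = list(gene = "gene_symbol", disease = "mondo_id",
                   somatic = "allele_origin", somatic_true = "somatic"),
    clinvar = list(gene = "GeneSymbol", disease = "Condition",
                   somatic = "OriginSimple", somatic_true = "somatic")
  )
}

write_source_files <- function(dir, rows) {
  # rows: data.frame source, gene_key, disease_key, somatic_flag
  paths <- c(uniprot = file.path(dir, "source_uniprot.tsv"),
             monarch = file.path(dir, "source_monarch.tsv"),
             clinvar = file.path(dir, "source_clinvar.tsv"))
  headers <- list(
    uniprot = c("accession", "disease_id", "origin"),
    monarch = c("gene_symbol", "mondo_id", "allele_origin"),
    clinvar = c("GeneSymbol", "Condition", "OriginSimple")
  )
  for (s in names(paths)) {
    sub <- rows[rows$source == s, , drop = FALSE]
    df <- data.frame(a = sub$gene_key, b = sub$disease_key,
                     c = ifelse(sub$somatic_flag, "somatic", "germline"),
                     stringsAsFactors = FALSE)
    names(df) <- headers[[s]]
    utils::write.table(df, paths[[s]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  paths
}

#' Generate a complete synthetic input bundle with a planted truth manifest
#'
#' Builds, constructively, a pathway forest (including the two excluded
#' roots), a molecular-function ontology rooted at catalytic activity, a
#' MONDO-like disease ontology with OMIM/Orphanet xrefs, gene records, three
#' source association tables (UniProt-, Monarch- and ClinVar-flavoured, with
#' planted cross-source duplicates and somatic rows) and protein-to-pathway /
#' protein-to-reaction annotation files. Category membership is planted
#' first and files are derived from it, so the returned manifest states the
#' exact counts the pipeline must recover.
#'
#' @param spec A `generator_spec`.
#' @param dir Output directory (created).
#' @return List with `dir`, `files` (named paths), `sources` (ready-made
#'   `sources` argument for [pipeline_config()]) and `manifest` (see
#'   details). The manifest is also written to `manifest.json`.
#' @details Manifest fields: `n_union`, `n_enzymes`,
#'   `n_enzyme_associations`, `n_diseases`, `category_counts`,
#'   `association_type_counts`, `hist_enzymes_per_disease`,
#'   `hist_roots_per_enzyme`, `hist_roots_per_disease`, `network_nodes`,
#'   `network_edges`, `n_rare`, `n_somatic_rows`.
#' @export
generate_dataset <- function(spec, dir) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  species <- "Homo sapiens"
  counts <- spec$counts

  ## ---- pathway forest ----------------------------------------------------
  pid_counter <- 0L
  new_pid <- function() {
    pid_counter <<- pid_counter + 1L
    sprintf("R-TOY-%07d", pid_counter)
  }
  root_names <- c(paste("Synthetic root", seq_len(spec$n_roots - 2L)),
                  "Disease", "Drug ADME")
  pathways <- data.frame(id = character(0), name = character(0),
                         stringsAsFactors = FALSE)
  relations <- data.frame(parent = character(0), child = character(0),
                          stringsAsFactors = FALSE)
  leaf_root <- character(0)  # leaf id -> owning root id (trees by design)
  root_ids <- character(spec$n_roots)
  for (r in seq_len(spec$n_roots)) {
    rid <- new_pid(); root_ids[r] <- rid
    pathways <- rbind(pathways, data.frame(id = rid, name = root_names[r]))
    level <- rid
    for (d in seq_len(spec$depth)) {
      nxt <- character(0)
      for (p in level) {
        for (b in seq_len(spec$branching)) {
          cid <- new_pid()
          kindname <- if (d == spec$depth) "leaf" else "node"
          pathways <- rbind(pathways, data.frame(
            id = cid, name = paste0("Synthetic ", kindname, " ", cid)))
          relations <- rbind(relations, data.frame(parent = p, child = cid))
          nxt <- c(nxt, cid)
        }
      }
      level <- nxt
    }
    leaf_root[level] <- rid
  }
  excluded_ids <- root_ids[root_names %in% c("Disease", "Drug ADME")]
  ok_leaves <- names(leaf_root)[!(leaf_root %in% excluded_ids)]
  excl_leaves <- names(leaf_root)[leaf_root %in% excluded_ids]

  n_annotated <- sum(counts[c("monogenic_A", "monogenic_B",
                              "polygenic_A", "polygenic_B")])
  if (n_annotated > 0 && length(ok_leaves) == 0) {
    stop("infeasible spec: annotated categories planted but the hierarchy ",
         "has no leaf outside the excluded roots")
  }
  if (counts[["monogenic_B"]] + counts[["polygenic_B"]] > 0 &&
      length(ok_leaves) < 2) {
    stop("infeasible spec: type-B categories need at least two usable leaves")
  }

  ## ---- genes, diseases, planted structure --------------------------------
  genes <- list(accession = character(0), symbol = character(0),
                synonyms = list(), ec = list(), go = list())
  gene_counter <- 0L
  new_gene <- function(ec, go) {
    gene_counter <<- gene_counter + 1L
    acc <- sprintf("P%05d", 10000L + gene_counter)
    sym <- sprintf("GENE%04d", gene_counter)
    genes$accession <<- c(genes$accession, acc)
    genes$symbol <<- c(genes$symbol, sym)
    genes$synonyms[[length(genes$synonyms) + 1L]] <<- paste0(sym, c("A", "B"))
    genes$ec[[length(genes$ec) + 1L]] <<- ec
    genes$go[[length(genes$go) + 1L]] <<- go
    acc
  }
  random_ec <- function(class) {
    sprintf("%d.%d.%d.%d", class, sample(1:20, 1), sample(1:20, 1),
            sample(1:50, 1))
  }
  new_enzyme <- function() {
    if (stats::runif(1) < spec$p_go_only) {
      return(new_gene(character(0), sample(catalytic_leaf_pool(), 1)))
    }
    k <- if (stats::runif(1) < spec$p_multiclass) 2L else 1L
    classes <- sample(1:7, k, prob = spec$ec_class_weights)
    go <- if (stats::runif(1) < 0.3) sample(catalytic_leaf_pool(), 1) else character(0)
    new_gene(vapply(classes, random_ec, character(1)), go)
  }

  dis_counter <- 0L
  diseases <- data.frame(id = character(0), name = character(0),
                         omim = character(0), orphanet = character(0),
                         stringsAsFactors = FALSE)
  new_disease <- function(rare = stats::runif(1) < spec$p_orphanet) {
    dis_counter <<- dis_counter + 1L
    id <- sprintf("MONDO:%07d", 800000L + dis_counter)
    diseases <<- rbind(diseases, data.frame(
      id = id, name = paste("synthetic disease", dis_counter),
      omim = sprintf("OMIM:%06d", 600000L + dis_counter),
      orphanet = if (rare) sprintf("Orphanet:%d", 100000L + dis_counter) else "",
      stringsAsFactors = FALSE
    ))
    id
  }

  pairs <- data.frame(accession = character(0), disease = character(0),
                      stringsAsFactors = FALSE)
  annotations <- list()   # accession -> leaf ids (includes excluded-root extras)
  planted_cat <- character(0)  # disease id -> category

  add_pair <- function(acc, dis) {
    pairs <<- rbind(pairs, data.frame(accession = acc, disease = dis))
  }
  maybe_excluded_extra <- function(leaves) {
    if (length(excl_leaves) &&
        stats::runif(1) < spec$p_extra_excluded_leaf) {
      c(leaves, sample(excl_leaves, 1))
    } else leaves
  }

  plant_monogenic <- function(n, type) {
    if (n == 0L) return(invisible())
    n_pairs <- floor(spec$p_shared_enzyme * n / 2)
    i <- 0L
    while (i < n) {
      shared <- n_pairs > 0L && (n - i) >= 2L
      if (shared) n_pairs <- n_pairs - 1L
      leaves <- if (type == "A") {
        sample(ok_leaves, 1)
      } else {
        rng <- 2:min(4, length(ok_leaves))
        sample(ok_leaves, rng[sample.int(length(rng), 1)])
      }
      if (type == "B") leaves <- maybe_excluded_extra(leaves)
      acc <- new_enzyme()
      annotations[[acc]] <<- sort(unique(leaves))
      for (j in seq_len(if (shared) 2L else 1L)) {
        d <- new_disease()
        planted_cat[d] <<- paste0("monogenic_", type)
        add_pair(acc, d)
        i <- i + 1L
      }
    }
  }
  plant_monogenic(counts[["monogenic_A"]], "A")
  plant_monogenic(counts[["monogenic_B"]], "B")

  for (k in seq_len(counts[["polygenic_A"]])) {
    leaf <- sample(ok_leaves, 1)
    d <- new_disease(); planted_cat[d] <- "polygenic_A"
    for (j in 1:2) {
      acc <- new_enzyme()
      annotations[[acc]] <- leaf
      add_pair(acc, d)
    }
  }
  for (k in seq_len(counts[["polygenic_B"]])) {
    d <- new_disease(); planted_cat[d] <- "polygenic_B"
    n_enz <- sample(2:3, 1)
    for (j in seq_len(n_enz)) {
      n_leaf <- if (j == 1L) 2L else sample(1:3, 1)
      leaves <- sample(ok_leaves, min(n_leaf, length(ok_leaves)))
      acc <- new_enzyme()
      annotations[[acc]] <- sort(unique(maybe_excluded_extra(leaves)))
      add_pair(acc, d)
    }
  }
  for (k in seq_len(counts[["excluded"]])) {
    d <- new_disease(); planted_cat[d] <- "excluded"
    add_pair(new_enzyme(), d)  # enzyme left without pathway annotation
  }

  enzyme_accessions <- genes$accession
  for (k in seq_len(spec$n_nonenzyme_genes)) {
    acc <- new_gene(character(0), "GO:0005488")
    add_pair(acc, new_disease())
  }

  ## ---- truth manifest (direct arithmetic on the planted structure) -------
  enz_pairs <- pairs[pairs$accession %in% enzyme_accessions, , drop = FALSE]
  n_dis_per_enz <- table(enz_pairs$accession)
  n_enz_per_dis <- table(enz_pairs$disease)
  assoc_type <- vapply(names(n_dis_per_enz), function(a) {
    if (n_dis_per_enz[[a]] >= 2L) return("non_univocal")
    d <- enz_pairs$disease[enz_pairs$accession == a]
    if (n_enz_per_dis[[d]] == 1L) "biunivocal" else "univocal"
  }, character(1))

  enzyme_roots_truth <- lapply(annotations, function(lv) {
    sort(unique(unname(leaf_root[setdiff(lv, excl_leaves)])))
  })
  disease_roots_truth <- lapply(split(enz_pairs$accession, enz_pairs$disease),
                                function(accs) {
    sort(unique(unlist(enzyme_roots_truth[accs], use.names = FALSE)))
  })
  disease_roots_truth <- disease_roots_truth[lengths(disease_roots_truth) > 0]

  hist_of <- function(v) {
    tab <- table(v)
    data.frame(bucket = as.integer(names(tab)), count = as.integer(tab))
  }
  edge_weights <- list()
  for (s in disease_roots_truth) {
    if (length(s) < 2L) next
    cmb <- utils::combn(sort(s), 2L)
    for (j in seq_len(ncol(cmb))) {
      key <- paste(cmb[1, j], cmb[2, j], sep = "|")
      edge_weights[[key]] <- (edge_weights[[key]] %||% 0L) + 1L
    }
  }
  nodes_truth <- sort(unique(unlist(disease_roots_truth, use.names = FALSE)))
  node_weights <- vapply(nodes_truth, function(r)
    sum(vapply(disease_roots_truth, function(s) r %in% s, logical(1))),
    integer(1))

  manifest <- list(
    n_union = nrow(pairs),
    n_enzymes = length(enzyme_accessions),
    n_enzyme_associations = nrow(enz_pairs),
    n_diseases = length(unique(enz_pairs$disease)),
    category_counts = as.list(table(factor(planted_cat,
                                           levels = disease_category_levels()))),
    association_type_counts = as.list(table(factor(assoc_type,
      levels = c("biunivocal", "univocal", "non_univocal")))),
    hist_enzymes_per_disease = hist_of(as.integer(n_enz_per_dis)),
    hist_roots_per_enzyme = hist_of(
      lengths(enzyme_roots_truth)[lengths(enzyme_roots_truth) > 0]),
    hist_roots_per_disease = hist_of(lengths(disease_roots_truth)),
    network_nodes = data.frame(root = nodes_truth,
                               disease_count = unname(node_weights),
                               stringsAsFactors = FALSE),
    network_edges = if (length(edge_weights)) {
      parts <- do.call(rbind, strsplit(names(edge_weights), "|", fixed = TRUE))
      ew <- data.frame(root_a = parts[, 1], root_b = parts[, 2],
                       shared_diseases = unlist(edge_weights, use.names = FALSE),
                       stringsAsFactors = FALSE)
      ew <- ew[order(ew$root_a, ew$root_b), , drop = FALSE]
      rownames(ew) <- NULL
      ew
    } else {
      data.frame(root_a = character(0), root_b = character(0),
                 shared_diseases = integer(0), stringsAsFactors = FALSE)
    },
    n_rare = sum(diseases$orphanet != "" &
                   diseases$id %in% enz_pairs$disease)
  )

  ## ---- association rows (sources, duplicates, somatic noise) -------------
  n_pairs <- nrow(pairs)
  src_labels <- c("uniprot", "monarch", "clinvar")
  primary <- src_labels[(seq_len(n_pairs) - 1L) %% 3L + 1L]
  rows <- data.frame(source = primary, accession = pairs$accession,
                     disease = pairs$disease, somatic_flag = FALSE,
                     stringsAsFactors = FALSE)
  n_dup <- floor(spec$p_duplicate * n_pairs)
  if (n_dup > 0) {
    dup_i <- sample(n_pairs, n_dup)
    dup <- rows[dup_i, , drop = FALSE]
    dup$source <- src_labels[match(dup$source, src_labels) %% 3L + 1L]
    rows <- rbind(rows, dup)
  }
  n_som <- ceiling(spec$p_somatic * n_pairs)
  if (n_som > 0) {
    som_acc <- sample(enzyme_accessions, n_som, replace = TRUE)
    som_dis <- vapply(seq_len(n_som), function(i) new_disease(rare = FALSE),
                      character(1))
    rows <- rbind(rows, data.frame(
      source = src_labels[(seq_len(n_som) - 1L) %% 3L + 1L],
      accession = som_acc, disease = som_dis, somatic_flag = TRUE,
      stringsAsFactors = FALSE))
  }
  manifest$n_somatic_rows <- n_som

  # per-dialect gene and disease keys
  sym_of <- stats::setNames(genes$symbol, genes$accession)
  syn_of <- stats::setNames(vapply(genes$synonyms, `[`, character(1), 1),
                            genes$accession)
  omim_of <- stats::setNames(diseases$omim, diseases$id)
  name_of <- stats::setNames(diseases$name, diseases$id)
  rows$gene_key <- ifelse(rows$source == "uniprot", rows$accession,
                          ifelse(rows$source == "monarch",
                                 sym_of[rows$accession],
                                 syn_of[rows$accession]))
  rows$disease_key <- ifelse(rows$source == "uniprot", omim_of[rows$disease],
                             ifelse(rows$source == "monarch", rows$disease,
                                    toupper(name_of[rows$disease])))

  ## ---- write the bundle --------------------------------------------------
  files <- write_pathway_files(dir, pathways, relations, species)
  go_path <- file.path(dir, "go_mf.obo")
  write_toy_go_obo(go_path)
  dis_path <- file.path(dir, "diseases.obo")
  write_disease_obo(dis_path, diseases)
  gene_path <- write_gene_records(file.path(dir, "gene_records.tsv"), genes)

  ann_acc <- rep(names(annotations), lengths(annotations))
  ann_pw <- unlist(annotations, use.names = FALSE)
  pw_names <- pathways$name[match(ann_pw, pathways$id)]
  ann_path <- write_annotation_file(file.path(dir, "protein2pathway.tsv"),
                                    ann_acc, ann_pw, pw_names, species)
  # one toy reaction per annotated leaf
  rx_path <- write_annotation_file(
    file.path(dir, "protein2reaction.tsv"), ann_acc,
    sub("R-TOY", "R-RXN", ann_pw), paste("reaction of", pw_names), species)

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

  list(
    dir = dir,
    files = c(files, go_obo = go_path, disease_obo = dis_path,
              gene_records = gene_path, protein_pathways = ann_path,
              protein_reactions = rx_path, src_paths,
              manifest = manifest_path),
    sources = sources,
    manifest = manifest
  )
}

#' Pipeline configuration for a generated bundle
#'
#' @param bundle Return value of [generate_dataset()] or
#'   [mini_paper_world()].
#' @param out_dir Optional output directory for [run_pipeline()].
#' @return A `pipeline_config`.
#' @export
bundle_config <- function(bundle, out_dir = NULL) {
  f <- bundle$files
  pipeline_config(
    go_obo = f[["go_obo"]], disease_obo = f[["disease_obo"]],
    pathway_table = f[["pathway_table"]],
    relation_table = f[["relation_table"]],
    protein_pathways = f[["protein_pathways"]],
    protein_reactions = f[["protein_reactions"]],
    gene_records = f[["gene_records"]],
    sources = bundle$sources, out_dir = out_dir
  )
}
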