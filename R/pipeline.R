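#' Assemble a pipeline configuration
#'
#' Collects the input file paths and options of a full pipeline run. Paths
#' are checked at run time, stage by stage, so an error names the stage that
#' needed the file.
#'
#' @param go_obo Path to the molecular-function OBO file (must contain the
#'   catalytic activity term GO:0003824).
#' @param disease_obo Path to the disease ontology OBO file (MONDO-like, with
#'   OMIM/Orphanet xrefs).
#' @param pathway_table,relation_table Reactome-style pathway list and
#'   parent-child relation TSVs.
#' @param protein_pathways,protein_reactions Protein-to-pathway and
#'   protein-to-reaction flat files (UniProt2Reactome dialect).
#' @param gene_records Gene record TSV (accession, symbol, synonyms, EC
#'   numbers, GO MF terms).
#' @param sources Named list (names are source labels) of
#'   `list(path = ..., columns = ...)` per association source; `columns` as in
#'   [load_source()].
#' @param species Species kept from the pathway files.
#' @param excluded_root_names Root names dropped from root-level statistics.
#' @param out_dir Output directory (created if absent).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(go_obo, disease_obo, pathway_table, relation_table,
                            protein_pathways, protein_reactions, gene_records,
                            sources, species = "Homo sapiens",
                            excluded_root_names = c("Disease", "Drug ADME"),
                            out_dir = NULL) {
  stopifnot(is.list(sources), length(sources) > 0, !is.null(names(sources)))
  structure(
    list(go_obo = go_obo, disease_obo = disease_obo,
         pathway_table = pathway_table, relation_table = relation_table,
         protein_pathways = protein_pathways,
         protein_reactions = protein_reactions,
         gene_records = gene_records, sources = sources, species = species,
         excluded_root_names = excluded_root_names, out_dir = out_dir),
    class = "pipeline_config"
  )
}

stage_run <- function(name, files, expr) {
  absent <- files[!file.exists(files)]
  if (length(absent)) {
    stop("stage ", name, ": missing input file(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  tryCatch(expr, error = function(e)
    stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
}

#' Append a totals row to a summary table
#'
#' Sums the stated columns (those for which the component rows partition the
#' underlying set, e.g. enzymes and associations of the association-type and
#' enzyme-class tables); any column listed in `recomputed` is filled from a
#' value recomputed on the full data instead, since overlapping columns
#' (distinct diseases, pathways, roots) must never be summed.
#'
#' @param df Summary table with a `set` label column.
#' @param sum_cols Character vector of columns to sum.
#' @param recomputed Named list of values for the remaining columns.
#' @param label Label of the appended row.
#' @return The table with one extra row.
#' @export
add_totals_row <- function(df, sum_cols, recomputed = list(), label = "Total") {
  total <- df[1, , drop = FALSE]
  total$set <- label
  for (col in setdiff(names(df), "set")) {
    total[[col]] <- if (col %in% sum_cols) {
      sum(df[[col]])
    } else if (col %in% names(recomputed)) {
      recomputed[[col]]
    } else {
      NA
    }
  }
  out <- rbind(df, total)
  rownames(out) <- NULL
  out
}

summary_row <- function(label, accessions, union, annotations, reactions,
                        forest) {
  rows <- union[union$accession %in% accessions, , drop = FALSE]
  direct <- unique(unlist(annotations[accessions], use.names = FALSE))
  expanded <- if (length(direct)) expand_to_roots(forest, direct) else character(0)
  rts <- intersect(expanded, setdiff(forest$roots, forest$excluded_roots))
  data.frame(
    set = label,
    enzymes = length(unique(accessions)),
    diseases = length(unique(rows$disease_id)),
    associations = nrow(rows),
    reactome_direct = length(direct),
    reactome_expanded = length(expanded),
    reactions = length(unique(unlist(reactions[accessions], use.names = FALSE))),
    roots = length(rts),
    stringsAsFactors = FALSE
  )
}

#' Build an association-type or enzyme-class summary table
#'
#' One row per group of enzymes plus a recomputed totals row. Per row:
#' enzyme count, distinct diseases, association count, distinct directly
#' annotated pathways, their leaf-to-root expansion, distinct reaction ids
#' and distinct non-excluded roots. The same disease, pathway or root can
#' appear in more than one row; only the enzyme and association columns are
#' partition sums.
#'
#' @param groups Named list: row label -> enzyme accessions.
#' @param union Union-set data.frame restricted to enzymes.
#' @param annotations,reactions Named lists accession -> pathway/reaction ids.
#' @param forest A `pathway_forest`.
#' @return data.frame with columns `set`, `enzymes`, `diseases`,
#'   `associations`, `reactome_direct`, `reactome_expanded`, `reactions`,
#'   `roots`.
#' @export
build_summary_table <- function(groups, union, annotations, reactions,
                                forest) {
  if (length(groups) == 0L) {
    empty <- summary_row("Total", character(0), union, annotations,
                         reactions, forest)
    return(empty[0, , drop = FALSE])
  }
  rows <- do.call(rbind, lapply(names(groups), function(lb)
    summary_row(lb, groups[[lb]], union, annotations, reactions, forest)))
  all_acc <- unique(unlist(groups, use.names = FALSE))
  full <- summary_row("Total", all_acc, union, annotations, reactions, forest)
  add_totals_row(rows, sum_cols = c("enzymes", "associations"),
                 recomputed = as.list(full[-1]))
}

#' Write the two summary tables of a pipeline bundle
#'
#' @param bundle A `summary_bundle` from [run_pipeline()].
#' @param out_dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_summary_tables <- function(bundle, out_dir) {
  p1 <- file.path(out_dir, "table1_association_types.tsv")
  p2 <- file.path(out_dir, "table2_enzyme_classes.tsv")
  utils::write.table(bundle$table1, p1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(bundle$table2, p2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(p1, p2))
}

#' Run the full disease-enzyme-pathway pipeline
#'
#' Stages: ontology parsing and disease-id mapping; pathway hierarchy and
#' protein annotation loading; association ingest (somatic exclusion, union
#' merge); enzyme restriction and EC classification; association-type and
#' disease categorization; root mapping, histograms and the root
#' co-occurrence network; report writing. The run is deterministic for fixed
#' inputs. Any stage failure aborts with a stage-named message. Per-stage
#' record counts go to `message()` (stderr); `quiet = TRUE` suppresses them.
#'
#' @param config A `pipeline_config`.
#' @param quiet Suppress progress messages.
#' @return An object of class `summary_bundle` with all intermediate and
#'   final objects (union set, rejects, enzyme classes, association types,
#'   disease categories, histograms, root maps, network, table1, table2,
#'   summary list). When `config$out_dir` is set, all TSV/JSON/GraphML
#'   outputs are written there.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(...)
  hush <- function(expr) if (quiet) suppressMessages(expr) else expr

  # -- ontology_io ----------------------------------------------------------
  onto <- stage_run("ontology_io", c(config$go_obo, config$disease_obo), {
    go <- parse_obo(config$go_obo)
    dis <- parse_obo(config$disease_obo)
    list(go = go, disease = dis, map = build_disease_map(dis))
  })
  say("ontology_io: ", nrow(onto$go$terms), " GO terms, ",
      nrow(onto$disease$terms), " disease terms")

  # -- pathway_hierarchy ----------------------------------------------------
  pw <- stage_run("pathway_hierarchy",
                  c(config$pathway_table, config$relation_table,
                    config$protein_pathways, config$protein_reactions), {
    forest <- load_forest(config$pathway_table, config$relation_table,
                          excluded_root_names = config$excluded_root_names,
                          species = config$species)
    list(forest = forest,
         annotations = load_protein_pathways(config$protein_pathways, forest,
                                             species = config$species),
         reactions = load_protein_reactions(config$protein_reactions,
                                            species = config$species))
  })
  say("pathway_hierarchy: ", nrow(pw$forest$events), " events, ",
      length(pw$forest$roots), " roots (",
      length(pw$forest$excluded_roots), " excluded)")

  # -- association_ingest ---------------------------------------------------
  src_paths <- vapply(config$sources, `[[`, character(1), "path")
  ingest <- stage_run("association_ingest",
                      c(src_paths, config$gene_records), {
    records <- load_gene_records(config$gene_records)
    per_source <- lapply(names(config$sources), function(s)
      hush(load_source(config$sources[[s]]$path, source = s,
                       columns = config$sources[[s]]$columns)))
    germline <- hush(exclude_somatic(do.call(rbind, per_source)))
    merged <- merge_union(germline, build_gene_index(records), onto$map)
    c(merged, list(records = records))
  })
  say("association_ingest: ", ingest$n_input, " records in, ",
      nrow(ingest$union), " union associations, ",
      nrow(ingest$rejects), " rejects")

  # -- enzyme_annotation ----------------------------------------------------
  enz <- stage_run("enzyme_annotation", character(0), {
    classes <- classify_enzymes(ingest$records, onto$go)
    union_enz <- ingest$union[ingest$union$accession %in% classes$accession, ,
                              drop = FALSE]
    classes <- classes[classes$accession %in% union_enz$accession, ,
                       drop = FALSE]
    list(classes = classes, union = union_enz)
  })
  say("enzyme_annotation: ", nrow(enz$classes), " disease-associated enzymes")

  # -- disease_classification -----------------------------------------------
  cls <- stage_run("disease_classification", character(0), {
    types <- label_association_types(enz$union)
    categories <- categorize_diseases(enz$union, pw$annotations)
    list(types = types, categories = categories,
         report = category_report(categories))
  })
  say("disease_classification: ",
      paste(names(cls$report$counts), cls$report$counts,
            sep = "=", collapse = ", "))

  # -- root_network ---------------------------------------------------------
  net <- stage_run("root_network", character(0), {
    enz_ann <- pw$annotations[intersect(names(pw$annotations),
                                        enz$classes$accession)]
    disease_roots <- hush(map_diseases_to_roots(enz$union, enz_ann,
                                                pw$forest))
    enzyme_roots <- map_enzymes_to_roots(enz_ann, pw$forest)
    list(
      disease_roots = disease_roots, enzyme_roots = enzyme_roots,
      network = build_root_network(disease_roots),
      hist_enzymes_per_disease =
        pipeline_histogram("enzymes-per-disease", union = enz$union),
      hist_roots_per_enzyme =
        pipeline_histogram("roots-per-enzyme", enzyme_roots = enzyme_roots),
      hist_roots_per_disease =
        pipeline_histogram("roots-per-disease", disease_roots = disease_roots),
      per_root = per_root_table(disease_roots)
    )
  })
  say("root_network: ", nrow(net$network$nodes), " roots, ",
      nrow(net$network$edges), " edges")

  # -- reporting ------------------------------------------------------------
  bundle <- stage_run("reporting", character(0), {
    type_groups <- split(cls$types$accession, cls$types$association_type)
    type_groups <- type_groups[intersect(
      c("biunivocal", "univocal", "non_univocal"), names(type_groups))]
    class_groups <- split(enz$classes$accession, enz$classes$class_label)
    class_groups <- class_groups[intersect(ec_class_levels(),
                                           names(class_groups))]
    table1 <- build_summary_table(type_groups, enz$union, pw$annotations,
                                  pw$reactions, pw$forest)
    table2 <- build_summary_table(class_groups, enz$union, pw$annotations,
                                  pw$reactions, pw$forest)
    summary <- list(
      schema_version = 1L,
      n_input_records = ingest$n_input,
      n_union = nrow(ingest$union),
      n_rejects = nrow(ingest$rejects),
      n_enzymes = nrow(enz$classes),
      n_enzyme_associations = nrow(enz$union),
      n_diseases = length(unique(enz$union$disease_id)),
      association_types = as.list(table(cls$types$association_type)),
      enzyme_classes = as.list(table(enz$classes$class_label)),
      disease_categories = as.list(cls$report$counts),
      n_monogenic = cls$report$n_monogenic,
      n_polygenic = cls$report$n_polygenic,
      n_network_nodes = nrow(net$network$nodes),
      n_network_edges = nrow(net$network$edges)
    )
    structure(
      list(union = ingest$union, rejects = ingest$rejects,
           enzyme_classes = enz$classes, enzyme_union = enz$union,
           association_types = cls$types, categories = cls$categories,
           category_report = cls$report,
           disease_roots = net$disease_roots,
           enzyme_roots = net$enzyme_roots, network = net$network,
           hist_enzymes_per_disease = net$hist_enzymes_per_disease,
           hist_roots_per_enzyme = net$hist_roots_per_enzyme,
           hist_roots_per_disease = net$hist_roots_per_disease,
           per_root = net$per_root, table1 = table1, table2 = table2,
           forest = pw$forest, summary = summary),
      class = "summary_bundle"
    )
  })

  if (!is.null(config$out_dir)) {
    stage_run("reporting", character(0), {
      write_bundle_outputs(bundle, config$out_dir)
    })
    say("reporting: outputs written to ", config$out_dir)
  }
  bundle
}

#' Write every file output of a pipeline bundle
#'
#' Union set, rejects, enzyme classes and association types, disease
#' classification, the three histograms, the per-root table, the network
#' (GraphML, SIF, node/edge tables), both summary tables and the versioned
#' JSON summary. All outputs are deterministically ordered.
#'
#' @param bundle A `summary_bundle`.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, `out_dir`.
#' @export
write_bundle_outputs <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  w(bundle$union, "union.tsv")
  w(bundle$rejects, "rejects.tsv")
  w(bundle$enzyme_classes, "enzyme_classes.tsv")
  w(bundle$association_types, "enzyme_types.tsv")
  w(bundle$categories, "classification.tsv")
  w(bundle$hist_enzymes_per_disease, "hist_enzymes_per_disease.tsv")
  w(bundle$hist_roots_per_enzyme, "hist_roots_per_enzyme.tsv")
  w(bundle$hist_roots_per_disease, "hist_roots_per_disease.tsv")
  w(bundle$per_root, "per_root_table.tsv")
  write_summary_tables(bundle, out_dir)
  write_network_graphml(bundle$network,
                        file.path(out_dir, "root_network.graphml"),
                        forest = bundle$forest)
  write_network_tables(bundle$network, file.path(out_dir, "root_network"))
  jsonlite::write_json(bundle$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
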