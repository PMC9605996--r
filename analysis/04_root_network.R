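#!/usr/bin/env Rscript
# Map diseases onto the non-excluded pathway roots, tabulate the three
# standard distributions and the per-root univocality table, and build the
# root co-occurrence network (GraphML + SIF + attribute tables).

library(enzymap)

src_dir <- "results/synthetic"
dir.create("results/network", showWarnings = FALSE, recursive = TRUE)

union <- read.delim("results/union/union.tsv", colClasses = "character")
types <- read.delim("results/classify/enzyme_types.tsv",
                    colClasses = "character")
union_enz <- union[union$accession %in% types$accession, ]

forest <- load_forest(file.path(src_dir, "pathways.tsv"),
                      file.path(src_dir, "pathway_relations.tsv"))
annotations <- load_protein_pathways(file.path(src_dir, "protein2pathway.tsv"),
                                     forest)
enz_ann <- annotations[intersect(names(annotations), types$accession)]

disease_roots <- map_diseases_to_roots(union_enz, enz_ann, forest)
enzyme_roots <- map_enzymes_to_roots(enz_ann, forest)
net <- build_root_network(disease_roots)
message("root map: ", length(disease_roots), " diseases on ",
        nrow(net$nodes), " roots; ", sum(lengths(disease_roots) == 1),
        " map univocally to a single root")
message("network: ", nrow(net$edges), " realized edges of ",
        nrow(net$nodes) * (nrow(net$nodes) - 1) / 2, " possible")

w <- function(df, f) write.table(df, file.path("results/network", f),
                                 sep = "\t", quote = FALSE, row.names = FALSE)
w(pipeline_histogram("enzymes-per-disease", union = union_enz),
  "hist_enzymes_per_disease.tsv")
w(pipeline_histogram("roots-per-enzyme", enzyme_roots = enzyme_roots),
  "hist_roots_per_enzyme.tsv")
w(pipeline_histogram("roots-per-disease", disease_roots = disease_roots),
  "hist_roots_per_disease.tsv")
w(per_root_table(disease_roots), "per_root_table.tsv")
write_network_graphml(net, "results/network/root_network.graphml",
                      forest = forest)
write_network_tables(net, "results/network/root_network")
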