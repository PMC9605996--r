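#!/usr/bin/env Rscript
# Restrict the Union set to enzymes, label EC classes, association types
# (biunivocal / univocal / non-univocal) and disease categories
# (monogenic/polygenic, type A/B by leaf-pathway footprint), and emit the two
# summary tables. Consumes results/union/ and the bundle from 01.

library(enzymap)

src_dir <- "results/synthetic"
union <- read.delim("results/union/union.tsv", colClasses = "character")
dir.create("results/classify", showWarnings = FALSE, recursive = TRUE)

go <- parse_obo(file.path(src_dir, "go_mf.obo"))
records <- load_gene_records(file.path(src_dir, "gene_records.tsv"))
classes <- classify_enzymes(records, go)
union_enz <- union[union$accession %in% classes$accession, ]
classes <- classes[classes$accession %in% union_enz$accession, ]
message("enzyme filter: ", length(unique(union$accession)), " genes -> ",
        nrow(classes), " disease-associated enzymes")

forest <- load_forest(file.path(src_dir, "pathways.tsv"),
                      file.path(src_dir, "pathway_relations.tsv"))
annotations <- load_protein_pathways(file.path(src_dir, "protein2pathway.tsv"),
                                     forest)
reactions <- load_protein_reactions(file.path(src_dir, "protein2reaction.tsv"))

types <- label_association_types(union_enz)
categories <- categorize_diseases(union_enz, annotations)
rep <- category_report(categories)
message("association types: ",
        paste(names(table(types$association_type)),
              table(types$association_type), sep = "=", collapse = ", "))
message("disease categories: ",
        paste(names(rep$counts), rep$counts, sep = "=", collapse = ", "),
        " (", rep$n_monogenic, " monogenic, ", rep$n_polygenic,
        " polygenic)")

type_groups <- split(types$accession, types$association_type)
class_groups <- split(classes$accession, classes$class_label)
table1 <- build_summary_table(type_groups, union_enz, annotations,
                              reactions, forest)
table2 <- build_summary_table(class_groups, union_enz, annotations,
                              reactions, forest)

w <- function(df, f) write.table(df, file.path("results/classify", f),
                                 sep = "\t", quote = FALSE, row.names = FALSE)
w(classes, "enzyme_classes.tsv")
w(types, "enzyme_types.tsv")
w(categories, "classification.tsv")
w(table1, "table1_association_types.tsv")
w(table2, "table2_enzyme_classes.tsv")
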