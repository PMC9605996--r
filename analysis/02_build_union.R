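#!/usr/bin/env Rscript
# Ingest the three synthetic association sources, drop somatic records, and
# merge everything into the deduplicated Union set with full provenance.
# Inputs come from analysis/01_simulate.R; outputs land in results/union/.

library(enzymap)

src_dir <- "results/synthetic"
stopifnot(dir.exists(src_dir))
dir.create("results/union", showWarnings = FALSE, recursive = TRUE)

cmap <- source_column_maps()
per_source <- lapply(names(cmap), function(s)
  load_source(file.path(src_dir, paste0("source_", s, ".tsv")),
              source = s, columns = cmap[[s]]))
n_raw <- sum(vapply(per_source, nrow, integer(1)))
message("loaded ", n_raw, " raw records from ", length(per_source),
        " sources")

germline <- exclude_somatic(do.call(rbind, per_source))

records <- load_gene_records(file.path(src_dir, "gene_records.tsv"))
disease_map <- build_disease_map(parse_obo(file.path(src_dir, "diseases.obo")))
merged <- merge_union(germline, build_gene_index(records), disease_map)

message("union set: ", nrow(merged$union), " associations over ",
        length(unique(merged$union$accession)), " genes and ",
        length(unique(merged$union$disease_id)), " diseases; ",
        nrow(merged$rejects), " rejected records")

write.table(merged$union, "results/union/union.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(merged$rejects, "results/union/rejects.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
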