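#' Load one source of disease-gene associations
#'
#' Sources use different column conventions (gene given as accession or
#' symbol; disease given as OMIM/Orphanet/MONDO id or free-text name;
#' differing somatic flags), so the caller supplies a column map. One record
#' is produced per valid row; rows with a blank gene key are dropped and
#' counted.
#'
#' @param path Path to the source TSV (with header).
#' @param source Source label, one of `"uniprot"`, `"monarch"`, `"clinvar"`,
#'   `"other"`.
#' @param columns Named list mapping roles to column names: `gene`, `disease`,
#'   and optionally `somatic` plus `somatic_true` (values of the somatic
#'   column counted as somatic; default `c("somatic", "yes", "true", "1")`).
#' @return data.frame of source associations with columns `source`,
#'   `gene_key`, `disease_key`, `somatic`.
#' @details A mapped column missing from the file is a hard error.
#' @export
load_source <- function(path, source = c("uniprot", "monarch", "clinvar", "other"),
                        columns = list(gene = "gene", disease = "disease")) {
  source <- match.arg(source)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  needed <- unlist(columns[intersect(names(columns), c("gene", "disease", "somatic"))])
  missing <- setdiff(needed, names(tab))
  if (length(missing)) {
    stop("source '", source, "': mapped column(s) absent from file: ",
         paste(missing, collapse = ", "))
  }
  gene <- trimws(tab[[columns$gene]])
  disease <- trimws(tab[[columns$disease]])
  somatic <- if (!is.null(columns$somatic)) {
    truthy <- columns$somatic_true %||% c("somatic", "yes", "true", "1")
    tolower(trimws(tab[[columns$somatic]])) %in% tolower(truthy)
  } else {
    rep(FALSE, nrow(tab))
  }
  bad <- !nzchar(gene)
  if (any(bad)) {
    message("source '", source, "': dropped ", sum(bad),
            " row(s) with blank gene key")
  }
  data.frame(source = rep(source, sum(!bad)), gene_key = gene[!bad],
             disease_key = disease[!bad], somatic = somatic[!bad],
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Drop somatic association records
#'
#' Keeps exactly the records flagged germline; the number of removed somatic
#' records is reported via `message()`.
#'
#' @param records data.frame of source associations (from [load_source()]).
#' @return The germline subset, same columns.
#' @export
exclude_somatic <- function(records) {
  n_somatic <- sum(records$somatic)
  if (n_somatic > 0) message("excluded ", n_somatic, " somatic record(s)")
  records[!records$somatic, , drop = FALSE]
}

#' Build a gene lookup index from gene records
#'
#' Resolution precedence is exact accession, then primary symbol, then
#' synonym; symbol and synonym matching is case-insensitive. A key matching
#' two accessions at the same precedence level is ambiguous and rejected at
#' merge time rather than guessed.
#'
#' @param records Gene record data.frame from [load_gene_records()].
#' @return An object of class `gene_index`.
#' @export
build_gene_index <- function(records) {
  by_symbol <- split(records$accession, tolower(records$symbol))
  syn <- records$synonyms
  by_synonym <- split(rep(records$accession, lengths(syn)),
                      tolower(unlist(syn, use.names = FALSE)))
  structure(
    list(accessions = records$accession,
         by_symbol = by_symbol, by_synonym = by_synonym),
    class = "gene_index"
  )
}

resolve_gene_key <- function(key, index) {
  if (key %in% index$accessions) return(list(acc = key, reason = NULL))
  k <- tolower(key)
  hit <- unique(index$by_symbol[[k]])
  if (is.null(hit)) hit <- unique(index$by_synonym[[k]])
  if (is.null(hit)) return(list(acc = NA_character_, reason = "unresolved_gene"))
  if (length(hit) > 1L) return(list(acc = NA_character_, reason = "ambiguous_gene"))
  list(acc = hit, reason = NULL)
}

#' Merge per-source associations into the deduplicated Union set
#'
#' Gene keys are resolved to accessions through the gene index and disease
#' keys onto the canonical disease namespace through the disease map.
#' Identical (accession, canonical disease) pairs contributed by several
#' sources collapse into a single association whose `sources` field lists all
#' contributors. Records whose gene or disease key fails to resolve are
#' quarantined in the rejects report with a reason code, never silently
#' dropped.
#'
#' @param per_source A data.frame of source associations, or a list of them
#'   (one per source), already filtered with [exclude_somatic()].
#' @param gene_index A `gene_index` from [build_gene_index()].
#' @param disease_map A `disease_id_map` from [build_disease_map()].
#' @return List with
#'   \describe{
#'     \item{union}{data.frame `accession`, `disease_id`, `sources`
#'       (`;`-joined sorted source labels), sorted by accession then disease.}
#'     \item{rejects}{data.frame `source`, `gene_key`, `disease_key`,
#'       `reason` with reasons in `unresolved_gene`, `ambiguous_gene`,
#'       `unresolved_disease`, `ambiguous_disease`.}
#'     \item{n_input}{number of input records (traceability:
#'       contributing records + rejects).}
#'   }
#' @export
merge_union <- function(per_source, gene_index, disease_map) {
  if (is.data.frame(per_source)) per_source <- list(per_source)
  recs <- do.call(rbind, per_source)
  n_input <- nrow(recs)
  if (n_input == 0L) {
    return(list(
      union = data.frame(accession = character(0), disease_id = character(0),
                         sources = character(0), stringsAsFactors = FALSE),
      rejects = data.frame(source = character(0), gene_key = character(0),
                           disease_key = character(0), reason = character(0),
                           stringsAsFactors = FALSE),
      n_input = 0L
    ))
  }

  acc <- character(n_input); did <- character(n_input)
  reason <- character(n_input)
  gene_cache <- new.env(parent = emptyenv())
  dis_cache <- new.env(parent = emptyenv())
  for (i in seq_len(n_input)) {
    gk <- recs$gene_key[i]
    g <- if (!is.null(gene_cache[[gk]])) gene_cache[[gk]] else {
      r <- resolve_gene_key(gk, gene_index); gene_cache[[gk]] <- r; r
    }
    if (!is.null(g$reason)) { reason[i] <- g$reason; next }
    dk <- recs$disease_key[i]
    d <- if (!is.null(dis_cache[[dk]])) dis_cache[[dk]] else {
      r <- tryCatch(resolve_disease_id(dk, disease_map),
                    error = function(e) "AMBIGUOUS")
      dis_cache[[dk]] <- r; r
    }
    if (identical(d, "AMBIGUOUS")) { reason[i] <- "ambiguous_disease"; next }
    if (is.na(d)) { reason[i] <- "unresolved_disease"; next }
    acc[i] <- g$acc; did[i] <- d
  }

  ok <- reason == ""
  rejects <- data.frame(source = recs$source[!ok],
                        gene_key = recs$gene_key[!ok],
                        disease_key = recs$disease_key[!ok],
                        reason = reason[!ok], stringsAsFactors = FALSE)
  rejects <- rejects[order(rejects$source, rejects$gene_key,
                           rejects$disease_key), , drop = FALSE]
  rownames(rejects) <- NULL

  key <- paste(acc[ok], did[ok], sep = "\r")
  src_by_pair <- split(recs$source[ok], key)
  pairs <- do.call(rbind, strsplit(names(src_by_pair), "\r", fixed = TRUE))
  union <- data.frame(
    accession = if (length(src_by_pair)) pairs[, 1] else character(0),
    disease_id = if (length(src_by_pair)) pairs[, 2] else character(0),
    sources = vapply(src_by_pair, function(s)
      paste(sort(unique(s)), collapse = ";"), character(1)),
    stringsAsFactors = FALSE
  )
  union <- union[order(union$accession, union$disease_id), , drop = FALSE]
  rownames(union) <- NULL
  list(union = union, rejects = rejects, n_input = n_input)
}
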