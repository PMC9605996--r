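#' Load the gene record table
#'
#' Tab-separated with header and columns `accession`, `symbol`, `synonyms`,
#' `ec_numbers`, `go_mf_terms`; the last three are `;`-joined lists.
#'
#' @param path Path to the gene record TSV.
#' @return data.frame with list-columns `synonyms`, `ec_numbers`,
#'   `go_mf_terms`.
#' @export
load_gene_records <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE, colClasses = "character")
  needed <- c("accession", "symbol", "synonyms", "ec_numbers", "go_mf_terms")
  missing <- setdiff(needed, names(tab))
  if (length(missing)) stop("gene record table missing column(s): ",
                            paste(missing, collapse = ", "))
  split_col <- function(x) lapply(strsplit(x, ";", fixed = TRUE),
                                  function(v) v[nzchar(trimws(v))])
  out <- data.frame(accession = tab$accession, symbol = tab$symbol,
                    stringsAsFactors = FALSE)
  out$synonyms <- split_col(tab$synonyms)
  out$ec_numbers <- split_col(tab$ec_numbers)
  out$go_mf_terms <- split_col(tab$go_mf_terms)
  out
}

#' The catalytic-activity term set of a molecular-function ontology
#'
#' Descendants of the catalytic activity term (GO:0003824) plus the term
#' itself: a protein annotated directly with catalytic activity qualifies as
#' an enzyme.
#'
#' @param go An `ontology_graph` for the molecular-function ontology.
#' @param catalytic_root The catalytic activity term id.
#' @return Character vector of term ids.
#' @export
catalytic_terms <- function(go, catalytic_root = "GO:0003824") {
  c(catalytic_root, descendants(go, catalytic_root))
}

#' Is a gene record an enzyme?
#'
#' True iff the record carries at least one EC number, or one of its GO
#' molecular-function terms lies in the catalytic-activity subtree
#' (self-inclusive).
#'
#' @param record One row of the gene record table (data.frame or list with
#'   `ec_numbers` and `go_mf_terms`).
#' @param go An `ontology_graph` containing GO:0003824, or a precomputed
#'   character vector from [catalytic_terms()].
#' @return Logical scalar.
#' @export
is_enzyme <- function(record, go) {
  cat_set <- if (inherits(go, "ontology_graph")) catalytic_terms(go) else go
  ec <- unlist(record$ec_numbers, use.names = FALSE)
  mf <- unlist(record$go_mf_terms, use.names = FALSE)
  length(ec) > 0 || any(mf %in% cat_set)
}

#' EC level-1 classes of a gene record
#'
#' Distinct first fields (1-7) of all EC strings, full or partial
#' (`"3.-.-.-"` contributes class 3). An unparseable EC string raises a
#' warning and is skipped.
#'
#' @param record One gene record row, or a character vector of EC strings.
#' @return Sorted integer vector (possibly empty).
#' @export
ec_level1_classes <- function(record) {
  ec <- if (is.character(record)) record else
    unlist(record$ec_numbers, use.names = FALSE)
  if (!length(ec)) return(integer(0))
  ok <- grepl("^[1-7]\\.([0-9]+|-)\\.([0-9]+|-)\\.([0-9]+|-)$", ec) |
    grepl("^[1-7]$", ec)
  if (any(!ok)) {
    warning("skipping unparseable EC string(s): ",
            paste(ec[!ok], collapse = ", "))
  }
  sort(unique(as.integer(substr(ec[ok], 1, 1))))
}

#' Assign the enzyme-class label of Table-2 style reports
#'
#' One EC level-1 class gives `EC1` ... `EC7`; two or more give `Multiclass`;
#' none (a GO-only enzyme annotated under catalytic activity) gives
#' `WithoutEC`. Calling this on a non-enzyme is an error.
#'
#' @inheritParams is_enzyme
#' @return One of `"EC1"` ... `"EC7"`, `"Multiclass"`, `"WithoutEC"`.
#' @export
assign_class_label <- function(record, go) {
  if (!is_enzyme(record, go)) stop("assign_class_label called on a non-enzyme")
  classes <- ec_level1_classes(record)
  if (length(classes) == 0L) return("WithoutEC")
  if (length(classes) >= 2L) return("Multiclass")
  paste0("EC", classes)
}

#' All nine enzyme-class labels in report order
#' @return Character vector: EC1..EC7 (oxidoreductases through translocases),
#'   Multiclass, WithoutEC.
#' @export
ec_class_levels <- function() {
  c(paste0("EC", 1:7), "Multiclass", "WithoutEC")
}

#' Restrict gene records to enzymes and label their EC classes
#'
#' @param records Gene record data.frame from [load_gene_records()].
#' @param go An `ontology_graph` (or precomputed catalytic term set).
#' @return data.frame `accession`, `class_label` for the enzyme subset.
#' @export
classify_enzymes <- function(records, go) {
  cat_set <- if (inherits(go, "ontology_graph")) catalytic_terms(go) else go
  keep <- vapply(seq_len(nrow(records)), function(i)
    is_enzyme(records[i, ], cat_set), logical(1))
  enz <- records[keep, , drop = FALSE]
  data.frame(
    accession = enz$accession,
    class_label = vapply(seq_len(nrow(enz)), function(i)
      assign_class_label(enz[i, ], cat_set), character(1)),
    stringsAsFactors = FALSE
  )
}
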