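#' Label enzyme-disease association types
#'
#' Each enzyme in the union set gets exactly one label: `biunivocal` (one
#' disease, and that disease has no other enzyme), `univocal` (one disease
#' that is also associated with other enzymes) or `non_univocal` (two or more
#' diseases). The labels partition the enzyme set. Note the disease-level
#' tallies derived from these labels may overlap: the same disease can appear
#' under several association types.
#'
#' @param union Union-set data.frame (`accession`, `disease_id`), restricted
#'   to enzymes.
#' @param enzymes Optional character vector of enzyme accessions expected in
#'   the union; members with zero associations are excluded from labeling
#'   with a warning.
#' @return data.frame `accession`, `association_type`, sorted by accession.
#' @export
label_association_types <- function(union, enzymes = NULL) {
  if (!is.null(enzymes)) {
    absent <- setdiff(enzymes, union$accession)
    if (length(absent)) {
      warning(length(absent),
              " enzyme(s) with no disease association excluded from labeling")
    }
  }
  n_dis <- table(union$accession)
  n_enz <- table(union$disease_id)
  acc <- sort(unique(union$accession))
  type <- vapply(acc, function(a) {
    if (n_dis[[a]] >= 2L) return("non_univocal")
    d <- union$disease_id[union$accession == a]
    if (n_enz[[d]] == 1L) "biunivocal" else "univocal"
  }, character(1))
  data.frame(accession = acc, association_type = unname(type),
             stringsAsFactors = FALSE)
}

#' Categorize one disease by its enzymes' leaf-pathway footprint
#'
#' Let P be the union of annotated leaf pathways over the disease's enzymes
#' that carry any pathway annotation. A disease with empty P (no annotated
#' enzyme at all) is `excluded`. Otherwise it is monogenic (one enzyme) or
#' polygenic (two or more), type A when |P| = 1 and type B when |P| >= 2; a
#' disease mixing annotated and unannotated enzymes is categorized on its
#' annotated enzymes.
#'
#' @param disease_id Canonical disease id.
#' @param enzymes Non-empty character vector of the disease's enzyme
#'   accessions.
#' @param annotations Named list accession -> character vector of annotated
#'   (leaf) pathway ids, as from [load_protein_pathways()].
#' @return List with `disease_id`, `category` (one of `monogenic_A`,
#'   `monogenic_B`, `polygenic_A`, `polygenic_B`, `excluded`), `n_enzymes`,
#'   `n_leaf_pathways`, `enzymes`.
#' @export
categorize_disease <- function(disease_id, enzymes, annotations) {
  stopifnot(length(enzymes) > 0)
  P <- unique(unlist(annotations[enzymes], use.names = FALSE))
  n_enz <- length(unique(enzymes))
  if (length(P) == 0L) {
    category <- "excluded"
  } else {
    arity <- if (n_enz == 1L) "monogenic" else "polygenic"
    breadth <- if (length(P) == 1L) "A" else "B"
    category <- paste(arity, breadth, sep = "_")
  }
  list(disease_id = disease_id, category = category, n_enzymes = n_enz,
       n_leaf_pathways = length(P), enzymes = sort(unique(enzymes)))
}

#' Categorize every disease of an enzyme-restricted union set
#'
#' @param union Union-set data.frame restricted to enzymes.
#' @param annotations Named list accession -> annotated pathway ids.
#' @return data.frame `disease_id`, `category`, `n_enzymes`,
#'   `n_leaf_pathways`, `enzymes` (`;`-joined), sorted by disease id.
#' @export
categorize_diseases <- function(union, annotations) {
  by_dis <- split(union$accession, union$disease_id)
  rows <- lapply(sort(names(by_dis)), function(d) {
    c <- categorize_disease(d, by_dis[[d]], annotations)
    data.frame(disease_id = c$disease_id, category = c$category,
               n_enzymes = c$n_enzymes, n_leaf_pathways = c$n_leaf_pathways,
               enzymes = paste(c$enzymes, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(disease_id = character(0), category = character(0),
                      n_enzymes = integer(0), n_leaf_pathways = integer(0),
                      enzymes = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' All disease category labels in report order
#' @return Character vector of the five categories.
#' @export
disease_category_levels <- function() {
  c("monogenic_A", "monogenic_B", "polygenic_A", "polygenic_B", "excluded")
}

#' Per-category disease counts and membership lists
#'
#' Counts always cover all five categories (zero-filled) and sum to the total
#' number of diseases; monogenic_A + monogenic_B + excluded monogenic
#' reproduces the monogenic total.
#'
#' @param categories data.frame from [categorize_diseases()].
#' @return List with `counts` (named integer vector over
#'   [disease_category_levels()]), `total`, `n_monogenic`, `n_polygenic`, and
#'   `members` (named list of disease ids per category).
#' @export
category_report <- function(categories) {
  lv <- disease_category_levels()
  f <- factor(categories$category, levels = lv)
  counts <- table(f)
  members <- split(categories$disease_id, f)
  list(
    counts = stats::setNames(as.integer(counts), lv),
    total = nrow(categories),
    n_monogenic = sum(categories$n_enzymes == 1L),
    n_polygenic = sum(categories$n_enzymes >= 2L),
    members = lapply(members, sort)
  )
}
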