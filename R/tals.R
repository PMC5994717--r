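# Transposon-associated locus (TAL) classification from functional labels,
# TAL family clustering (shared similarity/MCL machinery) and per-replicon
# TAL statistics.

#' Default transposable-element vocabulary
#'
#' Lowercase substrings covering the usual transposase / integrase /
#' recombinase / phage-integrase / IS-family annotation categories. A fuller
#' category list can be loaded with [read_tal_vocabulary()].
#'
#' @return Character vector of match terms.
#' @export
default_tal_vocabulary <- function() {
  c("transposase", "integrase", "recombinase", "transposon",
    "insertion sequence", "is family", "phage integrase")
}

#' Read a TAL vocabulary file
#'
#' One term per line; `#` starts a comment; blank lines ignored.
#'
#' @param path Path to the vocabulary file.
#' @return Character vector of lowercase terms.
#' @export
read_tal_vocabulary <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- stringr::str_trim(sub("#.*$", "", lines))
  terms <- tolower(lines[lines != ""])
  assert_that(length(terms) > 0, "vocabulary is empty")
  terms
}

#' Flag transposon-associated loci
#'
#' A gene is flagged iff any of its functional labels contains any
#' vocabulary term (case-insensitive substring match). Genes without labels
#' are never flagged; their count is attached as attribute
#' `n_no_annotation`.
#'
#' @param genes Gene tibble with a `labels` list column.
#' @param vocabulary Character vector of terms
#'   (default [default_tal_vocabulary()]).
#' @return Character vector of flagged gene ids, with attribute
#'   `n_no_annotation`.
#' @export
flag_tals <- function(genes, vocabulary = default_tal_vocabulary()) {
  assert_that(length(vocabulary) > 0, "vocabulary must be non-empty")
  vocabulary <- tolower(vocabulary)
  labs <- genes$labels
  n_unlab <- sum(vapply(labs, length, integer(1)) == 0)
  flagged <- vapply(labs, function(l) {
    if (length(l) == 0) return(FALSE)
    l <- tolower(l)
    any(vapply(vocabulary, function(term) {
      any(stringr::str_detect(l, stringr::fixed(term)))
    }, logical(1)))
  }, logical(1))
  structure(genes$gene_id[flagged], n_no_annotation = n_unlab)
}

#' Cluster TAL genes into families
#'
#' Restricts the gene table to flagged TALs and reuses
#' [pairwise_similarity()] + [mcl_cluster()]; family ids carry a `TAL`
#' prefix.
#'
#' @param genes Gene tibble.
#' @param tal_ids Flagged gene ids from [flag_tals()].
#' @param inflation MCL inflation (default 10, as for gene families).
#' @inheritParams pairwise_similarity
#' @return Family tibble `family_id`, `gene_id`, `strain_id`, `rep_class`,
#'   `replicon_id`.
#' @export
cluster_tals <- function(genes, tal_ids, kmer_size = 5, min_identity = 0.80,
                         min_coverage = 0.80, inflation = 10) {
  sub <- genes[genes$gene_id %in% tal_ids, , drop = FALSE]
  if (nrow(sub) == 0) {
    return(tibble::tibble(family_id = character(0), gene_id = character(0),
                          strain_id = character(0), rep_class = character(0),
                          replicon_id = character(0)))
  }
  fams <- cluster_genes(sub, kmer_size, min_identity, min_coverage, inflation)
  fams$family_id <- sub("^F", "TAL", fams$family_id)
  fams
}

#' Per-replicon TAL statistics
#'
#' Same density/spectrum contracts as [re_statistics()] (TAL genes are the
#' instances), plus a replicon-exclusivity table: for each TAL family, the
#' number of replicon classes it occurs on (accessory plasmids counted as a
#' single class when `accessory_as_class`).
#'
#' @param tal_families TAL family tibble from [cluster_tals()].
#' @param replicons Replicon tibble.
#' @param strain_exclusions Strains dropped from the statistics.
#' @param accessory_as_class Count accessory plasmids as one replicon class.
#' @return List of tibbles: `replicon_density`, `class_summary`,
#'   `family_counts`, `spectrum`, `exclusivity` (`family_id`, `classes`,
#'   `n_classes`) and `exclusivity_counts` (`n_classes`, `n_families`).
#' @export
tal_statistics <- function(tal_families, replicons,
                           strain_exclusions = character(0),
                           accessory_as_class = TRUE) {
  stats <- re_statistics(
    dplyr::rename(tal_families[, c("family_id", "replicon_id")],
                  replicon_id = "replicon_id"),
    replicons, strain_exclusions
  )
  fams <- tal_families[!tal_families$strain_id %in% strain_exclusions, ,
                       drop = FALSE]
  if (!accessory_as_class) {
    fams <- fams[fams$rep_class %in% MAIN_CLASSES, , drop = FALSE]
  }
  excl <- dplyr::summarise(
    dplyr::group_by(fams, .data$family_id),
    classes = paste(sort(unique(.data$rep_class)), collapse = "+"),
    n_classes = dplyr::n_distinct(.data$rep_class), .groups = "drop"
  )
  excl_counts <- dplyr::count(excl, .data$n_classes, name = "n_families")
  c(stats, list(exclusivity = excl, exclusivity_counts = excl_counts))
}
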