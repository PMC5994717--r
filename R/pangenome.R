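# Core/pan-genome structure: counts, rarefaction-style curves, per-replicon
# core sets, per-strain percent-core and accessory-plasmid gene sharing.

#' Core and pan family counts for a strain subset
#'
#' Core = families with at least one member in every strain of the subset;
#' pan = families with a member in any strain of the subset.
#'
#' @param families Family tibble (`family_id`, `strain_id`).
#' @param strain_subset Non-empty character vector of strain ids.
#' @return Tibble with one row: `core`, `pan`.
#' @export
core_pan_counts <- function(families, strain_subset) {
  assert_that(length(strain_subset) > 0, "strain_subset must be non-empty")
  known <- unique(families$strain_id)
  missing <- setdiff(strain_subset, known)
  assert_that(length(missing) == 0,
              paste0("unknown strain(s): ", paste(missing, collapse = ", ")))
  sub <- families[families$strain_id %in% strain_subset, , drop = FALSE]
  per_fam <- dplyr::summarise(
    dplyr::group_by(sub, .data$family_id),
    n_strains = dplyr::n_distinct(.data$strain_id), .groups = "drop"
  )
  tibble::tibble(
    core = sum(per_fam$n_strains == length(strain_subset)),
    pan = nrow(per_fam)
  )
}

#' Core/pan-genome curves over strain subsets
#'
#' For each subset size, evaluates [core_pan_counts()] on every subset when
#' the total number of subsets of that size is at most `max_enumeration`,
#' otherwise on `max_enumeration` subsets sampled uniformly without
#' replacement. Deterministic given `seed`.
#'
#' @param families Family tibble.
#' @param strains Strains to draw subsets from; defaults to all.
#' @param max_enumeration Cap on subsets evaluated per size.
#' @param seed Integer seed for the sampled regime.
#' @return Tibble `subset_size`, `replicate`, `core`, `pan`.
#' @export
core_pan_curve <- function(families, strains = NULL, max_enumeration = 200,
                           seed = 1) {
  strains <- strains %||% sort(unique(families$strain_id))
  n <- length(strains)
  with_seed(seed, {
    out <- list()
    for (k in seq_len(n)) {
      total <- choose(n, k)
      subsets <- if (total <= max_enumeration) {
        utils::combn(strains, k, simplify = FALSE)
      } else {
        lapply(seq_len(max_enumeration), function(i) sample(strains, k))
      }
      counts <- purrr::map_dfr(subsets, function(ss) {
        core_pan_counts(families, ss)
      })
      out[[k]] <- tibble::tibble(
        subset_size = k, replicate = seq_along(subsets),
        core = counts$core, pan = counts$pan
      )
    }
    dplyr::bind_rows(out)
  })
}

#' Core-replicon family set
#'
#' Families having at least one member on replicon class `rep_class` in
#' every non-excluded strain.
#'
#' @param families Family tibble (`family_id`, `strain_id`, `rep_class`).
#' @param rep_class Replicon class.
#' @param strain_exclusions Strains to drop before the all-strains test
#'   (e.g. strains carrying large translocations).
#' @return Character vector of family ids.
#' @export
core_replicon <- function(families, rep_class, strain_exclusions = character(0)) {
  keep <- setdiff(unique(families$strain_id), strain_exclusions)
  sub <- families[families$strain_id %in% keep &
                    families$rep_class == rep_class, , drop = FALSE]
  per_fam <- dplyr::summarise(
    dplyr::group_by(sub, .data$family_id),
    n_strains = dplyr::n_distinct(.data$strain_id), .groups = "drop"
  )
  sort(per_fam$family_id[per_fam$n_strains == length(keep)])
}

#' Per-strain fraction of genes on a replicon class that are core
#'
#' For each strain: genes on `rep_class` whose family is in the genome core
#' (all strains), divided by all genes on `rep_class`. Gene counts, not
#' family counts. Strains whose replicon of that class carries no genes are
#' reported as `NA`.
#'
#' @param families Family tibble (`family_id`, `gene_id`, `strain_id`,
#'   `rep_class`).
#' @param rep_class Replicon class.
#' @return Tibble `strain_id`, `n_genes`, `n_core_genes`, `fraction_core`.
#' @export
percent_core <- function(families, rep_class) {
  strains <- sort(unique(families$strain_id))
  core_ids <- core_genome_families(families)
  sub <- families[families$rep_class == rep_class, , drop = FALSE]
  out <- dplyr::summarise(
    dplyr::group_by(sub, .data$strain_id),
    n_genes = dplyr::n(),
    n_core_genes = sum(.data$family_id %in% core_ids),
    .groups = "drop"
  )
  out <- dplyr::left_join(tibble::tibble(strain_id = strains), out,
                          by = "strain_id")
  out$n_genes[is.na(out$n_genes)] <- 0L
  out$n_core_genes[is.na(out$n_core_genes)] <- 0L
  out$fraction_core <- ifelse(out$n_genes == 0, NA_real_,
                              out$n_core_genes / out$n_genes)
  out
}

# Families present in every strain.
core_genome_families <- function(families, strain_exclusions = character(0)) {
  keep <- setdiff(unique(families$strain_id), strain_exclusions)
  sub <- families[families$strain_id %in% keep, , drop = FALSE]
  per_fam <- dplyr::summarise(
    dplyr::group_by(sub, .data$family_id),
    n_strains = dplyr::n_distinct(.data$strain_id), .groups = "drop"
  )
  sort(per_fam$family_id[per_fam$n_strains == length(keep)])
}

#' Classify accessory-plasmid genes by main-replicon sharing
#'
#' Each gene on an accessory plasmid is assigned to the main replicon class
#' pattern of its family elsewhere in the population: exclusive to one main
#' pan-replicon, found on multiple main classes, or unclassified when the
#' family has no member on any main replicon. Accessory plasmids are treated
#' as a single replicon class throughout.
#'
#' @param families Family tibble (`family_id`, `gene_id`, `strain_id`,
#'   `rep_class`, `replicon_id`).
#' @param accessory_replicon Replicon id of the accessory plasmid to
#'   classify, or `NULL` for all accessory genes pooled per replicon.
#' @return Tibble per accessory replicon: `replicon_id`, `total_genes`,
#'   `chromosome_exclusive`, `pSymA_exclusive`, `pSymB_exclusive`,
#'   `multiple`, `unclassified`.
#' @export
classify_accessory_genes <- function(families, accessory_replicon = NULL) {
  acc <- families[families$rep_class == "accessory", , drop = FALSE]
  if (!is.null(accessory_replicon)) {
    acc <- acc[acc$replicon_id %in% accessory_replicon, , drop = FALSE]
  }
  main <- families[families$rep_class %in% MAIN_CLASSES, , drop = FALSE]
  fam_classes <- dplyr::summarise(
    dplyr::group_by(main, .data$family_id),
    classes = list(sort(unique(.data$rep_class))), .groups = "drop"
  )
  class_of <- stats::setNames(fam_classes$classes, fam_classes$family_id)
  cat_of <- vapply(acc$family_id, function(f) {
    cl <- class_of[[f]]
    if (is.null(cl) || length(cl) == 0) return("unclassified")
    if (length(cl) > 1) return("multiple")
    paste0(cl, "_exclusive")
  }, character(1))
  acc$category <- unname(cat_of)
  lvls <- c("chromosome_exclusive", "pSymA_exclusive", "pSymB_exclusive",
            "multiple", "unclassified")
  out <- dplyr::count(acc, .data$replicon_id, .data$category)
  out <- tidyr::pivot_wider(out, names_from = "category",
                            values_from = "n", values_fill = 0L)
  for (l in lvls) if (!l %in% names(out)) out[[l]] <- 0L
  totals <- dplyr::count(acc, .data$replicon_id, name = "total_genes")
  out <- dplyr::left_join(totals, out, by = "replicon_id")
  out[, c("replicon_id", "total_genes", lvls)]
}
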