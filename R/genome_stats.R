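# Replicon-level summary tables and G+C hypothesis tests.

#' Per-class replicon summary table
#'
#' Means and ranges across strains per replicon class: size (Mb), gene
#' count, fraction of genes in genome-core families, G+C (mol%), and, when
#' supplied, repeat-instance and TAL densities per Mb and family counts.
#'
#' @param genomes Genome list (`replicons`, `genes` tibbles).
#' @param families Gene-family tibble.
#' @param re_instances Optional resolved repeat instances.
#' @param tal_families Optional TAL family tibble.
#' @param strain_exclusions Strains dropped from the summary.
#' @return Tidy tibble `rep_class`, `metric`, `mean`, `min`, `max`
#'   (family-count metrics have `mean = min = max = count`).
#' @export
replicon_summary <- function(genomes, families, re_instances = NULL,
                             tal_families = NULL,
                             strain_exclusions = character(0)) {
  reps <- genomes$replicons
  reps <- reps[!reps$strain_id %in% strain_exclusions, , drop = FALSE]
  fams <- families[!families$strain_id %in% strain_exclusions, , drop = FALSE]
  per_rep <- tibble::tibble(
    replicon_id = reps$replicon_id, strain_id = reps$strain_id,
    rep_class = reps$rep_class,
    size_mb = reps$length_bp / 1e6,
    gc_molpct = 100 * gc_content(reps$sequence)
  )
  gene_counts <- dplyr::count(fams, .data$replicon_id, name = "n_genes")
  per_rep <- dplyr::left_join(per_rep, gene_counts, by = "replicon_id")
  per_rep$n_genes[is.na(per_rep$n_genes)] <- 0L
  core_ids <- core_genome_families(fams)
  core_counts <- dplyr::count(
    fams[fams$family_id %in% core_ids, , drop = FALSE],
    .data$replicon_id, name = "n_core"
  )
  per_rep <- dplyr::left_join(per_rep, core_counts, by = "replicon_id")
  per_rep$n_core[is.na(per_rep$n_core)] <- 0L
  per_rep$fraction_core <- ifelse(per_rep$n_genes == 0, NA_real_,
                                  per_rep$n_core / per_rep$n_genes)
  long <- tidyr::pivot_longer(
    per_rep[, c("rep_class", "size_mb", "n_genes", "fraction_core",
                "gc_molpct")],
    -"rep_class", names_to = "metric", values_to = "value"
  )
  add_density <- function(long, tbl, label) {
    if (is.null(tbl)) return(long)
    st <- re_statistics(tbl, reps, strain_exclusions)
    dens <- tidyr::pivot_longer(
      st$replicon_density[, c("rep_class", "per_mb")],
      -"rep_class", names_to = "metric", values_to = "value"
    )
    dens$metric <- paste0(label, "_per_mb")
    dplyr::bind_rows(long, dens)
  }
  long <- add_density(long, re_instances, "re")
  if (!is.null(tal_families)) {
    long <- add_density(long, tal_families[, c("replicon_id", "family_id")],
                        "tal")
  }
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$rep_class, .data$metric),
    mean = mean(.data$value, na.rm = TRUE),
    min = suppressWarnings(min(.data$value, na.rm = TRUE)),
    max = suppressWarnings(max(.data$value, na.rm = TRUE)),
    .groups = "drop"
  )
  fam_counts <- function(tbl, label) {
    if (is.null(tbl)) return(NULL)
    inst <- dplyr::inner_join(tbl, reps[, c("replicon_id", "rep_class")],
                              by = "replicon_id")
    fc <- dplyr::summarise(
      dplyr::group_by(inst, .data$rep_class),
      mean = dplyr::n_distinct(.data$family_id), .groups = "drop"
    )
    fc$metric <- paste0(label, "_families")
    fc$min <- fc$mean
    fc$max <- fc$mean
    fc
  }
  out <- dplyr::bind_rows(
    out,
    fam_counts(re_instances, "re"),
    fam_counts(if (is.null(tal_families)) NULL else
      tal_families[, c("replicon_id", "family_id")], "tal")
  )
  dplyr::arrange(out, .data$rep_class, .data$metric)
}

#' Pairwise G+C hypothesis tests and per-class variances
#'
#' Per-strain replicon G+C values (mol%): paired two-sided t-tests for each
#' pair of main classes (pairing by strain, Bonferroni factor 3), unpaired
#' Welch tests of each main class against the accessory plasmids, and
#' per-class variances of per-replicon G+C (population and sample forms;
#' `main` is the mean within-class population variance of the three main
#' classes).
#'
#' @param genomes Genome list with a `replicons` tibble.
#' @param strain_exclusions Strains dropped before testing.
#' @return List: `tests` tibble (`class_a`, `class_b`, `method`, `t`, `df`,
#'   `p_raw`, `p_bonferroni`, `zero_difference`) and `variances` tibble
#'   (`rep_class`, `n`, `var_population`, `var_sample`).
#' @export
gc_tests <- function(genomes, strain_exclusions = character(0)) {
  reps <- genomes$replicons
  reps <- reps[!reps$strain_id %in% strain_exclusions, , drop = FALSE]
  gc <- tibble::tibble(
    strain_id = reps$strain_id, rep_class = reps$rep_class,
    gc_molpct = 100 * gc_content(reps$sequence)
  )
  main <- gc[gc$rep_class %in% MAIN_CLASSES, , drop = FALSE]
  strains <- sort(unique(main$strain_id))
  assert_that(length(strains) >= 3,
              "insufficient data: need >= 3 strains for G+C tests")
  wide <- tidyr::pivot_wider(main, names_from = "rep_class",
                             values_from = "gc_molpct")
  pairs <- utils::combn(MAIN_CLASSES, 2, simplify = FALSE)
  tests <- purrr::map_dfr(pairs, function(pr) {
    x <- wide[[pr[1]]]; y <- wide[[pr[2]]]
    d <- x - y
    if (stats::sd(d) == 0) {
      return(tibble::tibble(class_a = pr[1], class_b = pr[2],
                            method = "paired t", t = NA_real_,
                            df = NA_real_, p_raw = 1, p_bonferroni = 1,
                            zero_difference = TRUE))
    }
    tt <- stats::t.test(x, y, paired = TRUE)
    tibble::tibble(class_a = pr[1], class_b = pr[2], method = "paired t",
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p_raw = tt$p.value,
                   p_bonferroni = min(1, 3 * tt$p.value),
                   zero_difference = FALSE)
  })
  acc <- gc[gc$rep_class == "accessory", , drop = FALSE]
  if (nrow(acc) >= 3) {
    welch <- purrr::map_dfr(MAIN_CLASSES, function(cls) {
      tt <- stats::t.test(gc$gc_molpct[gc$rep_class == cls], acc$gc_molpct)
      tibble::tibble(class_a = cls, class_b = "accessory",
                     method = "Welch t", t = unname(tt$statistic),
                     df = unname(tt$parameter), p_raw = tt$p.value,
                     p_bonferroni = min(1, 3 * tt$p.value),
                     zero_difference = FALSE)
    })
    tests <- dplyr::bind_rows(tests, welch)
  }
  var_pop <- function(x) mean((x - mean(x))^2)
  variances <- dplyr::summarise(
    dplyr::group_by(gc, .data$rep_class),
    n = dplyr::n(),
    var_population = var_pop(.data$gc_molpct),
    var_sample = stats::var(.data$gc_molpct),
    .groups = "drop"
  )
  main_var <- mean(variances$var_population[
    variances$rep_class %in% MAIN_CLASSES
  ])
  variances <- dplyr::bind_rows(
    variances,
    tibble::tibble(rep_class = "main", n = sum(gc$rep_class %in% MAIN_CLASSES),
                   var_population = main_var, var_sample = NA_real_)
  )
  list(tests = tests, variances = variances)
}
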