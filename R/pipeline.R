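# End-to-end orchestration: simulate (or load) -> cluster -> pangenome ->
# repeats/TALs -> movement -> divergence -> report, with stage caching keyed
# on the configuration and a plain-text run log. All outputs are TSV / FASTA
# / Newick text files, byte-identical for identical configs and seeds.

#' Default pipeline configuration
#'
#' @param outdir Output directory.
#' @param seed Master seed; every stage derives its own seed from it.
#' @return Named list of configuration values (flat key/value document).
#' @export
pipeline_config <- function(outdir = "panreplicon_out", seed = 1) {
  list(
    outdir = outdir, seed = seed,
    # simulate
    n_strains = 3, n_families = 60, core_fraction = 0.7,
    mutation_rate = 0.01, n_accessory_min = 1, n_accessory_max = 1,
    chromosome_bp = 6e4, pSymA_bp = 5e4, pSymB_bp = 5e4, accessory_bp = 2e4,
    n_repeat_families = 2, repeat_length = 300, repeat_copies = 3,
    repeat_divergence = 0.02, n_gene_moves = 1,
    # clustering
    kmer_size = 5, min_identity = 0.8, min_coverage = 0.8, inflation = 10,
    # repeats
    re_min_length = 65, re_inflation = 2, re_min_coverage = 0.5,
    evalue_cutoff = 1e-4,
    # movement / synteny
    anchor_min_len = 65, max_gap = 1e4, min_block_len = 5e3,
    min_block_identity = 0.9, min_span = 2e4,
    # divergence
    n_perm = 999
  )
}

stage_key <- function(config, stage, extra = NULL) {
  dat <- paste(stage, paste(names(config), unlist(config), collapse = ";"),
               paste(unlist(extra), collapse = ";"), sep = "|")
  tmp <- tempfile()
  writeLines(dat, tmp)
  key <- unname(tools::md5sum(tmp))
  unlink(tmp)
  key
}

stage_cached <- function(outdir, stage, key, outputs) {
  keyfile <- file.path(outdir, paste0(".stage_", stage, ".key"))
  file.exists(keyfile) && identical(readLines(keyfile, warn = FALSE), key) &&
    all(file.exists(file.path(outdir, outputs)))
}

stage_done <- function(outdir, stage, key) {
  writeLines(key, file.path(outdir, paste0(".stage_", stage, ".key")))
}

log_line <- function(outdir, ...) {
  cat(paste0(sprintf(...), "\n"), file = file.path(outdir, "run.log"),
      append = TRUE)
}

#' Run the full comparative pipeline
#'
#' Executes simulate -> cluster -> pangenome -> repeats -> tals -> movement
#' -> divergence -> report in dependency order, writing TSV/FASTA/Newick
#' reports under `config$outdir`. Stages whose configuration key matches a
#' previous run (and whose outputs exist) are skipped; `force` reruns
#' everything. Identical configs and seeds give byte-identical outputs.
#'
#' @param config Configuration list from [pipeline_config()] (or a YAML file
#'   path readable by `yaml::read_yaml`).
#' @param force Rerun all stages even when cached.
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), force = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  writeLines(yaml::as.yaml(config), file.path(outdir, "config.yaml"))
  res <- list()

  # -- simulate ---------------------------------------------------------------
  key <- stage_key(config, "simulate")
  sim <- NULL
  run_sim <- function() {
    sim <- generate_strain_set(
      pan_genome_spec(n_families = config$n_families,
                      core_fraction = config$core_fraction),
      n_strains = config$n_strains,
      mutation_rate = config$mutation_rate,
      replicon_sizes = c(chromosome = config$chromosome_bp,
                         pSymA = config$pSymA_bp, pSymB = config$pSymB_bp,
                         accessory = config$accessory_bp),
      n_accessory_range = c(config$n_accessory_min, config$n_accessory_max),
      seed = child_seed(config$seed, 1)
    )
    if (config$n_repeat_families > 0) {
      for (k in seq_len(config$n_repeat_families)) {
        sim <- plant_repeat_family(
          sim, consensus_length = config$repeat_length,
          copies_per_strain = config$repeat_copies,
          divergence = config$repeat_divergence,
          seed = child_seed(config$seed, 10 + k)
        )
      }
    }
    if (config$n_gene_moves > 0) {
      moves <- list(c("chromosome", "pSymB"), c("pSymB", "pSymA"),
                    c("pSymA", "pSymB"))
      strains <- sprintf("S%02d", seq_len(config$n_strains))
      for (k in seq_len(config$n_gene_moves)) {
        mv <- moves[[(k - 1) %% length(moves) + 1]]
        sim <- plant_gene_move(sim, strains[(k - 1) %% length(strains) + 1],
                               mv[1], mv[2],
                               seed = child_seed(config$seed, 20 + k))
      }
    }
    sim
  }
  simdir <- file.path(outdir, "genomes")
  if (force || !stage_cached(outdir, "simulate", key, "genomes/families.tsv")) {
    sim <- run_sim()
    write_strain_set(sim, simdir)
    stage_done(outdir, "simulate", key)
    log_line(outdir, "stage simulate: %d strains, seed %d",
             config$n_strains, config$seed)
  } else {
    sim <- run_sim()  # cheap relative to downstream; cache keeps files stable
    log_line(outdir, "stage simulate: cached")
  }
  res$sim <- sim
  genomes <- sim$genomes

  # -- cluster ----------------------------------------------------------------
  key <- stage_key(config, "cluster")
  fam_path <- file.path(outdir, "gene_families.tsv")
  if (force || !stage_cached(outdir, "cluster", key, "gene_families.tsv")) {
    families <- cluster_genes(genomes$genes, config$kmer_size,
                              config$min_identity, config$min_coverage,
                              config$inflation)
    readr::write_tsv(families, fam_path)
    stage_done(outdir, "cluster", key)
    log_line(outdir, "stage cluster: %d families",
             dplyr::n_distinct(families$family_id))
  } else {
    families <- readr::read_tsv(fam_path, show_col_types = FALSE)
    log_line(outdir, "stage cluster: cached")
  }
  res$families <- families

  # -- pangenome --------------------------------------------------------------
  key <- stage_key(config, "pangenome")
  outs <- c("core_pan_curve.tsv", "percent_core.tsv", "accessory_sharing.tsv")
  if (force || !stage_cached(outdir, "pangenome", key, outs)) {
    curve <- core_pan_curve(families, seed = child_seed(config$seed, 2))
    readr::write_tsv(curve, file.path(outdir, "core_pan_curve.tsv"))
    pc <- purrr::map_dfr(REP_CLASSES, function(cls) {
      out <- percent_core(families, cls)
      out$rep_class <- cls
      out
    })
    readr::write_tsv(pc, file.path(outdir, "percent_core.tsv"))
    acc <- classify_accessory_genes(families)
    readr::write_tsv(acc, file.path(outdir, "accessory_sharing.tsv"))
    stage_done(outdir, "pangenome", key)
    log_line(outdir, "stage pangenome: core %d / pan %d",
             core_pan_counts(families,
                             unique(families$strain_id))$core,
             core_pan_counts(families,
                             unique(families$strain_id))$pan)
  } else {
    log_line(outdir, "stage pangenome: cached")
  }

  # -- repeats ----------------------------------------------------------------
  key <- stage_key(config, "repeats")
  outs <- c("repeat_instances.tsv", "repeat_consensus.fasta")
  if (force || !stage_cached(outdir, "repeats", key, outs)) {
    fams_re <- discover_repeat_families(
      genomes$replicons, min_length = config$re_min_length,
      min_coverage = config$re_min_coverage, inflation = config$re_inflation
    )
    inst <- purrr::map_dfr(seq_len(nrow(genomes$replicons)), function(i) {
      scan_genome(fams_re, genomes$replicons$sequence[[i]],
                  genomes$replicons$replicon_id[[i]],
                  evalue_cutoff = config$evalue_cutoff,
                  seed = child_seed(config$seed, 3))
    })
    inst <- resolve_overlaps(inst)
    readr::write_tsv(inst, file.path(outdir, "repeat_instances.tsv"))
    write_fasta(tibble::tibble(
      record_id = vapply(fams_re, function(f) f$family_id, character(1)),
      sequence = vapply(fams_re, function(f) f$consensus, character(1))
    ), file.path(outdir, "repeat_consensus.fasta"))
    stage_done(outdir, "repeats", key)
    log_line(outdir, "stage repeats: %d families, %d instances",
             length(fams_re), nrow(inst))
  } else {
    inst <- readr::read_tsv(file.path(outdir, "repeat_instances.tsv"),
                            show_col_types = FALSE)
    log_line(outdir, "stage repeats: cached")
  }
  res$re_instances <- inst

  # -- tals -------------------------------------------------------------------
  key <- stage_key(config, "tals")
  if (force || !stage_cached(outdir, "tals", key, "tal_families.tsv")) {
    tal_ids <- flag_tals(genomes$genes)
    tal_fams <- cluster_tals(genomes$genes, tal_ids,
                             inflation = config$inflation)
    readr::write_tsv(tal_fams, file.path(outdir, "tal_families.tsv"))
    stage_done(outdir, "tals", key)
    log_line(outdir, "stage tals: %d TALs in %d families", length(tal_ids),
             dplyr::n_distinct(tal_fams$family_id))
  } else {
    tal_fams <- readr::read_tsv(file.path(outdir, "tal_families.tsv"),
                                show_col_types = FALSE)
    log_line(outdir, "stage tals: cached")
  }
  res$tal_families <- tal_fams

  # -- movement ---------------------------------------------------------------
  key <- stage_key(config, "movement")
  outs <- c("movement_events.tsv", "translocations.tsv")
  if (force || !stage_cached(outdir, "movement", key, outs)) {
    ev <- detect_gene_movement(families)
    flat <- movement_class_pairs(ev)
    readr::write_tsv(flat, file.path(outdir, "movement_events.tsv"))
    strains <- sort(unique(genomes$replicons$strain_id))
    tr <- purrr::map_dfr(strains, function(s) {
      detect_large_translocations(
        genomes, s, setdiff(strains, s),
        anchor_min_len = config$anchor_min_len, max_gap = config$max_gap,
        min_block_len = config$min_block_len,
        min_identity = config$min_block_identity,
        min_span = config$min_span
      )
    })
    readr::write_tsv(tr, file.path(outdir, "translocations.tsv"))
    stage_done(outdir, "movement", key)
    log_line(outdir, "stage movement: %d events, %d large translocations",
             nrow(ev), nrow(tr))
  } else {
    log_line(outdir, "stage movement: cached")
  }

  # -- divergence -------------------------------------------------------------
  key <- stage_key(config, "divergence")
  outs <- c("mantel.tsv")
  if (force || !stage_cached(outdir, "divergence", key, outs)) {
    mats <- list()
    for (cls in MAIN_CLASSES) {
      aln <- tryCatch(concat_core_alignment(families, genomes$genes, cls),
                      error = function(e) NULL)
      if (is.null(aln)) next
      D <- tn93_matrix(aln)
      readr::write_tsv(
        tibble::as_tibble(D, rownames = "strain_id"),
        file.path(outdir, paste0("tn93_", cls, ".tsv"))
      )
      if (nrow(D) >= 3) {
        writeLines(nj_tree(D), file.path(outdir, paste0("nj_", cls, ".nwk")))
      }
      mats[[cls]] <- D
    }
    mantel_rows <- list()
    if (length(mats) >= 2 && nrow(mats[[1]]) >= 4) {
      prs <- utils::combn(names(mats), 2, simplify = FALSE)
      for (pr in prs) {
        mt <- mantel_test(mats[[pr[1]]], mats[[pr[2]]],
                          n_perm = config$n_perm,
                          seed = child_seed(config$seed, 4))
        mantel_rows[[length(mantel_rows) + 1]] <- tibble::tibble(
          class_a = pr[1], class_b = pr[2], r = mt$r, p = mt$p,
          n_perm = mt$n_perm
        )
      }
    }
    readr::write_tsv(dplyr::bind_rows(mantel_rows),
                     file.path(outdir, "mantel.tsv"))
    stage_done(outdir, "divergence", key)
    log_line(outdir, "stage divergence: %d replicon classes", length(mats))
  } else {
    log_line(outdir, "stage divergence: cached")
  }

  # -- report -----------------------------------------------------------------
  key <- stage_key(config, "report")
  if (force || !stage_cached(outdir, "report", key, "replicon_summary.tsv")) {
    summ <- replicon_summary(genomes, families, res$re_instances,
                             res$tal_families)
    readr::write_tsv(summ, file.path(outdir, "replicon_summary.tsv"))
    gct <- gc_tests(genomes)
    readr::write_tsv(gct$tests, file.path(outdir, "gc_tests.tsv"))
    readr::write_tsv(gct$variances, file.path(outdir, "gc_variances.tsv"))
    stage_done(outdir, "report", key)
    log_line(outdir, "stage report: done")
  } else {
    log_line(outdir, "stage report: cached")
  }
  invisible(res)
}
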