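fam_fixture <- function() {
  # 3 strains; F1 core on chromosome everywhere; F2 core but on pSymA in s3;
  # F3 only in s1/s2 on pSymB; F4 private to s1 accessory.
  tibble::tribble(
    ~family_id, ~gene_id, ~strain_id, ~rep_class, ~replicon_id,
    "F1", "g01", "s1", "chromosome", "s1_chr",
    "F1", "g02", "s2", "chromosome", "s2_chr",
    "F1", "g03", "s3", "chromosome", "s3_chr",
    "F2", "g04", "s1", "chromosome", "s1_chr",
    "F2", "g05", "s2", "chromosome", "s2_chr",
    "F2", "g06", "s3", "pSymA", "s3_pA",
    "F3", "g07", "s1", "pSymB", "s1_pB",
    "F3", "g08", "s2", "pSymB", "s2_pB",
    "F4", "g09", "s1", "accessory", "s1_acc"
  )
}

test_that("core/pan counts follow the subset definition", {
  fams <- fam_fixture()
  expect_equal(core_pan_counts(fams, c("s1", "s2", "s3")),
               tibble::tibble(core = 2L, pan = 4L))
  one <- core_pan_counts(fams, "s1")
  expect_equal(one$core, one$pan)
  expect_equal(one$pan, 4L)
  expect_error(core_pan_counts(fams, character(0)), "non-empty")
  expect_error(core_pan_counts(fams, "nope"), "unknown strain")
})

test_that("core/pan curve is monotone along inclusion chains", {
  fams <- small_sim_families()
  strains <- sort(unique(fams$strain_id))
  # explicit chains
  set.seed(12)
  for (r in 1:5) {
    chain <- sample(strains)
    prev <- NULL
    for (k in seq_along(chain)) {
      cp <- core_pan_counts(fams, chain[seq_len(k)])
      if (!is.null(prev)) {
        expect_lte(cp$core, prev$core)
        expect_gte(cp$pan, prev$pan)
      }
      prev <- cp
    }
  }
  curve <- core_pan_curve(fams, seed = 3)
  means <- dplyr::summarise(dplyr::group_by(curve, subset_size),
                            core = mean(core), pan = mean(pan),
                            .groups = "drop")
  expect_true(all(diff(means$core) <= 1e-9))
  expect_true(all(diff(means$pan) >= -1e-9))
  # deterministic given seed
  expect_identical(curve, core_pan_curve(fams, seed = 3))
})

test_that("two identical strains give flat curves", {
  sim0 <- small_sim_mu0()
  tf <- sim0$truth$families
  tf2 <- tf[tf$strain_id %in% c("S01", "S02"), ]
  # restrict to core families so both strains carry identical content
  core_ids <- intersect(tf2$family_id[tf2$strain_id == "S01"],
                        tf2$family_id[tf2$strain_id == "S02"])
  flat <- tf2[tf2$family_id %in% core_ids, ]
  curve <- core_pan_curve(flat, seed = 1)
  expect_equal(unique(curve$core), length(core_ids))
  expect_equal(unique(curve$pan), length(core_ids))
})

test_that("core-replicon respects class placement and exclusions", {
  fams <- fam_fixture()
  expect_identical(core_replicon(fams, "chromosome"), "F1")
  # excluding the deviant strain restores F2 to the chromosome core
  expect_setequal(core_replicon(fams, "chromosome", "s3"), c("F1", "F2"))
  expect_identical(core_replicon(fams, "pSymB", "s3"), "F3")
  sim0 <- small_sim_mu0()
  tf <- sim0$truth$families
  planted_b <- unique(tf$family_id[tf$rep_class == "pSymB"])
  all_strains_b <- Filter(function(f) {
    length(unique(tf$strain_id[tf$family_id == f & tf$rep_class == "pSymB"])) ==
      length(unique(tf$strain_id))
  }, planted_b)
  expect_setequal(core_replicon(tf, "pSymB"), all_strains_b)
})

test_that("percent core counts genes, not families", {
  fams <- fam_fixture()
  pc <- percent_core(fams, "chromosome")
  # s1 chromosome: g01 (core F1) + g04 (core F2) -> 2/2
  expect_equal(pc$fraction_core[pc$strain_id == "s1"], 1)
  # s3 chromosome: only g03 (core) -> 1/1
  expect_equal(pc$fraction_core[pc$strain_id == "s3"], 1)
  pb <- percent_core(fams, "pSymB")
  expect_equal(pb$fraction_core[pb$strain_id == "s1"], 0)
  expect_true(is.na(pb$fraction_core[pb$strain_id == "s3"]))
})

test_that("accessory plasmids carry no core genes in the generator design", {
  fams <- small_sim_families()
  pc <- percent_core(fams, "accessory")
  expect_true(all(pc$fraction_core[!is.na(pc$fraction_core)] == 0))
})

test_that("percent core approximates the spec core fraction", {
  sim0 <- small_sim_mu0()
  tf <- sim0$truth$families
  core_ids <- core_genome_families(tf)
  frac <- length(core_ids) /
    length(unique(tf$family_id[tf$strain_id == "S01"]))
  # spec core_fraction 0.7 of families; per-strain pan includes only
  # sampled non-core, so the observed fraction sits above 0.7
  expect_gt(frac, 0.5)
  expect_lt(frac, 0.95)
})

test_that("accessory genes classify by their family's main-replicon pattern", {
  fams <- fam_fixture()
  fams2 <- dplyr::bind_rows(fams, tibble::tibble(
    family_id = c("F2", "F3"), gene_id = c("g10", "g11"),
    strain_id = "s2", rep_class = "accessory", replicon_id = "s2_acc"
  ))
  out <- classify_accessory_genes(fams2)
  s2 <- out[out$replicon_id == "s2_acc", ]
  # F2 occurs on chromosome and pSymA elsewhere -> multiple;
  # F3 only on pSymB -> pSymB-exclusive
  expect_equal(s2$multiple, 1L)
  expect_equal(s2$pSymB_exclusive, 1L)
  s1 <- out[out$replicon_id == "s1_acc", ]
  expect_equal(s1$unclassified, 1L)
  # category sums equal totals
  cats <- c("chromosome_exclusive", "pSymA_exclusive", "pSymB_exclusive",
            "multiple", "unclassified")
  expect_equal(rowSums(out[, cats]), out$total_genes,
               ignore_attr = TRUE)
})

test_that("pSymA-biased accessory sampling shows in the sharing table", {
  fams <- small_sim_families()
  out <- classify_accessory_genes(fams)
  expect_gt(sum(out$pSymA_exclusive), sum(out$chromosome_exclusive))
})

test_that("movement candidates equal core minus the core-replicon union", {
  fams <- small_sim_families()
  core_ids <- panreplicon:::core_genome_families(fams)
  union_cr <- unique(unlist(lapply(c("chromosome", "pSymA", "pSymB"),
                                   function(cls) core_replicon(fams, cls))))
  ev <- detect_gene_movement(fams)
  expect_setequal(ev$family_id, setdiff(core_ids, union_cr))
})
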