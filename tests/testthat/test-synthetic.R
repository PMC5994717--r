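test_that("identical seeds give byte-identical simulated outputs", {
  spec <- pan_genome_spec(n_families = 15)
  sizes <- c(chromosome = 2e4, pSymA = 15e3, pSymB = 15e3, accessory = 8e3)
  s1 <- generate_strain_set(spec, n_strains = 2, mutation_rate = 0.02,
                            replicon_sizes = sizes, seed = 9)
  s2 <- generate_strain_set(spec, n_strains = 2, mutation_rate = 0.02,
                            replicon_sizes = sizes, seed = 9)
  expect_identical(s1$genomes, s2$genomes)
  expect_identical(s1$truth, s2$truth)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_strain_set(s1, d1)
  write_strain_set(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  s3 <- generate_strain_set(spec, n_strains = 2, mutation_rate = 0.02,
                            replicon_sizes = sizes, seed = 10)
  expect_false(identical(s1$genomes$replicons$sequence,
                         s3$genomes$replicons$sequence))
})

test_that("every truth coordinate slices back to the stored sequence", {
  sim <- repeat_sim()
  reps <- sim$genomes$replicons
  seq_of <- stats::setNames(reps$sequence, reps$replicon_id)
  g <- sim$genomes$genes
  for (i in seq_len(nrow(g))) {
    sl <- substr(seq_of[[g$replicon_id[i]]], g$start[i], g$end[i])
    if (g$strand[i] == "-") sl <- revcomp(sl)
    expect_identical(sl, g$cds[i])
  }
  tr <- sim$truth$repeats
  for (i in seq_len(nrow(tr))) {
    expect_identical(substr(seq_of[[tr$replicon_id[i]]], tr$start[i] + 1,
                            tr$end[i]),
                     tr$sequence[i])
  }
})

test_that("full-core unmutated spec yields identical copies everywhere", {
  sim <- generate_strain_set(
    pan_genome_spec(n_families = 10, core_fraction = 1, tal_fraction = 0),
    n_strains = 3, mutation_rate = 0,
    replicon_sizes = c(chromosome = 15e3, pSymA = 12e3, pSymB = 12e3,
                       accessory = 6e3),
    n_accessory_range = c(0, 0), seed = 4
  )
  fams <- sim$truth$families
  per_fam <- dplyr::count(fams, family_id, strain_id)
  expect_true(all(per_fam$n == 1))
  expect_identical(nrow(dplyr::distinct(per_fam[, "family_id"])), 10L)
  cds_of <- stats::setNames(sim$genomes$genes$cds, sim$genomes$genes$gene_id)
  for (fid in unique(fams$family_id)) {
    members <- cds_of[fams$gene_id[fams$family_id == fid]]
    expect_identical(length(unique(members)), 1L)
  }
})

test_that("replicon G+C lands within half a mol% of the class target", {
  sim <- generate_strain_set(
    pan_genome_spec(n_families = 60), n_strains = 2, mutation_rate = 0.01,
    replicon_sizes = c(chromosome = 1.2e5, pSymA = 1e5, pSymB = 1e5,
                       accessory = 5e4),
    n_accessory_range = c(0, 0), seed = 31
  )
  reps <- sim$genomes$replicons
  targets <- stats::setNames(sim$truth$gc_targets$gc_molpct,
                             sim$truth$gc_targets$rep_class)
  big <- reps[reps$length_bp >= 1e5, ]
  for (i in seq_len(nrow(big))) {
    got <- 100 * gc_content(big$sequence[[i]])
    expect_lt(abs(got - targets[[big$rep_class[[i]]]]), 0.5)
  }
})

test_that("oversized gene content trips the sizing error", {
  expect_error(
    generate_strain_set(
      pan_genome_spec(n_families = 200),
      n_strains = 2,
      replicon_sizes = c(chromosome = 5e3, pSymA = 5e3, pSymB = 5e3,
                         accessory = 2e3),
      seed = 1
    ),
    "sizing error"
  )
})

test_that("planted repeat copies match the divergence expectation", {
  base <- generate_strain_set(
    pan_genome_spec(n_families = 10), n_strains = 2, mutation_rate = 0,
    replicon_sizes = c(chromosome = 3e4, pSymA = 2e4, pSymB = 2e4,
                       accessory = 8e3),
    n_accessory_range = c(0, 0), seed = 5
  )
  exact <- plant_repeat_family(base, consensus_length = 200,
                               copies_per_strain = 3, divergence = 0,
                               revcomp_fraction = 0, seed = 6)
  copies <- exact$truth$repeats$sequence
  expect_identical(length(unique(copies)), 1L)

  div <- 0.05
  diverged <- plant_repeat_family(base, consensus_length = 500,
                                  copies_per_strain = 4, divergence = div,
                                  revcomp_fraction = 0, seed = 7)
  seqs <- diverged$truth$repeats$sequence
  pair_id <- utils::combn(length(seqs), 2, function(ij) {
    a <- strsplit(seqs[ij[1]], "")[[1]]
    b <- strsplit(seqs[ij[2]], "")[[1]]
    mean(a == b)
  })
  # expected pairwise identity ~ (1 - d)^2 + small back-mutation term
  expect_lt(abs(mean(pair_id) - (1 - div)^2), 0.02)
  expect_error(plant_repeat_family(base, consensus_length = 50),
               ">= 66")
})

test_that("translocations conserve genes and shift sizes exactly", {
  sim <- small_sim()
  before <- sim$genomes
  moved <- plant_translocation(sim, "S01", "chromosome", "pSymB", 2e4,
                               seed = 9)
  expect_identical(nrow(moved$genomes$genes), nrow(before$genes))
  span <- moved$truth$blocks$span_bp[1]
  expect_gte(span, 2e4)
  sizes_b <- stats::setNames(before$replicons$length_bp,
                             before$replicons$replicon_id)
  sizes_a <- stats::setNames(moved$genomes$replicons$length_bp,
                             moved$genomes$replicons$replicon_id)
  expect_equal(sizes_b[["S01_chromosome"]] - span,
               sizes_a[["S01_chromosome"]])
  expect_equal(sizes_b[["S01_pSymB"]] + span, sizes_a[["S01_pSymB"]])
  same <- setdiff(names(sizes_b), c("S01_chromosome", "S01_pSymB"))
  expect_identical(sizes_a[same], sizes_b[same])
  # no-op span
  expect_identical(plant_translocation(sim, "S01", "chromosome", "pSymB", 0),
                   sim)
})

test_that("single-gene moves land in truth and in replicon assignments", {
  sim <- small_sim()
  moved <- plant_gene_move(sim, "S02", "pSymB", "pSymA", seed = 17)
  mv <- moved$truth$moves
  expect_identical(nrow(mv), 1L)
  g <- moved$genomes$genes
  row <- g[g$gene_id == mv$gene_id, ]
  expect_identical(row$rep_class, "pSymA")
  tf <- moved$truth$families
  expect_identical(tf$rep_class[tf$gene_id == mv$gene_id], "pSymA")
  # the gene still slices correctly from its new home
  seqs <- stats::setNames(moved$genomes$replicons$sequence,
                          moved$genomes$replicons$replicon_id)
  sl <- substr(seqs[[row$replicon_id]], row$start, row$end)
  if (row$strand == "-") sl <- revcomp(sl)
  expect_identical(sl, row$cds)
})
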