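move_fixture <- function(n_strains = 16) {
  strains <- sprintf("s%02d", seq_len(n_strains))
  stay <- tibble::tibble(
    family_id = "Fstay", gene_id = paste0("a", seq_len(n_strains)),
    strain_id = strains, rep_class = "chromosome",
    replicon_id = paste0(strains, "_chr")
  )
  moved <- tibble::tibble(
    family_id = "Fmove", gene_id = paste0("b", seq_len(n_strains)),
    strain_id = strains,
    rep_class = c(rep("pSymB", n_strains - 1), "pSymA"),
    replicon_id = paste0(strains, "_x")
  )
  dplyr::bind_rows(stay, moved)
}

test_that("movement events carry modal class and deviant strains", {
  fams <- move_fixture()
  ev <- detect_gene_movement(fams)
  expect_identical(ev$family_id, "Fmove")
  expect_identical(ev$modal_class, "pSymB")
  expect_identical(ev$n_deviants, 1L)
  expect_identical(ev$deviants[[1]]$strain_id, "s16")
  expect_identical(ev$deviants[[1]]$rep_class, "pSymA")
  expect_false(ev$ambiguous)
  pairs <- movement_class_pairs(ev)
  expect_equal(pairs,
               tibble::tibble(from_class = "pSymB", to_class = "pSymA",
                              n = 1L))
})

test_that("modal ties are flagged ambiguous and excluded from counts", {
  fams <- move_fixture(4)
  fams$rep_class[fams$family_id == "Fmove"] <-
    c("pSymB", "pSymB", "pSymA", "pSymA")
  ev <- detect_gene_movement(fams)
  expect_true(ev$ambiguous[ev$family_id == "Fmove"])
  expect_identical(nrow(movement_class_pairs(ev)), 0L)
})

test_that("event detection is invariant to strain input order", {
  fams <- move_fixture()
  set.seed(9)
  shuffled <- fams[sample(nrow(fams)), ]
  a <- detect_gene_movement(fams)
  b <- detect_gene_movement(shuffled)
  expect_identical(a$family_id, b$family_id)
  expect_identical(a$modal_class, b$modal_class)
  expect_identical(lapply(a$deviants, function(d) dplyr::arrange(d, strain_id)),
                   lapply(b$deviants, function(d) dplyr::arrange(d, strain_id)))
})

test_that("TAL families can be excluded and single-copy filter applies", {
  fams <- move_fixture()
  ev <- detect_gene_movement(fams, exclude_tals = TRUE,
                             tal_family_ids = "Fmove")
  expect_identical(nrow(ev), 0L)
  dup <- dplyr::bind_rows(fams, tibble::tibble(
    family_id = "Fmove", gene_id = "extra", strain_id = "s01",
    rep_class = "pSymB", replicon_id = "s01_x"
  ))
  ev2 <- detect_gene_movement(dup, single_copy_only = TRUE)
  expect_identical(nrow(ev2), 0L)
})

test_that("planted moves are recovered exactly with zero false events", {
  sim <- small_sim()
  sim <- plant_gene_move(sim, "S01", "chromosome", "pSymB", seed = 21)
  sim <- plant_gene_move(sim, "S02", "pSymB", "pSymA", seed = 22)
  fams <- cluster_genes(sim$genomes$genes)
  ev <- detect_gene_movement(fams)
  # map detected families back to truth via member genes
  fam_of_gene <- stats::setNames(sim$truth$families$family_id,
                                 sim$truth$families$gene_id)
  detected_truth <- vapply(ev$family_id, function(f) {
    unique(fam_of_gene[fams$gene_id[fams$family_id == f]])[1]
  }, character(1))
  expect_setequal(detected_truth, sim$truth$moves$family_id)
  dev <- dplyr::bind_rows(ev$deviants)
  expect_setequal(dev$strain_id, sim$truth$moves$strain_id)
})

test_that("identical sequences give one full-length synteny block", {
  set.seed(41)
  s <- rand_dna(20000)
  bl <- find_synteny_blocks(s, s, min_block_len = 10000)
  expect_identical(nrow(bl), 1L)
  expect_equal(bl$start_a, 0L)
  expect_equal(bl$end_a, 20000L)
  expect_equal(bl$identity, 1)
  expect_identical(bl$orientation, "forward")
})

test_that("block spans and anchors are symmetric between the two sides", {
  set.seed(42)
  anc <- rand_dna(30000)
  a <- panreplicon:::mutate_seq(anc, 0.01)
  b <- panreplicon:::mutate_seq(anc, 0.01)
  bl <- find_synteny_blocks(a, b, min_block_len = 5000, min_identity = 0.9)
  expect_gte(nrow(bl), 1L)
  expect_equal(sum(bl$end_a - bl$start_a), sum(bl$end_b - bl$start_b),
               tolerance = 1e-6)
  expect_true(all(bl$identity >= 0.9 & bl$identity <= 1))
})

test_that("greedy chaining agrees with the exhaustive chaining oracle", {
  set.seed(43)
  for (rep in 1:4) {
    anc <- rand_dna(4000)
    a <- panreplicon:::mutate_seq(anc, 0.02)
    b <- panreplicon:::mutate_seq(anc, 0.02)
    anchors <- maximal_exact_matches(a, b, 30, both_strands = FALSE)
    got <- find_synteny_blocks(a, b, anchor_min_len = 30, max_gap = 500,
                               min_block_len = 0, min_identity = 0)
    got_fw <- got[got$orientation == "forward", ]
    ref <- oracle_chain(anchors, 500, "forward")
    ref_spans <- sort(vapply(ref, function(x) x[2] - x[1], numeric(1)))
    expect_equal(sort(got_fw$end_a - got_fw$start_a), ref_spans)
  }
})

test_that("no translocation is called when strains are near-identical", {
  sim <- small_sim()
  ev <- detect_large_translocations(sim$genomes, "S01", c("S02", "S03"),
                                    min_block_len = 5e3, min_span = 1e4)
  expect_identical(nrow(ev), 0L)
})

test_that("a planted translocation is recovered with an accurate span", {
  sim <- plant_translocation(small_sim(), "S01", "chromosome", "pSymB",
                             2e4, seed = 5)
  ev <- detect_large_translocations(sim$genomes, "S01", c("S02", "S03"),
                                    min_block_len = 5e3, min_span = 1e4)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$from_class, "chromosome")
  expect_identical(ev$to_class, "pSymB")
  truth_span <- sim$truth$blocks$span_bp[1]
  expect_lt(abs(ev$span_bp - truth_span) / truth_span, 0.05)
})

test_that("breakpoint windows detect flanking TALs", {
  events <- tibble::tibble(
    strain_id = "s1", replicon_id = "r1", from_class = "chromosome",
    to_class = "pSymB", start = 10000L, end = 30000L, span_bp = 20000L,
    n_references = 2L
  )
  genes <- tibble::tibble(
    gene_id = c("t1", "t2"), replicon_id = "r1",
    start = c(9000L, 50000L), end = c(9500L, 50500L)
  )
  with_tal <- flanking_tal_check(events, genes, tal_ids = "t1",
                                 window_bp = 5000)
  expect_true(with_tal$tal_left)
  expect_false(with_tal$tal_right)
  expect_true(with_tal$tal_flanked)
  none <- flanking_tal_check(events, genes, tal_ids = "t2",
                             window_bp = 5000)
  expect_false(none$tal_flanked)
})
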