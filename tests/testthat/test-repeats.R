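test_that("self-match discovery equals the exhaustive diagonal oracle", {
  set.seed(61)
  for (i in 1:4) {
    s <- rand_dna(sample(800:1500, 1))
    # plant a forward duplication and a reverse-complement copy
    s <- paste0(s, substr(s, 51, 250), revcomp(substr(s, 301, 420)))
    got <- find_self_repeats(s, min_length = 65)
    ref <- oracle_self_matches(s, 65)
    key <- function(x) paste(x$start_a, x$end_a, x$start_b, x$end_b,
                             x$orientation)
    expect_setequal(key(got), key(ref))
  }
})

test_that("exact duplications are reported once with both intervals", {
  set.seed(62)
  s <- rand_dna(1200)
  dup <- substr(s, 101, 600)
  s2 <- paste0(s, dup)
  sm <- find_self_repeats(s2, 65)
  expect_identical(nrow(sm), 1L)
  expect_equal(sm$length, 500L)
  expect_equal(sm$orientation, "forward")
  expect_equal(c(sm$start_a, sm$end_a, sm$start_b, sm$end_b),
               c(100L, 600L, 1200L, 1700L))
  s3 <- paste0(s, revcomp(dup))
  sm3 <- find_self_repeats(s3, 65)
  expect_identical(sm3$orientation, "revcomp")
  expect_error(find_self_repeats(s, min_length = 5), ">= 10")
})

test_that("coverage clustering groups copies and isolates strangers", {
  set.seed(63)
  a <- rand_dna(300)
  pooled <- tibble::tibble(
    seq_id = c("p1", "p2", "p3", "p4"),
    sequence = c(a, a, panreplicon:::mutate_seq(a, 0.02), rand_dna(280))
  )
  clus <- cluster_repeat_sequences(pooled)
  expect_identical(clus$family_id[1], clus$family_id[2])
  expect_identical(clus$family_id[1], clus$family_id[3])
  expect_false(clus$family_id[4] == clus$family_id[1])
})

test_that("planted repeat families are recovered from pooled self-matches", {
  sim <- repeat_sim()
  res <- repeat_sim_results()
  pooled <- attr(res$families, "members")
  # assign each pooled sequence to the planted family it overlaps
  tr <- sim$truth$repeats
  truth_of <- vapply(seq_len(nrow(pooled)), function(i) {
    hit <- tr$replicon_id == pooled$replicon_id[i] &
      pmin(tr$end, pooled$end[i]) - pmax(tr$start, pooled$start[i]) >
      0.5 * (tr$end - tr$start)
    if (any(hit)) tr$family_id[which(hit)[1]] else NA_character_
  }, character(1))
  keep <- !is.na(truth_of)
  expect_gt(mean(keep), 0.8)  # most pooled sequences are planted repeats
  est <- stats::setNames(pooled$family_id[keep], pooled$seq_id[keep])
  tru <- stats::setNames(truth_of[keep], pooled$seq_id[keep])
  expect_gte(rand_index(est, tru), 0.95)
})

test_that("profile scanning recovers planted copies at their coordinates", {
  sim <- repeat_sim()
  res <- repeat_sim_results()
  tr <- sim$truth$repeats
  inst <- res$resolved
  hit <- vapply(seq_len(nrow(tr)), function(i) {
    cand <- inst[inst$replicon_id == tr$replicon_id[i], ]
    if (nrow(cand) == 0) return(FALSE)
    ov <- pmin(cand$end, tr$end[i]) - pmax(cand$start, tr$start[i])
    any(ov >= 0.9 * (tr$end[i] - tr$start[i]) &
          ov >= 0.9 * (cand$end - cand$start))
  }, logical(1))
  # parameter-recovery gate: divergence <= 5%, length >= 100 bp
  gate <- tr$divergence <= 0.05 & (tr$end - tr$start) >= 100
  expect_true(all(hit[gate]))
  expect_true(all(inst$evalue <= 1e-4))
})

test_that("an exact planted consensus copy is found with tiny E-value", {
  set.seed(64)
  fam <- build_family_profile(
    vapply(1:3, function(i) panreplicon:::mutate_seq(rand_dna(200), 0), character(1)),
    family_id = "RF_X"
  )
  # all three members identical -> consensus == member
  genome <- paste0(rand_dna(4000), fam$consensus, rand_dna(4000))
  inst <- scan_genome(list(fam), genome, "chr", seed = 5)
  expect_gte(nrow(inst), 1)
  best <- inst[which.max(inst$score), ]
  expect_equal(best$start, 4000L)
  expect_equal(best$end, 4200L)
  expect_lt(best$evalue, 1e-8)
  expect_equal(best$identity_to_consensus, 1)
})

test_that("decoy calibration is self-consistent in expectation", {
  set.seed(65)
  fam <- build_family_profile(
    rep(rand_dna(150, gc = 0.6), 3), family_id = "RF_C"
  )
  genome <- rand_dna(20000, gc = 0.6)
  counts <- vapply(1:10, function(k) {
    decoy <- panreplicon:::dinucleotide_shuffle(genome)
    inst <- scan_genome(list(fam), decoy, "decoy", evalue_cutoff = 2,
                        seed = 100 + k)
    sum(inst$evalue <= 2)
  }, numeric(1))
  # expected ~2 hits per decoy at E <= 2; allow generous Poisson slack
  expect_gt(mean(counts), 2 / 4)
  expect_lt(mean(counts), 2 * 4)
})

test_that("dinucleotide shuffling preserves dinucleotide counts", {
  set.seed(66)
  s <- rand_dna(3000, gc = 0.65)
  sh <- panreplicon:::dinucleotide_shuffle(s)
  din <- function(x) {
    ch <- strsplit(x, "")[[1]]
    table(paste0(ch[-length(ch)], ch[-1]))
  }
  expect_identical(din(sh), din(s))
  expect_false(identical(sh, s))
})

test_that("overlap ownership follows length, identity, score, coordinate", {
  base <- tibble::tibble(
    replicon_id = "r",
    start = c(0L, 350L), end = c(400L, 650L),
    family_id = c("A", "B"),
    score = c(50, 80), evalue = 1e-9,
    identity_to_consensus = c(0.90, 0.99),
    orientation = "forward"
  )
  kept <- resolve_overlaps(base)
  expect_identical(kept$family_id, "A")  # longer wins despite lower identity
  tie_len <- base
  tie_len$end <- c(400L, 750L)  # equal lengths, overlap remains
  kept2 <- resolve_overlaps(tie_len)
  expect_identical(kept2$family_id, "B")  # higher identity wins
  tie_all <- tie_len
  tie_all$identity_to_consensus <- c(0.95, 0.95)
  kept3 <- resolve_overlaps(tie_all)
  expect_identical(kept3$family_id, "B")  # higher score
  tie_full <- tie_all
  tie_full$score <- c(70, 70)
  kept4 <- resolve_overlaps(tie_full)
  expect_identical(kept4$family_id, "A")  # lower start coordinate
})

test_that("resolved instances are pairwise disjoint per replicon", {
  inst <- repeat_sim_results()$resolved
  for (rid in unique(inst$replicon_id)) {
    sub <- inst[inst$replicon_id == rid, ]
    sub <- sub[order(sub$start), ]
    if (nrow(sub) > 1) {
      expect_true(all(sub$start[-1] >= sub$end[-nrow(sub)]), label = rid)
    }
  }
})

test_that("repeat-covered fraction agrees between interval and per-base paths", {
  inst <- repeat_sim_results()$resolved
  reps <- repeat_sim()$genomes$replicons
  for (rid in unique(inst$replicon_id)) {
    sub <- inst[inst$replicon_id == rid, ]
    len <- reps$length_bp[reps$replicon_id == rid]
    ivals <- IRanges::reduce(IRanges::IRanges(sub$start + 1, sub$end))
    frac_iv <- sum(IRanges::width(ivals)) / len
    flags <- logical(len)
    for (i in seq_len(nrow(sub))) {
      flags[(sub$start[i] + 1):sub$end[i]] <- TRUE
    }
    expect_equal(frac_iv, mean(flags))
  }
})

test_that("density and occurrence spectrum follow their definitions", {
  reps <- tibble::tibble(
    replicon_id = c("r1", "r2"), strain_id = c("s1", "s2"),
    rep_class = "chromosome", length_bp = c(1e6L, 5e5L)
  )
  inst <- tibble::tibble(
    replicon_id = c("r1", "r2", "r2"),
    start = c(0L, 0L, 1000L), end = c(100L, 100L, 1100L),
    family_id = c("RF1", "RF1", "RF2"), score = 1, evalue = 1e-9,
    identity_to_consensus = 1, orientation = "forward"
  )
  st <- re_statistics(inst, reps)
  d <- st$replicon_density
  expect_equal(d$per_mb[d$replicon_id == "r1"], 1)
  expect_equal(d$per_mb[d$replicon_id == "r2"], 4)
  sp <- st$spectrum
  expect_equal(sp$n_strains[sp$family_id == "RF1"], 2L)
  expect_equal(sp$n_strains[sp$family_id == "RF2"], 1L)
})
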