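test_that("TN93 is zero on identity, symmetric, and skips ambiguous sites", {
  set.seed(71)
  s <- rand_dna(900)
  expect_equal(tn93_distance(s, s), 0)
  t <- panreplicon:::mutate_seq(s, 0.04)
  expect_equal(tn93_distance(s, t), tn93_distance(t, s))
  # N / gap sites are removed pairwise
  s2 <- paste0("NN", s)
  t2 <- paste0("AC", t)
  expect_equal(tn93_distance(s2, t2), tn93_distance(s, t))
  expect_error(tn93_distance("ACG", "AC"), "equal length")
  expect_error(tn93_distance("NNN", "ANN"), "comparable")
})

test_that("TN93 matches Jukes-Cantor in the balanced limit to 1e-9", {
  for (m in c(6, 12, 24)) {
    bp <- balanced_pair(2400, m)
    jc <- -0.75 * log(1 - 4 * bp$p / 3)
    expect_lt(abs(tn93_distance(bp$a, bp$b) - jc), 1e-9)
  }
})

test_that("TN93 agrees with the ape reference on random pairs", {
  set.seed(72)
  for (i in 1:8) {
    s <- rand_dna(3000, gc = runif(1, 0.3, 0.7))
    t <- panreplicon:::mutate_seq(s, runif(1, 0.01, 0.12))
    mine <- tn93_distance(s, t)
    m <- rbind(strsplit(s, "")[[1]], strsplit(t, "")[[1]])
    ref <- as.numeric(ape::dist.dna(ape::as.DNAbin(m), model = "TN93"))
    expect_equal(mine, ref, tolerance = 1e-10)
  }
})

test_that("TN93 grows monotonically with added substitutions and saturates", {
  set.seed(73)
  s <- rand_dna(2000)
  ch <- strsplit(s, "")[[1]]
  prev <- 0
  t <- ch
  for (k in c(50, 100, 200, 400)) {
    idx <- seq_len(k)
    t[idx] <- vapply(ch[idx], function(b) setdiff(c("A", "C", "G", "T"), b)[1],
                     character(1))
    d <- tn93_distance(s, paste(t, collapse = ""))
    expect_gt(d, prev)
    prev <- d
  }
  # forcing most sites to differ saturates the correction
  t_all <- vapply(ch, function(b) setdiff(c("A", "C", "G", "T"), b)[1],
                  character(1))
  expect_error(tn93_distance(s, paste(t_all, collapse = "")), "saturation")
})

test_that("concatenated core alignments line up per-family gap-free blocks", {
  sim <- small_sim()
  fams <- small_sim_families()
  aln <- concat_core_alignment(fams, sim$genomes$genes, "chromosome")
  expect_setequal(aln$strain_id, unique(fams$strain_id))
  expect_identical(length(unique(nchar(aln$sequence))), 1L)
  # identical inputs: alignment is the sequence itself
  one <- concat_core_alignment(
    tibble::tibble(family_id = "F1", gene_id = c("x1", "x2"),
                   strain_id = c("s1", "s2"), rep_class = "chromosome"),
    tibble::tibble(gene_id = c("x1", "x2"), cds = c("ATGAAACCC", "ATGAAACCC")),
    "chromosome"
  )
  expect_identical(one$sequence, c("ATGAAACCC", "ATGAAACCC"))
  # point-substitution divergence: mean pairwise difference ~ 2 * mu
  mu <- 0.01
  D <- tn93_matrix(aln)
  offdiag <- D[lower.tri(D)]
  expect_lt(abs(mean(offdiag) - 2 * mu) / (2 * mu), 0.35)
})

test_that("Mantel behaves on the self-comparison and degenerate cases", {
  set.seed(74)
  n <- 8
  m1 <- as.matrix(dist(matrix(rnorm(n * 3), n)))
  rownames(m1) <- colnames(m1) <- paste0("s", 1:n)
  mt <- mantel_test(m1, m1, n_perm = 199, seed = 2)
  expect_equal(mt$r, 1)
  expect_equal(mt$p, 1 / 200)
  expect_identical(mantel_test(m1, m1, n_perm = 99, seed = 7)$p,
                   mantel_test(m1, m1, n_perm = 99, seed = 7)$p)
  m0 <- matrix(0, n, n, dimnames = dimnames(m1))
  expect_error(mantel_test(m1, m0, n_perm = 99), "constant")
  expect_error(mantel_test(m1[1:3, 1:3], m1[1:3, 1:3], n_perm = 99),
               "at least 4")
  td <- tidy(mt)
  expect_identical(names(td), c("r", "p", "n_perm", "alternative"))
})

test_that("Mantel statistic matches the vegan implementation", {
  set.seed(75)
  n <- 9
  a <- as.matrix(dist(matrix(rnorm(n * 3), n)))
  b <- as.matrix(dist(matrix(rnorm(n * 3), n)))
  rownames(a) <- colnames(a) <- rownames(b) <- colnames(b) <- paste0("s", 1:n)
  mine <- mantel_test(a, b, n_perm = 99, seed = 1)
  ref <- vegan::mantel(stats::as.dist(a), stats::as.dist(b),
                       permutations = 99)
  expect_equal(mine$r, unname(ref$statistic), tolerance = 1e-12)
})

test_that("shared strain history drives Mantel p low across replicons", {
  set.seed(76)
  hits <- 0
  n_rep <- 20
  for (i in seq_len(n_rep)) {
    # one latent strain geometry observed twice with noise: strong signal
    base <- matrix(rnorm(8 * 3), 8)
    m1 <- as.matrix(dist(base + matrix(rnorm(24, sd = 0.1), 8)))
    m2 <- as.matrix(dist(base + matrix(rnorm(24, sd = 0.1), 8)))
    rownames(m1) <- colnames(m1) <- rownames(m2) <- colnames(m2) <-
      paste0("s", 1:8)
    p <- mantel_test(m1, m2, n_perm = 199, seed = 1000 + i)$p
    if (p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.8)
})

test_that("neighbour-joining solves three taxa exactly and recovers trees", {
  D3 <- matrix(c(0, 3, 4,
                 3, 0, 5,
                 4, 5, 0), 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  nw <- nj_tree(D3)
  tr <- attr(nw, "phylo")
  # three-point formulas: x = (dab+dac-dbc)/2 etc.
  lens <- stats::setNames(tr$edge.length[order(tr$edge[, 2])][1:3],
                          tr$tip.label[order(tr$edge[, 2])[1:3]])
  lens <- tr$edge.length[match(1:3, tr$edge[, 2])]
  expect_equal(lens, c((3 + 4 - 5) / 2, (3 + 5 - 4) / 2, (4 + 5 - 3) / 2))
  # additive 5-taxon matrix reproduces its source topology
  src <- ape::read.tree(text = "((a:1,b:2):1.5,(c:0.5,d:1):2,e:3);")
  D5 <- ape::cophenetic.phylo(src)
  nw5 <- nj_tree(D5)
  expect_equal(ape::dist.topo(ape::unroot(src), attr(nw5, "phylo")), 0,
               ignore_attr = TRUE)
  # ultrametric 4-taxon matrix pairs the sisters
  D4 <- matrix(0.6, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  D4[1, 2] <- D4[2, 1] <- 0.2
  D4[3, 4] <- D4[4, 3] <- 0.2
  diag(D4) <- 0
  t4 <- attr(nj_tree(D4), "phylo")
  ref4 <- ape::read.tree(text = "((a:0.1,b:0.1):0.2,(c:0.1,d:0.1):0.2);")
  expect_equal(ape::dist.topo(ape::unroot(ref4), t4), 0, ignore_attr = TRUE)
  expect_error(nj_tree(D3[1:2, 1:2]), "at least 3")
})

test_that("count PCA fixes signs, orders variance and spots degeneracy", {
  M <- rbind(a1 = c(5, 0, 1), a2 = c(5, 1, 0),
             b1 = c(0, 5, 2), b2 = c(0, 5, 3))
  p <- pca_counts(M, rep_class = c("A", "A", "B", "B"))
  ev <- p$explained_variance
  expect_lte(sum(ev), 1 + 1e-12)
  expect_true(all(diff(ev) <= 1e-12))
  expect_true(all(apply(p$loadings, 2, function(l) l[which.max(abs(l))] > 0)))
  # identical rows map to the same point
  M2 <- rbind(M, a1bis = c(5, 0, 1))
  p2 <- pca_counts(M2)
  expect_equal(unname(unlist(p2$scores[1, c("PC1", "PC2")])),
               unname(unlist(p2$scores[5, c("PC1", "PC2")])))
  expect_error(pca_counts(M[1, , drop = FALSE]), "at least 2")
  flat <- rbind(c(1, 1), c(2, 2), c(3, 3))  # rank 1 after centering
  expect_error(pca_counts(flat), "degenerac")
  expect_identical(nrow(tidy(p)), 4L)
  expect_identical(glance(p)$n, 4L)
})

test_that("class-specific planting clusters replicons by class, not strain", {
  set.seed(77)
  strains <- paste0("s", 1:4)
  classes <- c("chromosome", "pSymA", "pSymB")
  rows <- expand.grid(strain = strains, class = classes,
                      stringsAsFactors = FALSE)
  n_fam <- 9
  M <- matrix(0, nrow(rows), n_fam)
  for (i in seq_len(nrow(rows))) {
    cls_idx <- match(rows$class[i], classes)
    fam_idx <- ((cls_idx - 1) * 3 + 1):(cls_idx * 3)
    M[i, fam_idx] <- rpois(3, 8)
    M[i, -fam_idx] <- rpois(n_fam - 3, 0.5)
  }
  rownames(M) <- paste(rows$strain, rows$class, sep = "_")
  p <- pca_counts(M, rep_class = rows$class)
  X <- as.matrix(p$scores[, c("PC1", "PC2")])
  expect_gt(silhouette_mean(X, rows$class), silhouette_mean(X, rows$strain))
})
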