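# Per-replicon divergence: concatenated single-copy-core alignments, TN93
# distances (pairwise deletion, frequencies pooled over the pair), Mantel
# permutation tests, neighbour-joining trees and PCA of repeat/TAL family
# counts.

#' Concatenated single-copy-core alignment for one replicon class
#'
#' Restricts to single-copy core families whose members all lie on
#' `rep_class`, center-star aligns each family's coding sequences, removes
#' columns containing any gap, and concatenates the per-family alignments in
#' family-id order. Families missing a strain (after the class restriction)
#' are skipped with a warning.
#'
#' @param families Family tibble (`family_id`, `gene_id`, `strain_id`,
#'   `rep_class`).
#' @param genes Gene tibble (`gene_id`, `cds`).
#' @param rep_class Replicon class.
#' @param strains Strains required; defaults to all strains in `families`.
#' @return Tibble `strain_id`, `sequence` (equal lengths).
#' @export
concat_core_alignment <- function(families, genes, rep_class,
                                  strains = NULL) {
  strains <- strains %||% sort(unique(families$strain_id))
  scc <- single_copy_core(families, strains)
  on_class <- dplyr::summarise(
    dplyr::group_by(families[families$family_id %in% scc, , drop = FALSE],
                    .data$family_id),
    all_on = all(.data$rep_class == rep_class), .groups = "drop"
  )
  fids <- sort(on_class$family_id[on_class$all_on])
  cds_of <- stats::setNames(genes$cds, genes$gene_id)
  pieces <- stats::setNames(vector("list", length(strains)), strains)
  for (s in strains) pieces[[s]] <- character(0)
  used <- 0
  for (fid in fids) {
    memb <- families[families$family_id == fid, , drop = FALSE]
    memb <- memb[match(strains, memb$strain_id), , drop = FALSE]
    if (anyNA(memb$gene_id)) {
      warning(sprintf("family %s missing a strain; skipped", fid))
      next
    }
    seqs <- unname(cds_of[memb$gene_id])
    aln <- center_star_align(seqs, type = "dna")$alignment
    gapfree <- drop_gap_columns(aln)
    if (nchar(gapfree[[1]]) == 0) next
    for (k in seq_along(strains)) {
      pieces[[strains[[k]]]] <- c(pieces[[strains[[k]]]], gapfree[[k]])
    }
    used <- used + 1
  }
  assert_that(used > 0, paste0("no usable single-copy core family on ",
                               rep_class))
  tibble::tibble(
    strain_id = strains,
    sequence = vapply(strains, function(s) paste(pieces[[s]], collapse = ""),
                      character(1), USE.NAMES = FALSE)
  )
}

#' TN93 distance between two aligned sequences
#'
#' Tamura-Nei (1993) distance distinguishing purine transitions (A<->G),
#' pyrimidine transitions (C<->T) and transversions, with base frequencies
#' pooled over both sequences. Sites where either sequence carries a gap or
#' ambiguous base are skipped (pairwise deletion).
#'
#' @param seq_a,seq_b Equal-length aligned DNA strings.
#' @return Distance in substitutions per site.
#' @export
tn93_distance <- function(seq_a, seq_b) {
  assert_that(nchar(seq_a) == nchar(seq_b), "sequences must be equal length")
  ca <- seq_codes(seq_a)
  cb <- seq_codes(seq_b)
  ok <- !is.na(ca) & !is.na(cb)
  n <- sum(ok)
  assert_that(n >= 1, "no comparable sites")
  ca <- ca[ok]; cb <- cb[ok]
  # pooled base frequencies (A=1,C=2,G=3,T=4)
  f <- tabulate(c(ca, cb), nbins = 4) / (2 * n)
  gA <- f[1]; gC <- f[2]; gG <- f[3]; gT <- f[4]
  gR <- gA + gG; gY <- gC + gT
  diff <- ca != cb
  pur <- (ca == 1 & cb == 3) | (ca == 3 & cb == 1)
  pyr <- (ca == 2 & cb == 4) | (ca == 4 & cb == 2)
  P1 <- sum(pur) / n
  P2 <- sum(pyr) / n
  Q <- sum(diff & !pur & !pyr) / n
  k1 <- 2 * gA * gG / gR
  k2 <- 2 * gC * gT / gY
  k3 <- 2 * (gR * gY - gA * gG * gY / gR - gC * gT * gR / gY)
  w1 <- 1 - P1 / k1 - Q / (2 * gR)
  w2 <- 1 - P2 / k2 - Q / (2 * gY)
  w3 <- 1 - Q / (2 * gR * gY)
  if (w1 <= 0 || w2 <= 0 || w3 <= 0) {
    stop("TN93 saturation: log argument <= 0 for this pair", call. = FALSE)
  }
  -k1 * log(w1) - k2 * log(w2) - k3 * log(w3)
}

#' Pairwise TN93 distance matrix
#'
#' @param alignment Tibble `strain_id`, `sequence` (equal-length aligned
#'   sequences), e.g. from [concat_core_alignment()].
#' @return Symmetric labelled matrix of TN93 distances, zero diagonal.
#' @export
tn93_matrix <- function(alignment) {
  n <- nrow(alignment)
  D <- matrix(0, n, n,
              dimnames = list(alignment$strain_id, alignment$strain_id))
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d <- tn93_distance(alignment$sequence[[i]], alignment$sequence[[j]])
        D[i, j] <- d
        D[j, i] <- d
      }
    }
  }
  D
}

#' Mantel permutation test between two distance matrices
#'
#' The statistic is the Pearson correlation of the lower-triangle entries;
#' the null distribution is generated by simultaneous row/column relabelling
#' of the second matrix. One-sided (`greater`) p-value by default:
#' `(1 + #{r_perm >= r_obs}) / (1 + n_perm)`.
#'
#' @param m1,m2 Distance matrices with identical labels in identical order.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return A `mantel_result`: list with `r`, `p`, `n_perm`, `alternative`.
#' @export
mantel_test <- function(m1, m2, n_perm = 10000, seed = 1,
                        alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  assert_that(nrow(m1) == ncol(m1) && nrow(m2) == ncol(m2) &&
                nrow(m1) == nrow(m2), "matrices must be square, same size")
  assert_that(nrow(m1) >= 4, "need at least 4 labels")
  if (!is.null(rownames(m1)) && !is.null(rownames(m2))) {
    assert_that(identical(rownames(m1), rownames(m2)),
                "matrix labels must match in order")
  }
  lt <- lower.tri(m1)
  x <- m1[lt]
  if (stats::sd(x) == 0 || stats::sd(m2[lt]) == 0) {
    stop("Mantel statistic undefined: constant distance matrix", call. = FALSE)
  }
  r_obs <- stats::cor(x, m2[lt])
  n <- nrow(m1)
  r_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    idx <- sample(n)
    stats::cor(x, m2[idx, idx][lt])
  }, numeric(1)))
  p <- if (alternative == "greater") {
    (1 + sum(r_perm >= r_obs)) / (1 + n_perm)
  } else {
    (1 + sum(abs(r_perm) >= abs(r_obs))) / (1 + n_perm)
  }
  structure(list(r = r_obs, p = p, n_perm = n_perm,
                 alternative = alternative),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, p = %.4g (%s, %d permutations)\n",
              x$r, x$p, x$alternative, x$n_perm))
  invisible(x)
}

#' Neighbour-joining tree from a distance matrix
#'
#' Standard neighbour-joining (via the ape implementation); negative branch
#' lengths are clamped to zero (a message reports how many).
#'
#' @param m Symmetric labelled distance matrix (n >= 3).
#' @return Newick string; the `phylo` object is attached as attribute
#'   `phylo`.
#' @export
nj_tree <- function(m) {
  assert_that(nrow(m) >= 3, "need at least 3 taxa")
  tree <- ape::nj(stats::as.dist(m))
  neg <- tree$edge.length < 0
  if (any(neg)) {
    message(sprintf("nj_tree: clamped %d negative branch length(s) to 0",
                    sum(neg)))
    tree$edge.length[neg] <- 0
  }
  structure(ape::write.tree(tree), phylo = tree)
}

#' PCA of repeat/TAL family counts per replicon
#'
#' Column-centred covariance PCA (no scaling) of a replicon-by-family count
#' matrix. Component signs are fixed so that each component's
#' largest-magnitude loading is positive.
#'
#' @param count_matrix Numeric matrix: rows = replicon-per-strain (named),
#'   columns = families.
#' @param rep_class Optional per-row replicon class (recycled onto the
#'   scores for plotting).
#' @return A `pr_pca`: `scores` tibble (`row_id`, `rep_class`, `PC1`,
#'   `PC2`), `explained_variance` (fractions, all components), `loadings`.
#' @export
pca_counts <- function(count_matrix, rep_class = NULL) {
  assert_that(nrow(count_matrix) >= 2, "need at least 2 rows")
  pc <- stats::prcomp(count_matrix, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  assert_that(ncol(pc$x) >= 2 && pc$sdev[2] > 1e-12,
              "degeneracy error: fewer than 2 non-degenerate dimensions")
  for (k in 1:2) {
    flip <- sign(pc$rotation[which.max(abs(pc$rotation[, k])), k])
    if (flip < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  scores <- tibble::tibble(
    row_id = rownames(count_matrix) %||% as.character(seq_len(nrow(count_matrix))),
    rep_class = rep_class %||% NA_character_,
    PC1 = pc$x[, 1], PC2 = pc$x[, 2]
  )
  structure(list(scores = scores, explained_variance = ev,
                 loadings = pc$rotation[, 1:2, drop = FALSE]),
            class = "pr_pca")
}

#' @export
print.pr_pca <- function(x, ...) {
  cat(sprintf("<pr_pca> %d rows; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$scores), 100 * x$explained_variance[1],
              100 * x$explained_variance[2]))
  invisible(x)
}

#' Count-matrix builder for PCA
#'
#' Builds the replicon-per-strain by family count matrix from an instance
#' or membership table.
#'
#' @param tbl Tibble with `replicon_id` and `family_id` columns.
#' @param replicons Replicon tibble (`replicon_id`, `rep_class`).
#' @return List: `matrix`, `rep_class` (row classes).
#' @export
family_count_matrix <- function(tbl, replicons) {
  counts <- dplyr::count(tbl, .data$replicon_id, .data$family_id)
  wide <- tidyr::pivot_wider(counts, names_from = "family_id",
                             values_from = "n", values_fill = 0L)
  M <- as.matrix(wide[, -1, drop = FALSE])
  rownames(M) <- wide$replicon_id
  cls <- replicons$rep_class[match(wide$replicon_id, replicons$replicon_id)]
  list(matrix = M, rep_class = cls)
}
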