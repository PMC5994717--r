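# Independent reference implementations used to check the package's
# algorithms on small inputs. These deliberately avoid the code paths they
# verify: dense matrices without pruning for MCL, exhaustive diagonal scans
# for self-matches, exhaustive chaining for synteny.

# Dense MCL reference: no pruning, plain matrix ops, cluster read-off by the
# same attractor contract (attractors = positive diagonal; attractors
# sharing column support merge; nodes follow their strongest attractor).
oracle_mcl <- function(edges, nodes, inflation, iters = 300, tol = 1e-9) {
  nodes <- sort(nodes)
  n <- length(nodes)
  M <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges) > 0) {
    for (r in seq_len(nrow(edges))) {
      i <- match(edges$gene_a[r], nodes)
      j <- match(edges$gene_b[r], nodes)
      M[i, j] <- edges$score[r]
      M[j, i] <- edges$score[r]
    }
  }
  loops <- apply(M, 1, max)
  loops[loops <= 0] <- 1
  diag(M) <- loops
  M <- sweep(M, 2, colSums(M), "/")
  for (it in seq_len(iters)) {
    E <- M %*% M
    E <- E^inflation
    E <- sweep(E, 2, colSums(E), "/")
    if (max(abs(E - M)) < tol) {
      M <- E
      break
    }
    M <- E
  }
  thr <- 1e-6
  attractors <- which(diag(M) > thr)
  if (length(attractors) == 0) attractors <- seq_len(n)
  # merge attractors sharing support in any column (BFS union)
  lab <- seq_along(attractors)
  for (j in seq_len(n)) {
    sup <- which(M[attractors, j] > thr)
    if (length(sup) > 1) {
      tgt <- min(lab[sup])
      lab[lab %in% lab[sup]] <- tgt
    }
  }
  assign <- integer(n)
  for (j in seq_len(n)) {
    w <- M[attractors, j]
    if (all(w <= thr)) {
      assign[j] <- NA_integer_
      next
    }
    flow <- tapply(w, lab, sum)
    assign[j] <- as.integer(names(flow)[which.max(flow)])
  }
  if (anyNA(assign)) {
    assign[is.na(assign)] <- max(assign, na.rm = TRUE) + seq_len(sum(is.na(assign)))
  }
  tibble::tibble(gene_id = nodes, cluster = match(assign, unique(assign)))
}

# Compare two memberships as partitions (label-free).
same_partition <- function(p1, p2) {
  p1 <- p1[order(p1$gene_id), ]
  p2 <- p2[order(p2$gene_id), ]
  if (!identical(p1$gene_id, p2$gene_id)) return(FALSE)
  s1 <- split(p1$gene_id, p1$cluster)
  s2 <- split(p2$gene_id, p2$cluster)
  setequal(lapply(s1, sort), lapply(s2, sort))
}

# Pair-level Rand index of two memberships given as named vectors
# (gene -> label), over the shared genes.
rand_index <- function(a, b) {
  genes <- intersect(names(a), names(b))
  a <- a[genes]; b <- b[genes]
  sa <- outer(a, a, "==")
  sb <- outer(b, b, "==")
  ut <- upper.tri(sa)
  mean(sa[ut] == sb[ut])
}

# Exhaustive self-match oracle: scans every diagonal of the sequence (and of
# sequence vs reverse complement) for maximal match runs >= min_len.
oracle_self_matches <- function(s, min_len) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(ch)
  rows <- list()
  for (d in 1:(n - 1)) {
    m <- ch[1:(n - d)] == ch[(1 + d):n] & ch[1:(n - d)] != "N"
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    hit <- which(r$values & r$lengths >= min_len)
    for (h in hit) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        start_a = starts[h] - 1L, end_a = ends[h],
        start_b = starts[h] - 1L + d, end_b = ends[h] + d,
        length = r$lengths[h], orientation = "forward"
      )
    }
  }
  rc <- strsplit(panreplicon::revcomp(s), "", fixed = TRUE)[[1]]
  for (d in -(n - 1):(n - 1)) {
    lo <- max(1, 1 - d); hi <- min(n, n - d)
    if (hi - lo + 1 < min_len) next
    m <- ch[lo:hi] == rc[(lo + d):(hi + d)] & ch[lo:hi] != "N"
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    hit <- which(r$values & r$lengths >= min_len)
    for (h in hit) {
      sa <- lo + starts[h] - 2L; ea <- lo + ends[h] - 1L
      sb_rc <- sa + d; eb_rc <- ea + d
      sb <- n - eb_rc; eb <- n - sb_rc
      if (sb < sa || (sb == sa && eb == ea)) next  # canonical order / palindrome
      rows[[length(rows) + 1]] <- tibble::tibble(
        start_a = sa, end_a = ea, start_b = sb, end_b = eb,
        length = r$lengths[h], orientation = "revcomp"
      )
    }
  }
  # mirror-complete revcomp pairs (oracle reports each unordered pair once
  # with start_a <= start_b; drop duplicates arising from both diagonals)
  out <- dplyr::distinct(dplyr::bind_rows(rows))
  dplyr::arrange(out, start_a, start_b)
}

# Exhaustive colinear chaining oracle: connect anchors (sorted by query
# start) whenever gaps on both sides are within max_gap and order is
# preserved; chains = connected components of the sequential compatibility
# relation taken greedily in order (mirrors the chaining contract).
oracle_chain <- function(anchors, max_gap, orientation) {
  n <- nrow(anchors)
  ord <- order(anchors$start_a, anchors$start_b)
  anchors <- anchors[ord, ]
  chains <- list()
  used <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (used[i]) next
    chain <- i
    used[i] <- TRUE
    repeat {
      last <- chain[length(chain)]
      nxt <- NA
      for (j in seq_len(n)) {
        if (used[j]) next
        gap_a <- anchors$start_a[j] - anchors$end_a[last]
        ok_b <- if (orientation == "forward") {
          gb <- anchors$start_b[j] - anchors$end_b[last]
          gb >= 0 && gb <= max_gap
        } else {
          gb <- anchors$start_b[last] - anchors$end_b[j]
          gb >= 0 && gb <= max_gap
        }
        if (gap_a >= 0 && gap_a <= max_gap && ok_b) { nxt <- j; break }
      }
      if (is.na(nxt)) break
      chain <- c(chain, nxt)
      used[nxt] <- TRUE
    }
    chains[[length(chains) + 1]] <-
      c(min(anchors$start_a[chain]), max(anchors$end_a[chain]))
  }
  chains
}

# Random DNA / protein helpers for property tests.
rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

rand_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, TRUE),
        collapse = "")
}

# Mean silhouette width for a labelling of rows of X (Euclidean).
silhouette_mean <- function(X, labels) {
  D <- as.matrix(dist(X))
  n <- nrow(X)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l) {
      mean(D[i, labels == l])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Helper: pair of sequences with exactly balanced substitution pattern
# (equal pooled base frequencies, P1 = P2, transversions split evenly), the
# regime where TN93 collapses to the Jukes-Cantor closed form.
balanced_pair <- function(n_ident = 1200, m_per_type = 12) {
  stopifnot(n_ident %% 4 == 0)
  a <- rep(c("A", "C", "G", "T"), n_ident / 4)
  b <- a
  swaps <- list(c("A", "G"), c("C", "T"),   # transitions
                c("A", "C"), c("G", "T"),   # transversions, balanced
                c("A", "T"), c("C", "G"))
  pos <- 0
  extra_a <- character(0); extra_b <- character(0)
  for (sw in swaps) {
    half <- m_per_type / 2
    extra_a <- c(extra_a, rep(sw[1], half), rep(sw[2], half))
    extra_b <- c(extra_b, rep(sw[2], half), rep(sw[1], half))
  }
  list(a = paste(c(a, extra_a), collapse = ""),
       b = paste(c(b, extra_b), collapse = ""),
       p = length(extra_a) / (n_ident + length(extra_a)))
}

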