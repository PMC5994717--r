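# Repeat-element family pipeline: genomic self-matches -> pooled match
# sequences -> coverage-based MCL clustering -> center-star alignment with
# overlap trimming -> position-frequency profiles -> genome scanning with
# decoy-calibrated E-values -> overlap ownership -> densities and occurrence
# spectra.

#' Extract and pool self-match sequences across a strain set
#'
#' Runs [find_self_repeats()] on every replicon with a short anchor length,
#' chains anchors that lie on (nearly) the same diagonal within `merge_gap`
#' into diverged-copy match regions, and extracts the region sequences from
#' both sides of each match (reverse-complement matches are extracted on the
#' forward strand). Regions shorter than `min_length` are dropped; identical
#' intervals pooled more than once are kept once.
#'
#' @param replicons Replicon tibble (`replicon_id`, `strain_id`, `sequence`).
#' @param min_length Minimum pooled match-region length (bp); 65 by default,
#'   just under the shortest repeat element the pipeline is designed for.
#' @param anchor_len Minimum exact anchor length for self-matching.
#' @param merge_gap Maximum gap between chained anchors (bp).
#' @return Tibble `seq_id`, `strain_id`, `replicon_id`, `start`, `end`
#'   (0-based half-open), `sequence`.
#' @export
pool_self_matches <- function(replicons, min_length = 65, anchor_len = 15,
                              merge_gap = 90) {
  rows <- list()
  for (i in seq_len(nrow(replicons))) {
    sm <- find_self_repeats(replicons$sequence[[i]], anchor_len,
                            replicons$replicon_id[[i]])
    sm <- merge_self_matches(sm, merge_gap)
    sm <- sm[sm$end_a - sm$start_a >= min_length &
               sm$end_b - sm$start_b >= min_length, , drop = FALSE]
    if (nrow(sm) == 0) next
    sm <- extend_match_regions(sm, replicons$sequence[[i]])
    ivals <- dplyr::distinct(dplyr::bind_rows(
      tibble::tibble(start = sm$start_a, end = sm$end_a),
      tibble::tibble(start = sm$start_b, end = sm$end_b)
    ))
    rows[[length(rows) + 1]] <- tibble::tibble(
      strain_id = replicons$strain_id[[i]],
      replicon_id = replicons$replicon_id[[i]],
      start = ivals$start, end = ivals$end,
      sequence = substring(replicons$sequence[[i]], ivals$start + 1,
                           ivals$end)
    )
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(seq_id = character(0), strain_id = character(0),
                          replicon_id = character(0), start = integer(0),
                          end = integer(0), sequence = character(0)))
  }
  out <- dplyr::arrange(out, .data$replicon_id, .data$start, .data$end)
  tibble::tibble(seq_id = sprintf("rep%05d", seq_len(nrow(out))), out)
}

# Chain self-match anchors lying on (nearly) the same diagonal with gaps at
# most `merge_gap` into match regions covering diverged repeat copies.
merge_self_matches <- function(sm, merge_gap = 90, diag_tol = 10) {
  if (nrow(sm) == 0) return(sm)
  out <- list()
  for (ori in unique(sm$orientation)) {
    sub <- sm[sm$orientation == ori, , drop = FALSE]
    d <- if (ori == "forward") sub$start_b - sub$start_a else
      sub$start_a + sub$end_b
    ord <- order(d, sub$start_a)
    sub <- sub[ord, , drop = FALSE]
    d <- d[ord]
    grp <- integer(nrow(sub))
    g <- 1L
    grp[1] <- g
    for (k in seq_len(nrow(sub))[-1]) {
      same <- abs(d[k] - d[k - 1]) <= diag_tol &&
        sub$start_a[k] - max(sub$end_a[seq_len(k - 1)][grp[seq_len(k - 1)] == g]) <= merge_gap
      if (!same) g <- g + 1L
      grp[k] <- g
    }
    merged <- dplyr::summarise(
      dplyr::group_by(tibble::tibble(sub, grp = grp), .data$grp),
      replicon_id = .data$replicon_id[1],
      anchor_bp = sum(.data$length),
      start_a = min(.data$start_a), end_a = max(.data$end_a),
      start_b = min(.data$start_b), end_b = max(.data$end_b),
      length = max(.data$end_a) - min(.data$start_a),
      orientation = ori,
      identity = .data$anchor_bp / .data$length,
      .groups = "drop"
    )
    merged <- merged[, setdiff(names(merged), "anchor_bp")]
    out[[ori]] <- merged[, setdiff(names(merged), "grp")]
  }
  res <- dplyr::bind_rows(out)
  res$identity <- pmin(1, res$identity)
  dplyr::arrange(res, .data$start_a, .data$start_b)
}

# Extend merged match regions outward along their diagonal while local
# identity stays high, recovering the diverged copy edges that exact
# anchors erode. Extension stops once the trailing `window` bases fall
# below `min_frac` matches and backtracks to the last matching base.
extend_match_regions <- function(sm, sequence, max_ext = 200, window = 15,
                                 min_frac = 0.6) {
  if (nrow(sm) == 0) return(sm)
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n <- length(ch)
  step_match <- function(pa, pb, rc) {
    if (pa < 1 || pa > n || pb < 1 || pb > n) return(NA)
    b <- ch[pb]
    if (rc) b <- unname(comp[b])
    identical(ch[pa], b)
  }
  extend_dir <- function(pa0, pb0, da, db, rc) {
    hist <- logical(0)
    for (k in seq_len(max_ext)) {
      m <- step_match(pa0 + k * da, pb0 + k * db, rc)
      if (is.na(m)) break
      hist <- c(hist, m)
      recent <- utils::tail(hist, window)
      if (length(recent) >= window && mean(recent) < min_frac) break
    }
    if (length(hist) == 0) return(0L)
    # keep only an extension whose running identity stays high: matching
    # flanks extend at the copies' identity (~95%+), random flanks at ~25%
    frac <- cumsum(hist) / seq_along(hist)
    good <- which(hist & frac >= 0.75)
    if (length(good) == 0) 0L else max(good)
  }
  for (i in seq_len(nrow(sm))) {
    rc <- sm$orientation[[i]] == "revcomp"
    # left of interval a pairs with left of b (forward) or right of b (rc)
    el <- extend_dir(sm$start_a[[i]] + 1L,
                     if (rc) sm$end_b[[i]] else sm$start_b[[i]] + 1L,
                     -1L, if (rc) 1L else -1L, rc)
    er <- extend_dir(sm$end_a[[i]],
                     if (rc) sm$start_b[[i]] + 1L else sm$end_b[[i]],
                     1L, if (rc) -1L else 1L, rc)
    sm$start_a[[i]] <- sm$start_a[[i]] - el
    sm$end_a[[i]] <- sm$end_a[[i]] + er
    if (rc) {
      sm$start_b[[i]] <- sm$start_b[[i]] - er
      sm$end_b[[i]] <- sm$end_b[[i]] + el
    } else {
      sm$start_b[[i]] <- sm$start_b[[i]] - el
      sm$end_b[[i]] <- sm$end_b[[i]] + er
    }
    sm$length[[i]] <- sm$end_a[[i]] - sm$start_a[[i]]
  }
  sm
}

#' Cluster pooled repeat sequences by pairwise match coverage
#'
#' Edge weight between two pooled sequences is the fraction of the shorter
#' one covered by maximal exact matches (both orientations) to the other;
#' edges below `min_coverage` are dropped and the graph is partitioned with
#' [mcl_cluster()].
#'
#' @param pooled Tibble from [pool_self_matches()] (`seq_id`, `sequence`).
#' @param min_match Minimum exact-match length used for coverage (bp).
#' @param min_coverage Minimum coverage to keep an edge.
#' @param inflation MCL inflation; 2 by default for repeat clustering.
#' @return Tibble `seq_id`, `family_id`.
#' @export
cluster_repeat_sequences <- function(pooled, min_match = 12,
                                     min_coverage = 0.5, inflation = 2) {
  n <- nrow(pooled)
  edges <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        cov <- match_coverage(pooled$sequence[[i]], pooled$sequence[[j]],
                              min_match)
        if (cov >= min_coverage) {
          edges[[length(edges) + 1]] <- tibble::tibble(
            gene_a = pooled$seq_id[[i]], gene_b = pooled$seq_id[[j]],
            score = cov
          )
        }
      }
    }
  }
  edges <- dplyr::bind_rows(edges)
  if (nrow(edges) == 0) {
    edges <- tibble::tibble(gene_a = character(0), gene_b = character(0),
                            score = numeric(0))
  }
  memb <- mcl_cluster(edges, inflation = inflation, nodes = pooled$seq_id)
  sizes <- dplyr::count(memb, .data$cluster)
  sizes <- dplyr::arrange(sizes, dplyr::desc(.data$n), .data$cluster)
  sizes$family_id <- sprintf("RF%04d", seq_len(nrow(sizes)))
  memb <- dplyr::left_join(memb, sizes[, c("cluster", "family_id")],
                           by = "cluster")
  tibble::tibble(seq_id = memb$gene_id, family_id = memb$family_id)
}

# Fraction of the shorter sequence covered by exact matches to the other.
match_coverage <- function(a, b, min_match = 20) {
  swap <- nchar(a) > nchar(b)
  if (swap) { tmp <- a; a <- b; b <- tmp }
  mem <- maximal_exact_matches(a, b, min_length = min_match,
                               both_strands = TRUE)
  if (nrow(mem) == 0) return(0)
  iv <- IRanges::reduce(IRanges::IRanges(mem$start_a + 1, mem$end_a))
  sum(IRanges::width(iv)) / nchar(a)
}

#' Build a repeat-family profile from member sequences
#'
#' Center-star aligns the members, drops members that are poorly aligned
#' (a residue is well-aligned when at least `res_overlap` of the other
#' members carry a residue in its column; a member is kept when at least
#' `seq_overlap` percent of its residues are well-aligned), re-aligns the
#' survivors and derives a per-column base-frequency profile (pseudocount 1)
#' over the columns where fewer than half the members have a gap.
#'
#' @param member_sequences Character vector (>= 2 sequences).
#' @param res_overlap Minimum fraction of other members with a residue in a
#'   column for that residue to count as well-aligned.
#' @param seq_overlap Minimum percentage of well-aligned residues a member
#'   needs to be retained.
#' @param family_id Optional id stored on the result.
#' @return A `repeat_family` list: `family_id`, `n_members`, `profile`
#'   (4 x L frequency matrix), `consensus`, `consensus_length`, `trim_log`.
#' @export
build_family_profile <- function(member_sequences, res_overlap = 0.6,
                                 seq_overlap = 60, family_id = NA_character_) {
  assert_that(length(member_sequences) >= 2, "need >= 2 member sequences")
  aln <- center_star_align(member_sequences, type = "dna")$alignment
  keep <- trim_members(aln, res_overlap, seq_overlap)
  if (sum(keep) < 2) {
    stop(sprintf("degenerate repeat family %s: fewer than 2 members survive trimming",
                 family_id), call. = FALSE)
  }
  survivors <- member_sequences[keep]
  aln2 <- center_star_align(survivors, type = "dna")$alignment
  M <- alignment_matrix(aln2)
  gap_frac <- colMeans(M == "-")
  use <- gap_frac < 0.5
  M <- M[, use, drop = FALSE]
  L <- ncol(M)
  assert_that(L >= 1, "profile has no usable columns")
  prof <- vapply(seq_len(L), function(j) {
    counts <- table(factor(M[, j], levels = DNA_BASES)) + 1  # pseudocount
    as.numeric(counts / sum(counts))
  }, numeric(4))
  rownames(prof) <- DNA_BASES
  consensus <- paste(DNA_BASES[apply(prof, 2, which.max)], collapse = "")
  structure(list(
    family_id = family_id, n_members = length(survivors),
    profile = prof, consensus = consensus, consensus_length = L,
    trim_log = which(!keep)
  ), class = "repeat_family")
}

trim_members <- function(alignment, res_overlap, seq_overlap) {
  M <- alignment_matrix(alignment)
  m <- nrow(M)
  if (m == 2) return(rep(TRUE, 2))
  res_counts <- colSums(M != "-")
  keep <- logical(m)
  for (i in seq_len(m)) {
    cols <- which(M[i, ] != "-")
    other_frac <- (res_counts[cols] - 1) / (m - 1)
    good <- mean(other_frac >= res_overlap) * 100
    keep[i] <- good >= seq_overlap
  }
  keep
}

#' @export
print.repeat_family <- function(x, ...) {
  cat(sprintf("<repeat_family %s> %d members, consensus %d bp\n",
              x$family_id, x$n_members, x$consensus_length))
  invisible(x)
}

#' Discover repeat families across a strain set
#'
#' Full discovery arm of the repeat pipeline: self-matches pooled across all
#' replicons, coverage-based MCL clustering, then one profile per cluster
#' with >= 2 members (degenerate families are dropped and logged).
#'
#' @inheritParams pool_self_matches
#' @inheritParams cluster_repeat_sequences
#' @inheritParams build_family_profile
#' @return List of `repeat_family` objects (possibly empty), with the pooled
#'   member table in attribute `members`.
#' @export
discover_repeat_families <- function(replicons, min_length = 65,
                                     anchor_len = 15, min_match = 12,
                                     min_coverage = 0.5,
                                     inflation = 2, res_overlap = 0.6,
                                     seq_overlap = 60) {
  pooled <- pool_self_matches(replicons, min_length, anchor_len)
  if (nrow(pooled) == 0) {
    return(structure(list(), members = pooled))
  }
  clus <- cluster_repeat_sequences(pooled, min_match, min_coverage, inflation)
  pooled <- dplyr::left_join(pooled, clus, by = "seq_id")
  fams <- list()
  for (fid in sort(unique(pooled$family_id))) {
    members <- pooled$sequence[pooled$family_id == fid]
    if (length(members) < 2) next
    fam <- tryCatch(
      build_family_profile(members, res_overlap, seq_overlap, family_id = fid),
      error = function(e) NULL
    )
    if (!is.null(fam)) fams[[fid]] <- fam
  }
  structure(fams, members = pooled)
}

# ---- scanning ---------------------------------------------------------------

# Altschul-Erickson dinucleotide shuffle: preserves exact dinucleotide
# counts by walking a random Eulerian path over the transition multigraph.
dinucleotide_shuffle <- function(sequence) {
  s <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(s)
  if (n < 3) return(sequence)
  verts <- unique(s)
  last <- s[[n]]
  targets <- split(s[-1], s[-n])
  # choose random last-edge targets forming a tree into the final vertex
  repeat {
    last_edge <- vapply(verts, function(v) {
      if (v == last) return(NA_character_)
      sample(targets[[v]], 1)
    }, character(1))
    ok <- TRUE
    for (v in verts) {
      if (v == last) next
      seen <- character(0)
      cur <- v
      while (cur != last) {
        if (cur %in% seen || is.na(last_edge[[cur]])) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- last_edge[[cur]]
      }
      if (!ok) break
    }
    if (ok) break
  }
  lists <- lapply(verts, function(v) {
    tg <- targets[[v]]
    if (is.null(tg)) return(character(0))
    if (v != last) {
      le <- last_edge[[v]]
      drop_one <- match(le, tg)
      rest <- tg[-drop_one]
      c(sample(rest), le)
    } else {
      sample(tg)
    }
  })
  names(lists) <- verts
  ptr <- stats::setNames(rep(1L, length(verts)), verts)
  out <- character(n)
  out[1] <- s[1]
  cur <- s[1]
  for (i in 2:n) {
    nxt <- lists[[cur]][[ptr[[cur]]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

# Log-odds window scores of a profile along coded sequence; ambiguous bases
# contribute 0.
profile_window_scores <- function(codes, logodds) {
  L <- ncol(logodds)
  n <- length(codes)
  if (n < L) return(numeric(0))
  S <- numeric(n - L + 1)
  for (j in seq_len(L)) {
    col <- logodds[, j]
    idx <- codes[j:(n - L + j)]
    v <- numeric(length(idx))
    ok <- !is.na(idx)
    v[ok] <- col[idx[ok]]
    S <- S + v
  }
  S
}

# Merge above-threshold windows into segment hits (best window per segment).
segment_hits <- function(scores, threshold, L) {
  pos <- which(scores >= threshold)
  if (length(pos) == 0) {
    return(tibble::tibble(start = integer(0), score = numeric(0)))
  }
  grp <- cumsum(c(1L, diff(pos) > L))
  starts <- integer(max(grp)); best <- numeric(max(grp))
  for (g in seq_len(max(grp))) {
    p <- pos[grp == g]
    k <- p[which.max(scores[p])]
    starts[g] <- k
    best[g] <- scores[k]
  }
  tibble::tibble(start = starts, score = best)
}

#' Scan a replicon for repeat-family instances
#'
#' Gapless log-odds scan of every family profile along both strands, with
#' E-values calibrated on a dinucleotide-shuffled decoy of the same replicon
#' (exponential tail fitted to the decoy's top segment scores; one decoy per
#' replicon per run, seeded). Hits with `evalue <= evalue_cutoff` are
#' returned.
#'
#' @param families List of `repeat_family` objects.
#' @param sequence Replicon sequence.
#' @param replicon_id Id copied into the output.
#' @param evalue_cutoff E-value cutoff (default 1e-4).
#' @param seed Seed for the decoy shuffle.
#' @param n_tail Number of top decoy segment scores used in the tail fit.
#' @return Instance tibble: `replicon_id`, `start`, `end` (0-based
#'   half-open), `family_id`, `score` (bits), `evalue`,
#'   `identity_to_consensus`, `orientation`.
#' @export
scan_genome <- function(families, sequence, replicon_id = NA_character_,
                        evalue_cutoff = 1e-4, seed = 1, n_tail = 50) {
  empty <- tibble::tibble(
    replicon_id = character(0), start = integer(0), end = integer(0),
    family_id = character(0), score = numeric(0), evalue = numeric(0),
    identity_to_consensus = numeric(0), orientation = character(0)
  )
  if (length(families) == 0) return(empty)
  codes_f <- seq_codes(sequence)
  codes_r <- seq_codes(revcomp(sequence))
  decoy <- with_seed(seed, dinucleotide_shuffle(sequence))
  dcodes_f <- seq_codes(decoy)
  dcodes_r <- seq_codes(revcomp(decoy))
  bg <- table(factor(strsplit(sequence, "", fixed = TRUE)[[1]],
                     levels = DNA_BASES))
  bg <- pmax(as.numeric(bg) / sum(bg), 0.01)
  n <- nchar(sequence)
  out <- list()
  for (fam in families) {
    stopifnot(inherits(fam, "repeat_family"))
    W <- log2(fam$profile / bg)
    L <- ncol(W)
    if (n < L) next
    d_sc <- c(profile_window_scores(dcodes_f, W),
              profile_window_scores(dcodes_r, W))
    # independent-ish extreme values: maxima over disjoint L-wide blocks
    n_blocks <- length(d_sc) %/% L
    if (n_blocks < 10) next
    d_hits <- vapply(seq_len(n_blocks), function(b) {
      max(d_sc[((b - 1) * L + 1):(b * L)])
    }, numeric(1))
    m <- min(n_tail, length(d_hits) %/% 4)
    if (m < 5) next
    top <- sort(d_hits, decreasing = TRUE)[seq_len(m)]
    tau <- top[m]
    beta <- max(mean(top - tau), 1e-6)
    evalue_of <- function(s) m * exp(-(s - tau) / beta)
    s_min <- tau + beta * (log(m) - log(evalue_cutoff))
    for (strand in c("+", "-")) {
      codes <- if (strand == "+") codes_f else codes_r
      sc <- profile_window_scores(codes, W)
      hits <- segment_hits(sc, s_min, L)
      if (nrow(hits) == 0) next
      start0 <- hits$start - 1L  # 0-based on the scanned strand
      if (strand == "-") start0 <- n - (start0 + L)
      window <- substring(sequence, start0 + 1, start0 + L)
      if (strand == "-") window <- revcomp(window)
      idty <- vapply(window, function(w) {
        wc <- strsplit(w, "", fixed = TRUE)[[1]]
        cc <- strsplit(fam$consensus, "", fixed = TRUE)[[1]]
        mean(wc == cc)
      }, numeric(1), USE.NAMES = FALSE)
      out[[length(out) + 1]] <- tibble::tibble(
        replicon_id = replicon_id, start = start0, end = start0 + L,
        family_id = fam$family_id, score = hits$score,
        evalue = evalue_of(hits$score),
        identity_to_consensus = idty,
        orientation = ifelse(strand == "+", "forward", "revcomp")
      )
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) return(empty)
  res <- res[res$evalue <= evalue_cutoff, , drop = FALSE]
  dplyr::arrange(res, .data$start, .data$family_id)
}

#' Resolve overlapping repeat instances
#'
#' Within each maximal set of mutually overlapping instances on a replicon,
#' the best instance is kept by (1) length, (2) identity to consensus,
#' (3) score, in that order, with remaining ties broken by the lower start
#' coordinate; instances overlapping the winner are removed and the
#' procedure repeats until the interval set is pairwise disjoint.
#'
#' @param instances Instance tibble from [scan_genome()].
#' @return Non-overlapping instance tibble.
#' @export
resolve_overlaps <- function(instances) {
  if (nrow(instances) <= 1) return(instances)
  out <- list()
  for (rid in unique(instances$replicon_id)) {
    sub <- instances[instances$replicon_id == rid, , drop = FALSE]
    repeat {
      n <- nrow(sub)
      if (n <= 1) break
      ord <- order(sub$start, sub$end)
      sub <- sub[ord, , drop = FALSE]
      run_end <- cummax(sub$end)
      new_comp <- c(TRUE, sub$start[-1] >= run_end[-n])
      comp <- cumsum(new_comp)
      if (all(tabulate(comp) == 1)) break
      keep_rows <- logical(n)
      for (g in unique(comp)) {
        rows <- which(comp == g)
        if (length(rows) == 1) { keep_rows[rows] <- TRUE; next }
        cand <- sub[rows, , drop = FALSE]
        len <- cand$end - cand$start
        ord2 <- order(-len, -cand$identity_to_consensus, -cand$score,
                      cand$start)
        best <- rows[ord2[1]]
        keep_rows[best] <- TRUE
        overlap_best <- sub$start < sub$end[best] & sub$end > sub$start[best]
        survivors <- rows[!overlap_best[rows]]
        keep_rows[survivors] <- TRUE
      }
      sub <- sub[keep_rows, , drop = FALSE]
    }
    out[[rid]] <- sub
  }
  res <- dplyr::bind_rows(out)
  dplyr::arrange(res, .data$replicon_id, .data$start)
}

#' Per-replicon repeat statistics
#'
#' Densities (instances per Mb of replicon), per-class family counts and the
#' occurrence spectrum (for each family x replicon class, the number of
#' strains carrying at least one instance).
#'
#' @param instances Resolved instance tibble (`replicon_id`, `family_id`).
#' @param replicons Replicon tibble (`replicon_id`, `strain_id`,
#'   `rep_class`, `length_bp`).
#' @param strain_exclusions Strains dropped before computing statistics.
#' @return List of tibbles: `replicon_density`, `class_summary`,
#'   `family_counts`, `spectrum`.
#' @export
re_statistics <- function(instances, replicons,
                          strain_exclusions = character(0)) {
  reps <- replicons[!replicons$strain_id %in% strain_exclusions, , drop = FALSE]
  inst <- dplyr::inner_join(
    instances,
    reps[, c("replicon_id", "strain_id", "rep_class", "length_bp")],
    by = "replicon_id"
  )
  density <- dplyr::summarise(
    dplyr::group_by(
      dplyr::left_join(
        reps[, c("replicon_id", "strain_id", "rep_class", "length_bp")],
        dplyr::count(inst, .data$replicon_id),
        by = "replicon_id"
      ),
      .data$replicon_id, .data$strain_id, .data$rep_class, .data$length_bp
    ),
    n_instances = sum(.data$n, na.rm = TRUE), .groups = "drop"
  )
  density$per_mb <- density$n_instances / (density$length_bp / 1e6)
  class_summary <- dplyr::summarise(
    dplyr::group_by(density, .data$rep_class),
    mean_per_mb = mean(.data$per_mb), min_per_mb = min(.data$per_mb),
    max_per_mb = max(.data$per_mb), .groups = "drop"
  )
  family_counts <- dplyr::summarise(
    dplyr::group_by(inst, .data$rep_class),
    n_families = dplyr::n_distinct(.data$family_id), .groups = "drop"
  )
  spectrum <- occurrence_spectrum(inst)
  list(replicon_density = density, class_summary = class_summary,
       family_counts = family_counts, spectrum = spectrum)
}

# family x replicon class -> number of strains with >= 1 instance/member.
occurrence_spectrum <- function(tbl) {
  dplyr::summarise(
    dplyr::group_by(tbl, .data$family_id, .data$rep_class),
    n_strains = dplyr::n_distinct(.data$strain_id), .groups = "drop"
  )
}
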