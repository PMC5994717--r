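# All-vs-all protein similarity (k-mer seeded, gapped local alignment) and
# Markov clustering (MCL) into gene families. MCL is run independently on
# each connected component of the similarity graph; flow never crosses
# components, so the result equals a whole-graph run.

#' All-vs-all protein similarity graph
#'
#' Candidate pairs are found by shared k-mer seeding, then scored by gapped
#' local alignment (BLOSUM62, affine gaps). An edge is kept iff alignment
#' identity `>= min_identity` and the aligned span covers at least
#' `min_coverage` of the shorter protein. The retained alignment score is the
#' edge weight fed to clustering (bitscore-style weighting).
#'
#' @param genes Gene tibble with `gene_id` and `protein` columns.
#' @param kmer_size Seed k-mer length (amino acids).
#' @param min_identity Minimum fractional identity over aligned columns.
#' @param min_coverage Minimum fraction of the shorter protein covered by the
#'   local alignment.
#' @param gap_opening,gap_extension Affine gap penalties (positive costs).
#' @return Edge tibble `gene_a`, `gene_b`, `identity`, `coverage`, `score`
#'   with `gene_a < gene_b`; the full node set is kept in the `nodes`
#'   attribute.
#' @export
pairwise_similarity <- function(genes, kmer_size = 5, min_identity = 0.80,
                                min_coverage = 0.80, gap_opening = 10,
                                gap_extension = 4) {
  assert_that(all(nchar(genes$protein) > 0), "proteins must be non-empty")
  ids <- genes$gene_id
  prots <- stats::setNames(genes$protein, ids)
  cand <- seed_candidate_pairs(prots, kmer_size)
  edges <- score_pairs(cand, prots, gap_opening, gap_extension)
  if (nrow(edges) > 0) {
    edges <- edges[edges$identity >= min_identity &
                     edges$coverage >= min_coverage, , drop = FALSE]
  }
  edges <- dplyr::arrange(edges, .data$gene_a, .data$gene_b)
  attr(edges, "nodes") <- ids
  edges
}

seed_candidate_pairs <- function(prots, kmer_size) {
  tabs <- purrr::imap(prots, function(p, id) {
    n <- nchar(p)
    if (n < kmer_size) return(NULL)
    tibble::tibble(gene = id,
                   kmer = unique(substring(p, 1:(n - kmer_size + 1),
                                           kmer_size:n)))
  })
  tab <- dplyr::bind_rows(tabs)
  if (nrow(tab) == 0) {
    return(tibble::tibble(gene_a = character(0), gene_b = character(0)))
  }
  pairs <- dplyr::inner_join(tab, tab, by = "kmer",
                             relationship = "many-to-many")
  pairs <- pairs[pairs$gene.x < pairs$gene.y, c("gene.x", "gene.y")]
  names(pairs) <- c("gene_a", "gene_b")
  dplyr::distinct(pairs)
}

score_pairs <- function(pairs, prots, gap_opening, gap_extension) {
  empty <- tibble::tibble(
    gene_a = character(0), gene_b = character(0),
    identity = numeric(0), coverage = numeric(0), score = numeric(0)
  )
  if (nrow(pairs) == 0) return(empty)
  out <- vector("list", length(unique(pairs$gene_b)))
  i <- 0
  for (b in unique(pairs$gene_b)) {
    a_ids <- pairs$gene_a[pairs$gene_b == b]
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::AAStringSet(prots[a_ids]),
      subject = prots[[b]],
      type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = gap_opening, gapExtension = gap_extension
    )
    n_aa <- nchar(prots[a_ids]); n_b <- nchar(prots[[b]])
    shorter <- pmin(n_aa, n_b)
    # aligned span measured on the shorter partner of each pair
    span_pat <- Biostrings::width(Biostrings::pattern(aln)) -
      Biostrings::nindel(aln)@insertion[, "WidthSum"]
    span_sub <- Biostrings::width(Biostrings::subject(aln)) -
      Biostrings::nindel(aln)@deletion[, "WidthSum"]
    span_short <- ifelse(n_aa <= n_b, span_pat, span_sub)
    i <- i + 1
    out[[i]] <- tibble::tibble(
      gene_a = a_ids, gene_b = b,
      identity = unname(Biostrings::pid(aln, type = "PID1") / 100),
      coverage = unname(span_short / shorter),
      score = unname(Biostrings::score(aln))
    )
  }
  dplyr::bind_rows(out[seq_len(i)])
}

#' Markov clustering of a weighted similarity graph
#'
#' Classic MCL: build a column-stochastic matrix from symmetric edge weights
#' with self-loops (loop weight = the node's maximum incident edge weight, 1
#' for isolated nodes), then iterate expansion (matrix squaring) and
#' inflation (entrywise power + column renormalisation) with pruning until
#' the matrix is stable. Clusters are read off the converged attractor
#' structure; a node drawn to attractors of more than one cluster is assigned
#' to the cluster holding the largest flow (ties: larger attractor weight,
#' then smallest cluster label).
#'
#' @param edges Edge tibble (`gene_a`, `gene_b`, `score`), e.g. from
#'   [pairwise_similarity()].
#' @param inflation Inflation exponent (> 1); 10 is the package default for
#'   within-species gene clustering.
#' @param nodes Optional full node vector (isolated nodes become singleton
#'   clusters); defaults to the `nodes` attribute of `edges`, else the edge
#'   endpoints.
#' @param prune Entries below this are dropped each iteration.
#' @param tol Convergence threshold on the max entrywise change.
#' @param max_iter Iteration cap; non-convergence is an error.
#' @return Tibble `gene_id`, `cluster` (integer).
#' @export
mcl_cluster <- function(edges, inflation = 10, nodes = NULL, prune = 1e-5,
                        tol = 1e-6, max_iter = 100) {
  assert_that(inflation > 1, "inflation must be > 1")
  nodes <- nodes %||% attr(edges, "nodes") %||%
    sort(unique(c(edges$gene_a, edges$gene_b)))
  nodes <- sort(unique(nodes))
  if (length(nodes) == 0) {
    return(tibble::tibble(gene_id = character(0), cluster = integer(0)))
  }
  edges <- edges[edges$gene_a != edges$gene_b, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    edges[, c("gene_a", "gene_b")], directed = FALSE,
    vertices = data.frame(name = nodes)
  )
  comp <- igraph::components(g)$membership[nodes]
  cluster_of <- stats::setNames(integer(length(nodes)), nodes)
  next_cluster <- 0L
  for (cid in sort(unique(comp))) {
    members <- nodes[comp == cid]
    if (length(members) == 1) {
      next_cluster <- next_cluster + 1L
      cluster_of[members] <- next_cluster
      next
    }
    sub <- edges[edges$gene_a %in% members & edges$gene_b %in% members, ,
                 drop = FALSE]
    part <- mcl_component(members, sub, inflation, prune, tol, max_iter)
    cluster_of[members] <- part + next_cluster
    next_cluster <- next_cluster + max(part)
  }
  # relabel clusters deterministically by their smallest member id
  key <- vapply(split(nodes, cluster_of[nodes]), min, character(1))
  relabel <- stats::setNames(rank(key, ties.method = "first"), names(key))
  tibble::tibble(
    gene_id = nodes,
    cluster = as.integer(relabel[as.character(cluster_of[nodes])])
  )
}

mcl_component <- function(members, edges, inflation, prune, tol, max_iter) {
  n <- length(members)
  idx <- stats::setNames(seq_len(n), members)
  M <- matrix(0, n, n, dimnames = list(members, members))
  if (nrow(edges) > 0) {
    ia <- idx[edges$gene_a]; ib <- idx[edges$gene_b]
    M[cbind(ia, ib)] <- edges$score
    M[cbind(ib, ia)] <- edges$score
  }
  loop <- apply(M, 1, max)
  loop[loop <= 0] <- 1
  diag(M) <- loop
  M <- sweep(M, 2, colSums(M), "/")
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    E <- M %*% M
    E <- E^inflation
    E <- sweep(E, 2, colSums(E), "/")
    E[E < prune] <- 0
    cs <- colSums(E)
    cs[cs == 0] <- 1
    E <- sweep(E, 2, cs, "/")
    delta <- max(abs(E - M))
    M <- E
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop(sprintf("MCL did not converge in %d iterations (residual %.3g)",
                 max_iter, delta), call. = FALSE)
  }
  mcl_read_clusters(M, prune)
}

# Extract clusters from a converged MCL matrix (columns = nodes, rows =
# flow targets). Shared by the user-facing path; the test-suite oracle is an
# independent reimplementation.
mcl_read_clusters <- function(M, prune) {
  n <- ncol(M)
  attractors <- which(diag(M) > prune)
  if (length(attractors) == 0) attractors <- seq_len(n)
  # union attractors that share support in any column
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  union_ <- function(x, y) { parent[find(x)] <<- find(y) }
  for (j in seq_len(n)) {
    sup <- attractors[M[attractors, j] > prune]
    if (length(sup) > 1) for (s in sup[-1]) union_(sup[1], s)
  }
  attr_cluster <- vapply(attractors, find, integer(1))
  labels <- stats::setNames(match(attr_cluster, sort(unique(attr_cluster))),
                            attractors)
  out <- integer(n)
  for (j in seq_len(n)) {
    w <- M[attractors, j]
    if (all(w <= prune)) {
      # no attractor support: isolated converged column, own cluster
      out[j] <- if (j %in% attractors) labels[[as.character(j)]] else NA_integer_
      next
    }
    cl <- labels[as.character(attractors)]
    flow <- tapply(w, cl, sum)
    best <- names(flow)[flow == max(flow)]
    if (length(best) > 1) {
      aw <- tapply(diag(M)[attractors], cl, max)[best]
      best <- best[aw == max(aw)]
    }
    out[j] <- as.integer(min(as.integer(best)))
  }
  if (anyNA(out)) {
    miss <- which(is.na(out))
    out[miss] <- max(out, na.rm = TRUE) + seq_along(miss)
  }
  match(out, sort(unique(out)))
}

#' Cluster genes into families
#'
#' Convenience wrapper: [pairwise_similarity()] then [mcl_cluster()], with
#' deterministic family labels (families ordered by size, then by smallest
#' member id).
#'
#' @param genes Gene tibble with `gene_id`, `protein` and the bookkeeping
#'   columns `strain_id`, `rep_class`, `replicon_id`.
#' @param inflation MCL inflation (default 10 for within-species data).
#' @inheritParams pairwise_similarity
#' @return Family tibble `family_id`, `gene_id`, `strain_id`, `rep_class`,
#'   `replicon_id`.
#' @export
cluster_genes <- function(genes, kmer_size = 5, min_identity = 0.80,
                          min_coverage = 0.80, inflation = 10) {
  edges <- pairwise_similarity(genes, kmer_size, min_identity, min_coverage)
  memb <- mcl_cluster(edges, inflation = inflation, nodes = genes$gene_id)
  label_families(memb, genes)
}

label_families <- function(membership, genes) {
  memb <- dplyr::left_join(membership, genes, by = "gene_id")
  sizes <- dplyr::summarise(
    dplyr::group_by(memb, .data$cluster),
    n = dplyr::n(), key = min(.data$gene_id), .groups = "drop"
  )
  sizes <- dplyr::arrange(sizes, dplyr::desc(.data$n), .data$key)
  sizes$family_id <- sprintf("F%05d", seq_len(nrow(sizes)))
  memb <- dplyr::left_join(memb, sizes[, c("cluster", "family_id")],
                           by = "cluster")
  cols <- intersect(c("family_id", "gene_id", "strain_id", "rep_class",
                      "replicon_id"), names(memb))
  dplyr::arrange(memb[, cols], .data$family_id, .data$gene_id)
}

#' Single-copy core families
#'
#' Families with exactly one member in every strain of `strains`.
#'
#' @param families Family tibble (`family_id`, `gene_id`, `strain_id`).
#' @param strains Strain vector; defaults to all strains present.
#' @return Character vector of family ids.
#' @export
single_copy_core <- function(families, strains = NULL) {
  strains <- strains %||% sort(unique(families$strain_id))
  tab <- dplyr::count(families, .data$family_id, .data$strain_id)
  ok <- dplyr::summarise(
    dplyr::group_by(tab, .data$family_id),
    scc = all(.data$n == 1) && dplyr::n() == length(strains) &&
      setequal(.data$strain_id, strains),
    .groups = "drop"
  )
  sort(ok$family_id[ok$scc])
}
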