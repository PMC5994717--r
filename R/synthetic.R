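# Seeded synthetic multipartite genomes with machine-readable truth.
#
# The generator emulates the structure of a rhizobial strain collection: every
# strain carries a chromosome and two megaplasmid-class replicons (pSymA-like,
# pSymB-like) plus 0-3 accessory plasmids; gene families have a class-biased
# home replicon; accessory plasmids sample their content preferentially from
# the pSymA-homed non-core pool. Strains descend from per-class ancestral
# replicons (genes + intergenic background at the class G+C target) by i.i.d.
# point substitutions, so planted coordinates stay exact and both synteny and
# sequence distances are meaningful. No indels or recombination.

TAL_LABELS <- c(
  "IS3 family transposase", "IS66 family transposase",
  "site-specific integrase", "tyrosine recombinase XerC-like",
  "phage integrase family protein", "Tn3 family transposase"
)

BACKGROUND_LABELS <- c(
  "ABC transporter permease", "hypothetical protein", "MFS transporter",
  "GntR family transcriptional regulator", "nodulation protein NodD-like",
  "cytochrome c oxidase subunit", "two-component sensor histidine kinase",
  "50S ribosomal protein", "acyl-CoA dehydrogenase", "porin family protein"
)

#' Specification of a synthetic pan-genome
#'
#' @param n_families Number of gene families in the pan-genome.
#' @param core_fraction Fraction of families present in every strain.
#' @param class_placement_probs Named probabilities (chromosome/pSymA/pSymB)
#'   for a family's home replicon class; must sum to 1.
#' @param family_length_range CDS length range in bp (rounded to codons).
#' @param tal_fraction Fraction of families labelled as transposon-associated
#'   loci (their genes carry transposase/integrase-style labels).
#' @param noncore_presence_prob Per-strain presence probability of a non-core
#'   family on its home replicon.
#' @param accessory_bias Probability that an accessory-plasmid gene is drawn
#'   from the pSymA-homed non-core pool (vs any other non-core family).
#' @param genes_per_accessory Gene count per accessory plasmid.
#' @return A `pan_genome_spec` list.
#' @export
pan_genome_spec <- function(n_families = 120, core_fraction = 0.7,
                            class_placement_probs = c(chromosome = 0.5,
                                                      pSymA = 0.25,
                                                      pSymB = 0.25),
                            family_length_range = c(300, 900),
                            tal_fraction = 0.08,
                            noncore_presence_prob = 0.6,
                            accessory_bias = 0.7,
                            genes_per_accessory = 12) {
  assert_that(core_fraction >= 0 && core_fraction <= 1,
              "core_fraction must be in [0,1]")
  assert_that(tal_fraction >= 0 && tal_fraction <= 1,
              "tal_fraction must be in [0,1]")
  assert_that(abs(sum(class_placement_probs) - 1) < 1e-8,
              "class_placement_probs must sum to 1")
  assert_that(all(names(class_placement_probs) %in% MAIN_CLASSES),
              "class_placement_probs must be named by main replicon classes")
  structure(list(
    n_families = n_families, core_fraction = core_fraction,
    class_placement_probs = class_placement_probs,
    family_length_range = family_length_range,
    tal_fraction = tal_fraction,
    noncore_presence_prob = noncore_presence_prob,
    accessory_bias = accessory_bias,
    genes_per_accessory = genes_per_accessory
  ), class = "pan_genome_spec")
}

# Default per-class G+C targets in mol%, taken from replicon-class means
# typical of E. meliloti collections.
default_gc_targets <- function() {
  c(chromosome = 62.7, pSymA = 60.3, pSymB = 62.4, accessory = 59.2)
}

default_replicon_sizes <- function() {
  c(chromosome = 3e5, pSymA = 3e5, pSymB = 3e5, accessory = 8e4)
}

# Random CDS at a G+C target: ATG + GC-biased codons with stop codons
# rejected + TAA/TGA/TAG terminator.
random_cds <- function(n_codons, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  body <- character(n_codons - 2)
  i <- 1
  while (i <= length(body)) {
    codon <- paste(sample(DNA_BASES, 3, replace = TRUE, prob = p),
                   collapse = "")
    if (CODON_TABLE[[codon]] != "*") {
      body[i] <- codon
      i <- i + 1
    }
  }
  paste0("ATG", paste(body, collapse = ""), sample(c("TAA", "TGA", "TAG"), 1))
}

# Point substitutions at `rate`; replacement base drawn GC-biased among the
# three alternatives. If `codon_safe`, substitutions creating an in-frame
# stop are rejected (purifying selection against premature stops).
mutate_seq <- function(sequence, rate, gc = 0.5, codon_safe = FALSE) {
  n <- nchar(sequence)
  if (n == 0 || rate <= 0) return(sequence)
  hits <- which(stats::runif(n) < rate)
  if (length(hits) == 0) return(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  for (h in hits) {
    cur <- chars[[h]]
    if (!cur %in% DNA_BASES) next
    alt <- setdiff(DNA_BASES, cur)
    chars[[h]] <- sample(alt, 1, prob = p[alt])
  }
  if (codon_safe) {
    codon_idx <- unique((hits - 1) %/% 3)
    for (ci in codon_idx) {
      s <- ci * 3 + 1
      if (s + 2 > n) next
      codon <- paste(chars[s:(s + 2)], collapse = "")
      if (ci > 0 && identical(CODON_TABLE[[codon]], "*")) {
        orig <- substr(sequence, s, s + 2)
        chars[s:(s + 2)] <- strsplit(orig, "")[[1]]
      }
    }
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic strain set with truth tables
#'
#' Builds per-class ancestral replicons from a [pan_genome_spec()] and derives
#' `n_strains` strains by per-site point substitution at `mutation_rate`
#' (coding regions reject substitutions creating premature stops). Gene
#' families are placed on their home replicon class; non-core families are
#' present per strain with the spec's presence probability; accessory
#' plasmids (shared ancestral layouts, `n_accessory_range` per strain) sample
#' non-core families with a pSymA-homed bias. Intergenic background is i.i.d.
#' at the class G+C target.
#'
#' @param spec A [pan_genome_spec()].
#' @param n_strains Number of strains (>= 2).
#' @param mutation_rate Per-site substitution probability in `[0, 0.2]`.
#' @param gc_targets Named per-class G+C targets in mol%.
#' @param replicon_sizes Named per-class approximate replicon sizes (bp).
#' @param n_accessory_range Integer range of accessory plasmids per strain.
#' @param seed Integer seed; the whole output is deterministic given it.
#' @return A `replicon_sim` list: `genomes` (list of `replicons` and `genes`
#'   tibbles), `truth` (families / repeats / moves / blocks / gc_targets),
#'   and the echoed `config`.
#' @export
generate_strain_set <- function(spec, n_strains = 4, mutation_rate = 0.01,
                                gc_targets = default_gc_targets(),
                                replicon_sizes = default_replicon_sizes(),
                                n_accessory_range = c(0, 3), seed = 1) {
  assert_that(inherits(spec, "pan_genome_spec"), "spec must be a pan_genome_spec")
  assert_that(n_strains >= 2, "n_strains must be >= 2")
  assert_that(mutation_rate >= 0 && mutation_rate <= 0.2,
              "mutation_rate must be in [0, 0.2]")
  with_seed(seed, {
    fam <- draw_family_table(spec, gc_targets)
    layouts <- ancestral_layouts(fam, spec, gc_targets, replicon_sizes)
    strains <- sprintf("S%02d", seq_len(n_strains))
    presence <- draw_presence(fam, strains, spec)
    genomes <- assemble_strains(strains, layouts, fam, presence,
                                mutation_rate, gc_targets,
                                n_accessory_range)
    truth_families <- dplyr::select(
      genomes$genes, "gene_id", "family_id", "strain_id", "replicon_id",
      "rep_class"
    )
    truth_families <- dplyr::left_join(
      truth_families, fam[, c("family_id", "is_tal")], by = "family_id"
    )
    genes <- genomes$genes[, setdiff(names(genomes$genes), "family_id")]
    structure(list(
      genomes = list(replicons = genomes$replicons, genes = genes),
      truth = list(
        families = truth_families,
        repeat_families = tibble::tibble(family_id = character(0),
                                         consensus = character(0)),
        repeats = tibble::tibble(
          family_id = character(0), strain_id = character(0),
          replicon_id = character(0), start = integer(0), end = integer(0),
          strand = character(0), divergence = numeric(0),
          sequence = character(0)
        ),
        moves = tibble::tibble(
          family_id = character(0), gene_id = character(0),
          strain_id = character(0), from_class = character(0),
          to_class = character(0)
        ),
        blocks = tibble::tibble(
          strain_id = character(0), from_class = character(0),
          to_class = character(0), span_bp = integer(0),
          n_genes = integer(0)
        ),
        gc_targets = tibble::tibble(rep_class = names(gc_targets),
                                    gc_molpct = unname(gc_targets))
      ),
      config = list(
        spec = unclass(spec), n_strains = n_strains,
        mutation_rate = mutation_rate, gc_targets = as.list(gc_targets),
        replicon_sizes = as.list(replicon_sizes),
        n_accessory_range = n_accessory_range, seed = seed
      )
    ), class = "replicon_sim")
  })
}

draw_family_table <- function(spec, gc_targets) {
  n <- spec$n_families
  home <- sample(names(spec$class_placement_probs), n, replace = TRUE,
                 prob = spec$class_placement_probs)
  # pSymA is core-poor relative to the chromosome and pSymB, mirroring the
  # replicon biology; multipliers average to ~1 under the default placement
  is_core <- stats::runif(n) <
    spec$core_fraction * c(chromosome = 1.15, pSymA = 0.55,
                           pSymB = 1.15)[home]
  is_tal <- stats::runif(n) < spec$tal_fraction
  lens <- sample(seq(spec$family_length_range[1], spec$family_length_range[2]),
                 n, replace = TRUE)
  n_codons <- pmax(4L, lens %/% 3L)
  fam <- tibble::tibble(
    family_id = sprintf("FAM%04d", seq_len(n)),
    home_class = home, is_core = is_core, is_tal = is_tal,
    strand = sample(c("+", "-"), n, replace = TRUE),
    label = ifelse(is_tal,
                   sample(TAL_LABELS, n, replace = TRUE),
                   sample(BACKGROUND_LABELS, n, replace = TRUE))
  )
  fam$cds_anc <- vapply(seq_len(n), function(i) {
    random_cds(n_codons[[i]], gc_targets[[home[[i]]]] / 100)
  }, character(1))
  fam
}

ancestral_layouts <- function(fam, spec, gc_targets, replicon_sizes) {
  layouts <- list()
  for (cls in MAIN_CLASSES) {
    members <- fam[fam$home_class == cls, , drop = FALSE]
    members <- members[sample(nrow(members)), , drop = FALSE]
    layouts[[cls]] <- layout_one(members, replicon_sizes[[cls]],
                                 gc_targets[[cls]] / 100, cls)
  }
  # shared ancestral accessory plasmid layouts (up to 3)
  noncore <- fam[!fam$is_core, , drop = FALSE]
  for (k in 1:3) {
    w <- ifelse(noncore$home_class == "pSymA", spec$accessory_bias,
                1 - spec$accessory_bias)
    n_pick <- min(spec$genes_per_accessory, nrow(noncore))
    pick <- if (n_pick == 0) noncore[0, , drop = FALSE] else
      noncore[sample(nrow(noncore), n_pick, prob = w), , drop = FALSE]
    layouts[[paste0("acc", k)]] <- layout_one(
      pick, replicon_sizes[["accessory"]], gc_targets[["accessory"]] / 100,
      "accessory"
    )
  }
  layouts
}

# Interleave ancestral spacers and genes to hit the target size.
layout_one <- function(members, size, gc, cls) {
  gene_bp <- sum(nchar(members$cds_anc))
  n_spacers <- nrow(members) + 1
  if (gene_bp >= size) {
    stop(sprintf("sizing error: %d bp of genes exceed %d bp budget for %s",
                 gene_bp, size, cls), call. = FALSE)
  }
  spacer_len <- (size - gene_bp) %/% n_spacers
  parts <- vector("list", nrow(members) * 2 + 1)
  parts[[1]] <- list(type = "spacer", id = paste0(cls, "_sp0"),
                     seq = random_dna(spacer_len, gc), strand = "+")
  for (i in seq_len(nrow(members))) {
    parts[[2 * i]] <- list(type = "gene", id = members$family_id[[i]],
                           seq = members$cds_anc[[i]],
                           strand = members$strand[[i]])
    parts[[2 * i + 1]] <- list(type = "spacer",
                               id = sprintf("%s_sp%d", cls, i),
                               seq = random_dna(spacer_len, gc), strand = "+")
  }
  parts
}

draw_presence <- function(fam, strains, spec) {
  pres <- matrix(TRUE, nrow(fam), length(strains),
                 dimnames = list(fam$family_id, strains))
  ban <- matrix(FALSE, nrow(fam), length(strains),
                dimnames = list(fam$family_id, strains))
  nc <- which(!fam$is_core)
  for (i in nc) {
    # non-core families are structurally non-universal: one strain never
    # carries the family on any replicon (main or accessory)
    banned <- sample(length(strains), 1)
    ban[i, banned] <- TRUE
    pres[i, ] <- stats::runif(length(strains)) < spec$noncore_presence_prob
    pres[i, banned] <- FALSE
  }
  list(pres = pres, ban = ban)
}

assemble_strains <- function(strains, layouts, fam, presence, mutation_rate,
                             gc_targets, n_accessory_range) {
  rep_rows <- list()
  gene_rows <- list()
  fam_by_id <- stats::setNames(seq_len(nrow(fam)), fam$family_id)
  acc_counts <- sample(seq(n_accessory_range[1], n_accessory_range[2]),
                       length(strains), replace = TRUE)
  for (si in seq_along(strains)) {
    s <- strains[[si]]
    gene_counter <- 0
    plan <- MAIN_CLASSES
    if (acc_counts[[si]] > 0) {
      plan <- c(plan, paste0("acc", sort(sample(3, acc_counts[[si]]))))
    }
    for (key in plan) {
      cls <- if (key %in% MAIN_CLASSES) key else "accessory"
      rid <- if (cls == "accessory") paste0(s, "_", sub("acc", "pAcc", key)) else
        paste0(s, "_", cls)
      gc <- gc_targets[[cls]] / 100
      pos <- 0L
      pieces <- character(0)
      for (part in layouts[[key]]) {
        if (part$type == "gene") {
          fi <- fam_by_id[[part$id]]
          if (cls != "accessory" && !presence$pres[fi, s]) next
          if (cls == "accessory" && presence$ban[fi, s]) next
          cds <- mutate_seq(part$seq, mutation_rate, gc, codon_safe = TRUE)
          placed <- if (part$strand == "-") revcomp(cds) else cds
          gene_counter <- gene_counter + 1
          gene_rows[[length(gene_rows) + 1]] <- tibble::tibble(
            gene_id = sprintf("%s_g%04d", s, gene_counter),
            strain_id = s, replicon_id = rid, rep_class = cls,
            start = pos + 1L, end = pos + nchar(placed),
            strand = part$strand, cds = cds,
            family_id = part$id,
            labels = list(fam$label[[fi]])
          )
          pieces <- c(pieces, placed)
          pos <- pos + nchar(placed)
        } else {
          sp <- mutate_seq(part$seq, mutation_rate, gc)
          pieces <- c(pieces, sp)
          pos <- pos + nchar(sp)
        }
      }
      sequence <- paste(pieces, collapse = "")
      rep_rows[[length(rep_rows) + 1]] <- tibble::tibble(
        strain_id = s, replicon_id = rid, rep_class = cls,
        length_bp = nchar(sequence), circular = TRUE, sequence = sequence
      )
    }
  }
  genes <- dplyr::bind_rows(gene_rows)
  genes$protein <- translate_cds(genes$cds)
  genes$internal_stop <- has_internal_stop(genes$protein)
  list(replicons = dplyr::bind_rows(rep_rows), genes = genes)
}

#' @export
print.replicon_sim <- function(x, ...) {
  cat(sprintf(
    "<replicon_sim> %d strains, %d replicons, %d genes, %d planted repeats, %d moves, %d blocks\n",
    length(unique(x$genomes$replicons$strain_id)),
    nrow(x$genomes$replicons), nrow(x$genomes$genes),
    nrow(x$truth$repeats), nrow(x$truth$moves), nrow(x$truth$blocks)
  ))
  invisible(x)
}

# ---- planting ---------------------------------------------------------------

# Intergenic insertion points on a replicon, avoiding genes and previously
# planted repeat intervals (0-based offsets).
valid_insertion_points <- function(sim, rid) {
  reps <- sim$genomes$replicons
  len <- reps$length_bp[reps$replicon_id == rid]
  genes <- sim$genomes$genes
  g <- genes[genes$replicon_id == rid, , drop = FALSE]
  blocked_from <- g$start - 1L  # 0-based interval [start-1, end)
  blocked_to <- g$end
  tr <- sim$truth$repeats
  tr <- tr[tr$replicon_id == rid, , drop = FALSE]
  blocked_from <- c(blocked_from, tr$start)
  blocked_to <- c(blocked_to, tr$end)
  ok <- rep(TRUE, len + 1)
  for (i in seq_along(blocked_from)) {
    lo <- blocked_from[[i]] + 2L  # forbid strictly interior points
    hi <- blocked_to[[i]]
    if (hi >= lo) ok[lo:hi] <- FALSE
  }
  which(ok) - 1L
}

# Insert `segment` at 0-based offset `pos` of replicon `rid`, shifting gene
# and truth coordinates downstream of the insertion point.
insert_segment <- function(sim, rid, pos, segment) {
  L <- nchar(segment)
  reps <- sim$genomes$replicons
  i <- which(reps$replicon_id == rid)
  seq_old <- reps$sequence[[i]]
  assert_that(pos >= 0 && pos <= nchar(seq_old), "insertion out of range")
  g <- sim$genomes$genes
  on_rep <- g$replicon_id == rid
  if (any(on_rep & (g$start - 1L) < pos & g$end > pos)) {
    stop("placement error: insertion point lies inside a gene", call. = FALSE)
  }
  reps$sequence[[i]] <- paste0(substr(seq_old, 1, pos), segment,
                               substr(seq_old, pos + 1, nchar(seq_old)))
  reps$length_bp[[i]] <- nchar(reps$sequence[[i]])
  shift <- on_rep & (g$start - 1L) >= pos
  g$start[shift] <- g$start[shift] + L
  g$end[shift] <- g$end[shift] + L
  sim$genomes$genes <- g
  tr <- sim$truth$repeats
  tshift <- tr$replicon_id == rid & tr$start >= pos
  tr$start[tshift] <- tr$start[tshift] + L
  tr$end[tshift] <- tr$end[tshift] + L
  sim$truth$repeats <- tr
  sim$genomes$replicons <- reps
  sim
}

#' Plant a repeat-element family into a synthetic strain set
#'
#' Inserts diverged copies of a random consensus into intergenic positions of
#' every strain. The first two copies of each strain share a replicon so that
#' genomic self-comparison can discover the family; a `revcomp_fraction` of
#' copies is inserted in reverse-complement orientation. Truth rows record
#' the exact planted coordinates (0-based half-open) and sequences.
#'
#' @param sim A `replicon_sim` from [generate_strain_set()].
#' @param consensus_length Consensus length in bp (>= 66, the shortest repeat
#'   element the pipeline is designed for).
#' @param copies_per_strain Copies planted per strain.
#' @param divergence Per-site substitution probability applied to each copy.
#' @param revcomp_fraction Expected fraction of reverse-complement copies.
#' @param family_id Optional id; autonumbered `REP01`, ... otherwise.
#' @param gc G+C fraction of the consensus.
#' @param seed Integer seed.
#' @return The updated `replicon_sim`.
#' @export
plant_repeat_family <- function(sim, consensus_length = 300,
                                copies_per_strain = 4, divergence = 0.02,
                                revcomp_fraction = 0.25, family_id = NULL,
                                gc = 0.6, seed = NULL) {
  assert_that(consensus_length >= 66,
              "consensus_length must be >= 66 bp")
  assert_that(copies_per_strain >= 1, "copies_per_strain must be >= 1")
  with_seed(seed, {
    family_id <- family_id %||%
      sprintf("REP%02d", nrow(sim$truth$repeat_families) + 1)
    consensus <- random_dna(consensus_length, gc)
    strains <- unique(sim$genomes$replicons$strain_id)
    for (s in strains) {
      rids <- sim$genomes$replicons$replicon_id[
        sim$genomes$replicons$strain_id == s
      ]
      target_rids <- sample(rids, copies_per_strain, replace = TRUE)
      if (copies_per_strain >= 2) target_rids[2] <- target_rids[1]
      for (rid in target_rids) {
        copy <- mutate_seq(consensus, divergence, gc)
        strand <- if (stats::runif(1) < revcomp_fraction) "-" else "+"
        placed <- if (strand == "-") revcomp(copy) else copy
        pts <- valid_insertion_points(sim, rid)
        assert_that(length(pts) > 0,
                    paste0("no intergenic insertion point on ", rid))
        pos <- sample(pts, 1)
        sim <- insert_segment(sim, rid, pos, placed)
        sim$truth$repeats <- dplyr::bind_rows(
          sim$truth$repeats,
          tibble::tibble(
            family_id = family_id, strain_id = s, replicon_id = rid,
            start = pos, end = pos + nchar(placed), strand = strand,
            divergence = divergence, sequence = placed
          )
        )
      }
    }
    sim$truth$repeat_families <- dplyr::bind_rows(
      sim$truth$repeat_families,
      tibble::tibble(family_id = family_id, consensus = consensus)
    )
    sim
  })
}

#' Plant a translocation between replicons of one strain
#'
#' Excises a contiguous span from the donor replicon of `strain_id` and
#' inserts it at an intergenic position of the recipient replicon. The window
#' is grown to the nearest intergenic positions so that no gene is split
#' (recorded span may therefore exceed `span_bp` slightly); genes inside the
#' window move with it and their `replicon_id`/`rep_class` are updated. Other
#' strains are untouched and total gene count is conserved.
#'
#' @param sim A `replicon_sim`.
#' @param strain_id Strain to edit.
#' @param from_class,to_class Donor and recipient replicon classes.
#' @param span_bp Requested span; 0 is a no-op.
#' @param seed Integer seed.
#' @return The updated `replicon_sim`.
#' @export
plant_translocation <- function(sim, strain_id, from_class, to_class,
                                span_bp, seed = NULL) {
  if (span_bp == 0) return(sim)
  with_seed(seed, {
    reps <- sim$genomes$replicons
    donor <- reps[reps$strain_id == strain_id & reps$rep_class == from_class, ]
    recip <- reps[reps$strain_id == strain_id & reps$rep_class == to_class, ]
    assert_that(nrow(donor) >= 1, "donor replicon not found")
    assert_that(nrow(recip) >= 1, "recipient replicon not found")
    donor_id <- donor$replicon_id[[1]]
    recip_id <- recip$replicon_id[[1]]
    dlen <- donor$length_bp[[1]]
    assert_that(span_bp < dlen, "span exceeds donor replicon")
    start0 <- sample(0:(dlen - span_bp), 1)
    end0 <- start0 + span_bp
    g <- sim$genomes$genes
    on_d <- which(g$replicon_id == donor_id)
    # grow to nearest intergenic boundaries: no gene may straddle an edge
    for (i in on_d) {
      if (g$start[i] - 1L < start0 && g$end[i] > start0) start0 <- g$start[i] - 1L
      if (g$start[i] - 1L < end0 && g$end[i] > end0) end0 <- g$end[i]
    }
    seq_d <- sim$genomes$replicons$sequence[
      sim$genomes$replicons$replicon_id == donor_id
    ]
    segment <- substr(seq_d, start0 + 1, end0)
    inside <- on_d[g$start[on_d] - 1L >= start0 & g$end[on_d] <= end0]
    moved_genes <- g$gene_id[inside]
    # excise from donor
    di <- which(sim$genomes$replicons$replicon_id == donor_id)
    sim$genomes$replicons$sequence[[di]] <-
      paste0(substr(seq_d, 1, start0), substr(seq_d, end0 + 1, nchar(seq_d)))
    sim$genomes$replicons$length_bp[[di]] <-
      nchar(sim$genomes$replicons$sequence[[di]])
    span <- end0 - start0
    after <- which(g$replicon_id == donor_id & g$start - 1L >= end0)
    g$start[after] <- g$start[after] - span
    g$end[after] <- g$end[after] - span
    tr <- sim$truth$repeats
    # planted repeats inside the window move; downstream ones shift
    tin <- which(tr$replicon_id == donor_id & tr$start >= start0 &
                   tr$end <= end0)
    taf <- which(tr$replicon_id == donor_id & tr$start >= end0)
    tr$start[taf] <- tr$start[taf] - span
    tr$end[taf] <- tr$end[taf] - span
    # insert into recipient at an intergenic point
    sim$genomes$genes <- g
    sim$truth$repeats <- tr
    pts <- valid_insertion_points(sim, recip_id)
    assert_that(length(pts) > 0, "no intergenic point on recipient")
    ins <- sample(pts, 1)
    sim <- insert_segment(sim, recip_id, ins, segment)
    g <- sim$genomes$genes
    gi <- match(moved_genes, g$gene_id)
    offset <- ins - start0
    g$start[gi] <- g$start[gi] + offset
    g$end[gi] <- g$end[gi] + offset
    g$replicon_id[gi] <- recip_id
    g$rep_class[gi] <- to_class
    sim$genomes$genes <- g
    tr <- sim$truth$repeats
    tr$start[tin] <- tr$start[tin] + offset
    tr$end[tin] <- tr$end[tin] + offset
    tr$replicon_id[tin] <- recip_id
    sim$truth$repeats <- tr
    # record truth (family-level moves for the genes involved)
    fams <- sim$truth$families
    fam_of <- stats::setNames(fams$family_id, fams$gene_id)
    sim$truth$blocks <- dplyr::bind_rows(
      sim$truth$blocks,
      tibble::tibble(strain_id = strain_id, from_class = from_class,
                     to_class = to_class, span_bp = span,
                     n_genes = length(moved_genes))
    )
    if (length(moved_genes) > 0) {
      sim$truth$moves <- dplyr::bind_rows(
        sim$truth$moves,
        tibble::tibble(
          family_id = unname(fam_of[moved_genes]), gene_id = moved_genes,
          strain_id = strain_id, from_class = from_class,
          to_class = to_class
        )
      )
      tf <- sim$truth$families
      ti <- match(moved_genes, tf$gene_id)
      tf$replicon_id[ti] <- recip_id
      tf$rep_class[ti] <- to_class
      sim$truth$families <- tf
    }
    sim
  })
}

#' Plant a single-gene inter-replicon move
#'
#' Relocates one core-family gene of one strain from its home replicon class
#' to another, using the same excision/insertion machinery as
#' [plant_translocation()] with a window of exactly one gene.
#'
#' @param sim A `replicon_sim`.
#' @param strain_id Strain to edit.
#' @param from_class,to_class Donor and recipient classes.
#' @param seed Integer seed.
#' @return The updated `replicon_sim`.
#' @export
plant_gene_move <- function(sim, strain_id, from_class, to_class,
                            seed = NULL) {
  with_seed(seed, {
    fams <- sim$truth$families
    n_strains <- length(unique(fams$strain_id))
    counts <- dplyr::count(fams, .data$family_id, name = "n_members")
    core_ids <- counts$family_id[counts$n_members == n_strains]
    already <- unique(sim$truth$moves$family_id)
    cand <- fams[fams$strain_id == strain_id &
                   fams$rep_class == from_class &
                   fams$family_id %in% setdiff(core_ids, already), ,
                 drop = FALSE]
    assert_that(nrow(cand) > 0, "no movable core gene on donor class")
    pick <- cand[sample(nrow(cand), 1), ]
    g <- sim$genomes$genes
    gi <- which(g$gene_id == pick$gene_id)
    span <- g$end[gi] - (g$start[gi] - 1L)
    # force the translocation window to this exact gene
    sim2 <- plant_gene_window(sim, strain_id, from_class, to_class, gi)
    sim2
  })
}

# Internal: move exactly the gene at row index `gi` (uses current RNG state
# for the insertion point).
plant_gene_window <- function(sim, strain_id, from_class, to_class, gi) {
  g <- sim$genomes$genes
  donor_id <- g$replicon_id[[gi]]
  start0 <- g$start[[gi]] - 1L
  end0 <- g$end[[gi]]
  reps <- sim$genomes$replicons
  recip <- reps[reps$strain_id == strain_id & reps$rep_class == to_class, ]
  assert_that(nrow(recip) >= 1, "recipient replicon not found")
  recip_id <- recip$replicon_id[[1]]
  seq_d <- reps$sequence[reps$replicon_id == donor_id]
  segment <- substr(seq_d, start0 + 1, end0)
  moved <- g$gene_id[[gi]]
  di <- which(reps$replicon_id == donor_id)
  sim$genomes$replicons$sequence[[di]] <-
    paste0(substr(seq_d, 1, start0), substr(seq_d, end0 + 1, nchar(seq_d)))
  sim$genomes$replicons$length_bp[[di]] <-
    nchar(sim$genomes$replicons$sequence[[di]])
  span <- end0 - start0
  after <- which(g$replicon_id == donor_id & g$start - 1L >= end0)
  g$start[after] <- g$start[after] - span
  g$end[after] <- g$end[after] - span
  tr <- sim$truth$repeats
  taf <- which(tr$replicon_id == donor_id & tr$start >= end0)
  tr$start[taf] <- tr$start[taf] - span
  tr$end[taf] <- tr$end[taf] - span
  sim$genomes$genes <- g
  sim$truth$repeats <- tr
  pts <- valid_insertion_points(sim, recip_id)
  ins <- sample(pts, 1)
  sim <- insert_segment(sim, recip_id, ins, segment)
  g <- sim$genomes$genes
  gi2 <- match(moved, g$gene_id)
  g$start[gi2] <- ins + 1L
  g$end[gi2] <- ins + span
  g$replicon_id[gi2] <- recip_id
  g$rep_class[gi2] <- to_class
  sim$genomes$genes <- g
  fams <- sim$truth$families
  ti <- match(moved, fams$gene_id)
  sim$truth$moves <- dplyr::bind_rows(
    sim$truth$moves,
    tibble::tibble(family_id = fams$family_id[[ti]], gene_id = moved,
                   strain_id = strain_id, from_class = from_class,
                   to_class = to_class)
  )
  fams$replicon_id[ti] <- recip_id
  fams$rep_class[ti] <- to_class
  sim$truth$families <- fams
  sim
}

#' Write a synthetic strain set to disk
#'
#' Emits per-strain FASTA and GFF3, truth tables as TSV (`families.tsv`,
#' `repeats.tsv` in BED-like 0-based half-open coordinates, `moves.tsv`,
#' `blocks.tsv`, `gc_targets.tsv`) and the run configuration as YAML.
#'
#' @param sim A `replicon_sim`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_strain_set <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  reps <- sim$genomes$replicons
  for (s in unique(reps$strain_id)) {
    sub <- reps[reps$strain_id == s, ]
    write_fasta(tibble::tibble(record_id = sub$replicon_id,
                               sequence = sub$sequence),
                file.path(dir, paste0(s, ".fasta")))
    genes <- sim$genomes$genes
    write_gff3(genes[genes$strain_id == s, ],
               file.path(dir, paste0(s, ".gff3")))
  }
  readr::write_tsv(sim$truth$families, file.path(dir, "families.tsv"))
  readr::write_tsv(sim$truth$repeats[, setdiff(names(sim$truth$repeats),
                                               "sequence")],
                   file.path(dir, "repeats.tsv"))
  readr::write_tsv(sim$truth$moves, file.path(dir, "moves.tsv"))
  readr::write_tsv(sim$truth$blocks, file.path(dir, "blocks.tsv"))
  readr::write_tsv(sim$truth$gc_targets, file.path(dir, "gc_targets.tsv"))
  writeLines(yaml::as.yaml(sim$config), file.path(dir, "config.yaml"))
  invisible(dir)
}
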