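# Inter-replicon gene movement (core families absent from every
# core-replicon) and large translocations from chained synteny anchors.

#' Detect inter-replicon gene movement
#'
#' A movement candidate is a genome-core family (present in every
#' non-excluded strain) that is absent from the core-replicon of every main
#' replicon class: at least one strain carries it on a different replicon
#' class than the rest. Each event reports the modal (most frequent) member
#' class and the deviant strain/class pairs; families without a strict modal
#' majority are flagged `ambiguous` and excluded from counting helpers.
#'
#' @param families Family tibble (`family_id`, `gene_id`, `strain_id`,
#'   `rep_class`).
#' @param strain_exclusions Strains excluded from core computations.
#' @param exclude_tals Drop TAL families (ids in `tal_family_ids`).
#' @param tal_family_ids Family ids considered transposon-associated.
#' @param single_copy_only Restrict candidates to single-copy core families.
#' @return Event tibble: `family_id`, `modal_class`, `n_deviants`,
#'   `deviants` (list column of `strain_id`/`rep_class` tibbles),
#'   `is_tal_family`, `ambiguous`.
#' @export
detect_gene_movement <- function(families, strain_exclusions = character(0),
                                 exclude_tals = FALSE,
                                 tal_family_ids = character(0),
                                 single_copy_only = FALSE) {
  fams <- families[!families$strain_id %in% strain_exclusions, , drop = FALSE]
  core_ids <- core_genome_families(fams)
  if (single_copy_only) {
    core_ids <- intersect(core_ids, single_copy_core(fams))
  }
  in_core_replicon <- unique(unlist(lapply(MAIN_CLASSES, function(cls) {
    core_replicon(fams, cls)
  })))
  candidates <- setdiff(core_ids, in_core_replicon)
  if (exclude_tals) candidates <- setdiff(candidates, tal_family_ids)
  out <- purrr::map_dfr(sort(candidates), function(fid) {
    memb <- fams[fams$family_id == fid, , drop = FALSE]
    tab <- sort(table(memb$rep_class), decreasing = TRUE)
    ambiguous <- length(tab) > 1 && tab[[1]] == tab[[2]]
    modal <- names(tab)[[1]]
    dev <- dplyr::distinct(
      memb[memb$rep_class != modal, c("strain_id", "rep_class")]
    )
    tibble::tibble(
      family_id = fid,
      modal_class = if (ambiguous) NA_character_ else modal,
      n_deviants = nrow(dev),
      deviants = list(dev),
      is_tal_family = fid %in% tal_family_ids,
      ambiguous = ambiguous
    )
  })
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      family_id = character(0), modal_class = character(0),
      n_deviants = integer(0), deviants = list(),
      is_tal_family = logical(0), ambiguous = logical(0)
    )
  }
  out
}

#' Count movement events by class pair
#'
#' @param events Event tibble from [detect_gene_movement()] (ambiguous
#'   events are skipped).
#' @return Tibble `from_class` (modal), `to_class` (deviant), `n`.
#' @export
movement_class_pairs <- function(events) {
  ev <- events[!events$ambiguous, , drop = FALSE]
  if (nrow(ev) == 0) {
    return(tibble::tibble(from_class = character(0), to_class = character(0),
                          n = integer(0)))
  }
  dev <- tidyr::unnest(ev[, c("family_id", "modal_class", "deviants")],
                       "deviants")
  dplyr::count(dev, from_class = .data$modal_class,
               to_class = .data$rep_class)
}

#' Find synteny blocks between two replicons
#'
#' Exact maximal matches of length at least `anchor_min_len` (both
#' orientations) are chained greedily in query order: an anchor joins the
#' open chain when it is colinear in the chain's orientation and the gap on
#' both sides is at most `max_gap`. Block identity is the fraction of
#' matching bases over the query span, counting matches inside equal-length
#' inter-anchor gaps (the expected case under substitution-only divergence).
#' Blocks shorter than `min_block_len` on the query or below `min_identity`
#' are dropped.
#'
#' @param seq_a,seq_b Replicon sequences (a = query).
#' @param anchor_min_len Minimum anchor length (bp).
#' @param max_gap Maximum within-chain gap on either side (bp).
#' @param min_block_len Minimum query span of a reported block (bp).
#' @param min_identity Minimum block identity.
#' @return Block tibble: `block_id`, `start_a`, `end_a`, `start_b`, `end_b`
#'   (0-based half-open), `orientation`, `n_anchors`, `anchor_bp`,
#'   `identity`.
#' @export
find_synteny_blocks <- function(seq_a, seq_b, anchor_min_len = 65,
                                max_gap = 10000, min_block_len = 10000,
                                min_identity = 0.92) {
  anchors <- maximal_exact_matches(seq_a, seq_b, anchor_min_len,
                                   both_strands = TRUE)
  empty <- tibble::tibble(
    block_id = integer(0), start_a = integer(0), end_a = integer(0),
    start_b = integer(0), end_b = integer(0), orientation = character(0),
    n_anchors = integer(0), anchor_bp = integer(0), identity = numeric(0)
  )
  if (nrow(anchors) == 0) return(empty)
  blocks <- list()
  for (ori in unique(anchors$orientation)) {
    sub <- anchors[anchors$orientation == ori, , drop = FALSE]
    sub <- dplyr::arrange(sub, .data$start_a, .data$start_b)
    chains <- chain_greedy(sub, max_gap, ori)
    for (ch in chains) {
      a <- sub[ch, , drop = FALSE]
      span_a <- max(a$end_a) - min(a$start_a)
      idty <- block_identity(a, seq_a, seq_b, ori)
      blocks[[length(blocks) + 1]] <- tibble::tibble(
        start_a = min(a$start_a), end_a = max(a$end_a),
        start_b = min(a$start_b), end_b = max(a$end_b),
        orientation = ori, n_anchors = nrow(a),
        anchor_bp = sum(a$length), identity = idty
      )
    }
  }
  out <- dplyr::bind_rows(blocks)
  out <- out[(out$end_a - out$start_a) >= min_block_len &
               out$identity >= min_identity, , drop = FALSE]
  if (nrow(out) == 0) return(empty)
  out <- dplyr::arrange(out, .data$start_a, .data$start_b)
  tibble::tibble(block_id = seq_len(nrow(out)), out)
}

# Greedy colinear chaining; returns a list of index vectors into `anchors`.
chain_greedy <- function(anchors, max_gap, orientation) {
  n <- nrow(anchors)
  used <- logical(n)
  chains <- list()
  for (i in seq_len(n)) {
    if (used[i]) next
    chain <- i
    used[i] <- TRUE
    cur_ea <- anchors$end_a[i]
    cur_sb <- anchors$start_b[i]
    cur_eb <- anchors$end_b[i]
    for (j in seq_len(n)) {
      if (used[j] || j <= i) next
      gap_a <- anchors$start_a[j] - cur_ea
      if (gap_a > max_gap) break
      if (gap_a < 0) next
      if (orientation == "forward") {
        gap_b <- anchors$start_b[j] - cur_eb
        if (gap_b < 0 || gap_b > max_gap) next
      } else {
        gap_b <- cur_sb - anchors$end_b[j]
        if (gap_b < 0 || gap_b > max_gap) next
      }
      chain <- c(chain, j)
      used[j] <- TRUE
      cur_ea <- anchors$end_a[j]
      cur_sb <- anchors$start_b[j]
      cur_eb <- anchors$end_b[j]
    }
    chains[[length(chains) + 1]] <- chain
  }
  chains
}

# Matching bases over the query span: anchors count fully; equal-length
# inter-anchor gaps are compared base by base; unequal gaps count their
# matches up to the shorter side.
block_identity <- function(a, seq_a, seq_b, orientation) {
  ord <- order(a$start_a)
  a <- a[ord, , drop = FALSE]
  matched <- sum(a$length)
  if (nrow(a) > 1) {
    for (k in seq_len(nrow(a) - 1)) {
      ga_s <- a$end_a[k]; ga_e <- a$start_a[k + 1]
      if (ga_e <= ga_s) next
      if (orientation == "forward") {
        gb_s <- a$end_b[k]; gb_e <- a$start_b[k + 1]
      } else {
        gb_s <- a$end_b[k + 1]; gb_e <- a$start_b[k]
      }
      if (gb_e <= gb_s) next
      sa <- substr(seq_a, ga_s + 1, ga_e)
      sb <- substr(seq_b, gb_s + 1, gb_e)
      if (orientation == "revcomp") sb <- revcomp(sb)
      la <- nchar(sa); lb <- nchar(sb)
      l <- min(la, lb)
      if (l == 0) next
      matched <- matched +
        sum(strsplit(substr(sa, 1, l), "")[[1]] ==
              strsplit(substr(sb, 1, l), "")[[1]])
    }
  }
  span <- max(a$end_a) - min(a$start_a)
  min(1, matched / span)
}

#' Detect large inter-replicon translocations in one strain
#'
#' Regions of a query strain's replicon whose best synteny blocks lie, in a
#' majority of reference strains, on a replicon of a different class are
#' called translocations of that class into the query replicon's class.
#' Per reference, "foreign" intervals are block intervals to a different
#' class minus block intervals to the query's own class; intervals foreign
#' in more than half of the references are merged (gaps up to `max_gap`)
#' and reported when at least `min_span` long.
#'
#' @param genomes Genome list with a `replicons` tibble (`strain_id`,
#'   `replicon_id`, `rep_class`, `sequence`).
#' @param strain_id Query strain.
#' @param reference_strains Reference strain ids (>= 1).
#' @param anchor_min_len,max_gap,min_block_len,min_identity Passed to
#'   [find_synteny_blocks()].
#' @param min_span Minimum reported span (bp); 50 kb separates large events
#'   from single-gene movement.
#' @return Event tibble: `strain_id`, `replicon_id`, `from_class`,
#'   `to_class`, `start`, `end` (0-based half-open on the query replicon),
#'   `span_bp`, `n_references`.
#' @export
detect_large_translocations <- function(genomes, strain_id,
                                        reference_strains,
                                        anchor_min_len = 65, max_gap = 10000,
                                        min_block_len = 10000,
                                        min_identity = 0.90,
                                        min_span = 50000) {
  assert_that(length(reference_strains) >= 1, "need >= 1 reference strain")
  reps <- genomes$replicons
  q <- reps[reps$strain_id == strain_id, , drop = FALSE]
  events <- list()
  for (qi in seq_len(nrow(q))) {
    q_class <- q$rep_class[[qi]]
    q_len <- nchar(q$sequence[[qi]])
    per_class_refs <- list()  # foreign class -> list of IRanges per reference
    for (ref in reference_strains) {
      r <- reps[reps$strain_id == ref, , drop = FALSE]
      own <- IRanges::IRanges()
      foreign <- list()
      for (ri in seq_len(nrow(r))) {
        blocks <- find_synteny_blocks(q$sequence[[qi]], r$sequence[[ri]],
                                      anchor_min_len, max_gap,
                                      min_block_len, min_identity)
        if (nrow(blocks) == 0) next
        iv <- IRanges::IRanges(blocks$start_a + 1, blocks$end_a)
        cls <- r$rep_class[[ri]]
        if (cls == q_class) {
          own <- IRanges::reduce(c(own, iv))
        } else {
          foreign[[cls]] <- IRanges::reduce(
            c(foreign[[cls]] %||% IRanges::IRanges(), iv)
          )
        }
      }
      for (cls in names(foreign)) {
        net <- IRanges::setdiff(foreign[[cls]], own)
        if (length(net) == 0) next
        per_class_refs[[cls]] <- c(per_class_refs[[cls]] %||% list(),
                                   list(net))
      }
    }
    majority <- length(reference_strains) / 2
    for (cls in names(per_class_refs)) {
      ivs <- per_class_refs[[cls]]
      if (length(ivs) == 0) next
      cov <- IRanges::coverage(do.call(c, ivs), width = q_len)
      sl <- IRanges::slice(cov, lower = floor(majority) + 1,
                           rangesOnly = TRUE)
      sl <- IRanges::reduce(sl, min.gapwidth = max_gap)
      sl <- sl[IRanges::width(sl) >= min_span]
      if (length(sl) == 0) next
      events[[length(events) + 1]] <- tibble::tibble(
        strain_id = strain_id, replicon_id = q$replicon_id[[qi]],
        from_class = cls, to_class = q_class,
        start = IRanges::start(sl) - 1L, end = IRanges::end(sl),
        span_bp = IRanges::width(sl),
        n_references = length(ivs)
      )
    }
  }
  out <- dplyr::bind_rows(events)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      strain_id = character(0), replicon_id = character(0),
      from_class = character(0), to_class = character(0),
      start = integer(0), end = integer(0), span_bp = integer(0),
      n_references = integer(0)
    )
  }
  out
}

#' Check for TAL genes flanking translocation breakpoints
#'
#' For each event, reports whether at least one TAL gene lies within
#' `window_bp` of each breakpoint (the event's start and end coordinates on
#' the query replicon).
#'
#' @param events Event tibble from [detect_large_translocations()].
#' @param genes Gene tibble (`gene_id`, `replicon_id`, `start`, `end`).
#' @param tal_ids TAL gene ids from [flag_tals()].
#' @param window_bp Window around each breakpoint (bp).
#' @return `events` with added logical columns `tal_left`, `tal_right`,
#'   `tal_flanked` (either side).
#' @export
flanking_tal_check <- function(events, genes, tal_ids, window_bp = 5000) {
  tal <- genes[genes$gene_id %in% tal_ids, , drop = FALSE]
  near <- function(rid, pos) {
    g <- tal[tal$replicon_id == rid, , drop = FALSE]
    if (nrow(g) == 0) return(FALSE)
    any(g$end >= pos - window_bp & (g$start - 1L) <= pos + window_bp)
  }
  events$tal_left <- vapply(seq_len(nrow(events)), function(i) {
    near(events$replicon_id[[i]], events$start[[i]])
  }, logical(1))
  events$tal_right <- vapply(seq_len(nrow(events)), function(i) {
    near(events$replicon_id[[i]], events$end[[i]])
  }, logical(1))
  events$tal_flanked <- events$tal_left | events$tal_right
  events
}
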