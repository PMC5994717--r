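# Maximal exact match (MEM) discovery by k-mer seeding + per-diagonal run
# scanning. This is the anchor engine behind genomic self-comparison (repeat
# discovery), repeat-vs-repeat coverage, synteny blocks and replicon-class
# assignment. All coordinates are 0-based half-open.

# All maximal exact matches >= min_length between two sequences, forward
# orientation only. `self` drops the trivial identity diagonal and returns
# each unordered pair once (start_a < start_b).
mem_forward <- function(a, b, min_length, self = FALSE, max_occ = 64,
                        max_diagonals = 50000) {
  na <- nchar(a); nb <- nchar(b)
  empty <- tibble::tibble(
    start_a = integer(0), end_a = integer(0),
    start_b = integer(0), end_b = integer(0), length = integer(0)
  )
  if (na < min_length || nb < min_length) return(empty)
  k <- min(min_length, 24L)
  ka <- substring(a, 1:(na - k + 1), k:na)
  kb <- if (self) ka else substring(b, 1:(nb - k + 1), k:nb)
  pos_a <- split(0:(na - k), ka)
  pos_b <- if (self) pos_a else split(0:(nb - k), kb)
  shared <- intersect(names(pos_a), names(pos_b))
  shared <- shared[!stringr::str_detect(shared, "N")]
  if (length(shared) == 0) return(empty)
  ia_list <- pos_a[shared]
  ib_list <- pos_b[shared]
  keep <- lengths(ia_list) <= max_occ & lengths(ib_list) <= max_occ
  ia_list <- ia_list[keep]
  ib_list <- ib_list[keep]
  single <- lengths(ia_list) == 1L & lengths(ib_list) == 1L
  diags <- unlist(ib_list[single], use.names = FALSE) -
    unlist(ia_list[single], use.names = FALSE)
  if (any(!single)) {
    diags <- c(diags, unlist(mapply(function(ia, ib) {
      rep(ib, each = length(ia)) - rep(ia, times = length(ib))
    }, ia_list[!single], ib_list[!single], SIMPLIFY = FALSE),
    use.names = FALSE))
  }
  diags <- unique(diags)
  if (self) diags <- diags[diags > 0]
  diags <- sort(unique(diags))
  if (length(diags) > max_diagonals) {
    warning(sprintf("MEM search truncated to %d diagonals", max_diagonals))
    diags <- diags[seq_len(max_diagonals)]
  }
  ca <- seq_codes(a)
  cb <- if (self) ca else seq_codes(b)
  ca[is.na(ca)] <- -1L
  cb[is.na(cb)] <- -2L
  res <- vector("list", length(diags))
  for (ii in seq_along(diags)) {
    d <- diags[[ii]]
    # overlap of a positions i (0-based) with b position i + d
    i0 <- max(0L, -d); i1 <- min(na - 1L, nb - 1L - d)
    if (i1 - i0 + 1L < min_length) next
    m <- ca[(i0 + 1L):(i1 + 1L)] == cb[(i0 + d + 1L):(i1 + d + 1L)]
    r <- rle(m)
    len <- r$lengths
    ends <- cumsum(len)
    starts <- ends - len + 1L
    hit <- which(r$values & len >= min_length)
    if (length(hit) == 0) next
    sa <- i0 + starts[hit] - 1L
    res[[ii]] <- tibble::tibble(
      start_a = sa, end_a = sa + len[hit],
      start_b = sa + d, end_b = sa + d + len[hit],
      length = len[hit]
    )
  }
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) return(empty)
  dplyr::arrange(out, .data$start_a, .data$start_b)
}

#' Maximal exact matches between two sequences
#'
#' All maximal exact matches of length at least `min_length` between `a` and
#' `b`, in forward and (optionally) reverse-complement orientation. This is a
#' `--maxmatch`-style search: every repeated placement is reported, not a
#' single best one. Coordinates are 0-based half-open on the original
#' (forward) strands of both sequences.
#'
#' @param a,b DNA strings.
#' @param min_length Minimum match length (bp).
#' @param both_strands Also search `a` against the reverse complement of `b`.
#' @return Tibble `start_a`, `end_a`, `start_b`, `end_b`, `length`,
#'   `orientation` (`forward`/`revcomp`).
#' @export
maximal_exact_matches <- function(a, b, min_length = 20, both_strands = TRUE) {
  fwd <- mem_forward(a, b, min_length)
  fwd$orientation <- rep("forward", nrow(fwd))
  out <- fwd
  if (both_strands) {
    nb <- nchar(b)
    rc <- mem_forward(a, revcomp(b), min_length)
    if (nrow(rc) > 0) {
      rc2 <- tibble::tibble(
        start_a = rc$start_a, end_a = rc$end_a,
        start_b = nb - rc$end_b, end_b = nb - rc$start_b,
        length = rc$length, orientation = "revcomp"
      )
      out <- dplyr::bind_rows(out, rc2)
    }
  }
  dplyr::arrange(out, .data$start_a, .data$start_b)
}

#' Find repeated segments within one replicon
#'
#' Genomic self-comparison in the maxmatch/nosimplify style: all maximal
#' exact matches of length at least `min_length` between distinct positions
#' of the sequence, in both orientations, excluding the trivial
#' whole-sequence identity match. Each unordered interval pair is reported
#' once.
#'
#' @param sequence Replicon DNA string.
#' @param min_length Minimum repeat length (bp); default 65, just below the
#'   shortest repeat element expected in rhizobial genomes (66 bp).
#' @param replicon_id Optional id copied into the output.
#' @return Tibble of self matches: `replicon_id`, `start_a`, `end_a`,
#'   `start_b`, `end_b`, `length`, `orientation`, `identity` (1 for exact
#'   matches).
#' @export
find_self_repeats <- function(sequence, min_length = 65, replicon_id = NA_character_) {
  assert_that(min_length >= 10, "min_length must be >= 10")
  fwd <- mem_forward(sequence, sequence, min_length, self = TRUE)
  fwd$orientation <- rep("forward", nrow(fwd))
  n <- nchar(sequence)
  rc <- mem_forward(sequence, revcomp(sequence), min_length)
  if (nrow(rc) > 0) {
    rc <- tibble::tibble(
      start_a = rc$start_a, end_a = rc$end_a,
      start_b = n - rc$end_b, end_b = n - rc$start_b,
      length = rc$length, orientation = "revcomp"
    )
    # canonical unordered pair once; drop exact self-palindrome placements
    swap <- rc$start_b < rc$start_a
    tmp_s <- rc$start_a[swap]; tmp_e <- rc$end_a[swap]
    rc$start_a[swap] <- rc$start_b[swap]; rc$end_a[swap] <- rc$end_b[swap]
    rc$start_b[swap] <- tmp_s; rc$end_b[swap] <- tmp_e
    rc <- dplyr::distinct(rc)
    rc <- rc[!(rc$start_a == rc$start_b & rc$end_a == rc$end_b), , drop = FALSE]
  }
  out <- dplyr::bind_rows(fwd, rc)
  out <- dplyr::arrange(out, .data$start_a, .data$start_b)
  tibble::tibble(
    replicon_id = rep(replicon_id, nrow(out)),
    out,
    identity = rep(1, nrow(out))
  )
}
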