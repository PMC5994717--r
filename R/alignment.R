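# Center-star multiple alignment built on pairwise global alignment.
# Used for repeat-family profile construction (DNA) and concatenated
# single-copy-core alignments. The center is the member with the maximum
# summed pairwise alignment score; all members are merged onto the center's
# coordinate system ("once a gap, always a gap").

pairwise_global <- function(a, b, type = "dna") {
  if (type == "dna") {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -1,
                                                    baseOnly = FALSE)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
      substitutionMatrix = mat, gapOpening = 5, gapExtension = 2
    )
  } else {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 4
    )
  }
  list(
    a = as.character(Biostrings::alignedPattern(aln)),
    b = as.character(Biostrings::alignedSubject(aln)),
    score = Biostrings::score(aln)
  )
}

# Summed-score matrix for center selection.
pairwise_score_matrix <- function(seqs, type = "dna") {
  m <- length(seqs)
  S <- matrix(0, m, m)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      sc <- pairwise_global(seqs[[i]], seqs[[j]], type)$score
      S[i, j] <- sc
      S[j, i] <- sc
    }
  }
  S
}

#' Center-star multiple sequence alignment
#'
#' Aligns all sequences to the center member (the one with the highest summed
#' pairwise alignment score; ties broken by input order) and merges the
#' pairwise alignments into a single gapped matrix.
#'
#' @param seqs Character vector of sequences (>= 1).
#' @param type `"dna"` or `"protein"`.
#' @param center Optional center index override.
#' @return List: `alignment` (character vector of equal-length gapped
#'   strings, in input order), `center` (index), `score_sum` (summed
#'   center-to-member alignment score).
#' @export
center_star_align <- function(seqs, type = "dna", center = NULL) {
  m <- length(seqs)
  assert_that(m >= 1, "need at least one sequence")
  if (m == 1) {
    return(list(alignment = unname(seqs), center = 1L, score_sum = 0))
  }
  if (is.null(center)) {
    S <- pairwise_score_matrix(seqs, type)
    center <- which.max(rowSums(S))
  }
  others <- setdiff(seq_len(m), center)
  master <- seqs[[center]]           # gapped center in master coordinates
  rows <- list()                     # gapped member strings
  score_sum <- 0
  for (k in others) {
    aln <- pairwise_global(seqs[[center]], seqs[[k]], type)
    score_sum <- score_sum + aln$score
    merged <- merge_onto_master(master, aln$a, aln$b, rows)
    master <- merged$master
    rows <- merged$rows
    rows[[as.character(k)]] <- merged$new_row
  }
  alignment <- character(m)
  alignment[center] <- master
  for (k in others) alignment[k] <- rows[[as.character(k)]]
  list(alignment = alignment, center = as.integer(center),
       score_sum = score_sum)
}

# Merge a new pairwise alignment (gapped center `ca`, gapped member `cb`)
# into the running master alignment; returns updated master/rows plus the
# new member row in master coordinates.
merge_onto_master <- function(master, ca, cb, rows) {
  mch <- strsplit(master, "", fixed = TRUE)[[1]]
  ach <- strsplit(ca, "", fixed = TRUE)[[1]]
  bch <- strsplit(cb, "", fixed = TRUE)[[1]]
  out_master <- character(0)
  out_new <- character(0)
  ins_at <- integer(0)   # positions (in output) where old rows need a gap
  i <- 1; j <- 1
  nm <- length(mch); na <- length(ach)
  while (i <= nm || j <= na) {
    if (i <= nm && mch[i] == "-" && (j > na || ach[j] != "-")) {
      # master-only gap column: new member gets a gap
      out_master <- c(out_master, "-")
      out_new <- c(out_new, "-")
      i <- i + 1
    } else if (j <= na && ach[j] == "-") {
      # insertion in new member relative to center: old rows get a gap
      out_master <- c(out_master, "-")
      out_new <- c(out_new, bch[j])
      ins_at <- c(ins_at, length(out_master))
      j <- j + 1
    } else if (i <= nm && j <= na) {
      out_master <- c(out_master, mch[i])
      out_new <- c(out_new, bch[j])
      i <- i + 1
      j <- j + 1
    } else {
      stop("alignment merge ran out of columns", call. = FALSE)
    }
  }
  width <- length(out_master)
  rows <- lapply(rows, function(r) {
    rch <- strsplit(r, "", fixed = TRUE)[[1]]
    new <- character(width)
    src <- 1
    for (p in seq_len(width)) {
      if (p %in% ins_at) {
        new[p] <- "-"
      } else {
        new[p] <- rch[src]
        src <- src + 1
      }
    }
    paste(new, collapse = "")
  })
  list(master = paste(out_master, collapse = ""), rows = rows,
       new_row = paste(out_new, collapse = ""))
}

# Column matrix (members x columns) from gapped strings.
alignment_matrix <- function(alignment) {
  do.call(rbind, strsplit(alignment, "", fixed = TRUE))
}

# Drop columns containing any gap; returns gapped strings without gaps.
drop_gap_columns <- function(alignment) {
  M <- alignment_matrix(alignment)
  keep <- colSums(M == "-") == 0
  apply(M[, keep, drop = FALSE], 1, paste, collapse = "")
}
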