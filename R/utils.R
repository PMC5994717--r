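# Shared low-level helpers: sequence manipulation, coordinate conventions,
# seeded RNG scoping. Internal coordinates for repeats/synteny are 0-based
# half-open; gene models are 1-based inclusive (GFF3); conversions happen at
# the I/O boundary only.

DNA_BASES <- c("A", "C", "G", "T")

MAIN_CLASSES <- c("chromosome", "pSymA", "pSymB")
REP_CLASSES <- c(MAIN_CLASSES, "accessory")

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Integer codes A=1,C=2,G=3,T=4, N/other = NA; vectorised over one sequence.
seq_codes <- function(sequence) {
  raw <- charToRaw(sequence)
  code <- integer(length(raw))
  code[raw == charToRaw("A")] <- 1L
  code[raw == charToRaw("C")] <- 2L
  code[raw == charToRaw("G")] <- 3L
  code[raw == charToRaw("T")] <- 4L
  code[code == 0L] <- NA_integer_
  code
}

codes_to_seq <- function(codes) {
  out <- DNA_BASES[codes]
  out[is.na(out)] <- "N"
  paste(out, collapse = "")
}

# Sample a random DNA string with a given G+C fraction.
random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# Run code with a local RNG state seeded from `seed` (NULL = use current).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed deterministically; kept below 2^31.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + 7919 * k) %% 2147483647)
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
}

write_tsv_report <- function(x, path, comment = NULL) {
  if (!is.null(comment)) {
    con <- file(path, "w")
    writeLines(paste0("# ", comment), con)
    close(con)
    readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_tsv(x, path)
  }
  invisible(path)
}
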