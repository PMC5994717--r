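# FASTA / GFF3 I/O and elementary sequence statistics.
#
# File conventions: FASTA wrapped at 70 columns; GFF3 with CDS features
# carrying ID (and optionally label=) attributes, 1-based inclusive
# coordinates as per the format.

# Bacterial/standard codon table (translation table 11 shares amino-acid
# assignments with the standard code; the difference is the start-codon set).
CODON_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

START_CODONS <- c("ATG", "GTG", "TTG")

#' Read a FASTA file
#'
#' Minimal strict FASTA reader: records are returned in file order, sequences
#' are uppercased and `N` is preserved. Non-IUPAC characters or data before
#' the first header raise an error naming the offending line.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `record_id`, `sequence`.
#' @export
read_fasta <- function(path) {
  assert_that(file.exists(path), paste0("FASTA file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  ids <- character(0)
  chunks <- list()
  cur <- NULL
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (line == "") next
    if (startsWith(line, ">")) {
      id <- stringr::str_trim(sub("^>", "", line))
      id <- stringr::str_split_fixed(id, "\\s+", 2)[1, 1]
      if (id == "") stop(sprintf("malformed FASTA header at line %d", i), call. = FALSE)
      ids <- c(ids, id)
      cur <- length(ids)
      chunks[[cur]] <- character(0)
    } else {
      if (is.null(cur)) {
        stop(sprintf("sequence data before first FASTA header at line %d", i), call. = FALSE)
      }
      up <- toupper(stringr::str_trim(line))
      if (stringr::str_detect(up, "[^ACGTNRYSWKMBDHV]")) {
        stop(sprintf("non-IUPAC character in FASTA at line %d", i), call. = FALSE)
      }
      chunks[[cur]] <- c(chunks[[cur]], up)
    }
  }
  tibble::tibble(
    record_id = ids,
    sequence = vapply(chunks, paste, character(1), collapse = "")
  )
}

#' Write a FASTA file
#'
#' @param records Tibble with columns `record_id`, `sequence` (or a named
#'   character vector).
#' @param path Output path.
#' @param wrap Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, wrap = 70) {
  if (!is.data.frame(records)) {
    records <- tibble::tibble(record_id = names(records), sequence = unname(records))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$record_id[[i]]), con)
    s <- records$sequence[[i]]
    n <- nchar(s)
    if (n > 0) {
      starts <- seq(1, n, by = wrap)
      writeLines(substring(s, starts, pmin(starts + wrap - 1, n)), con)
    }
  }
  invisible(path)
}

#' G+C content of a sequence
#'
#' Fraction (G + C) / (A + C + G + T); ambiguous bases (`N` etc.) are excluded
#' from both numerator and denominator, so the value is mol% G+C over called
#' bases when multiplied by 100.
#'
#' @param sequence DNA string (vectorised).
#' @return Numeric fraction in `[0, 1]`.
#' @export
gc_content <- function(sequence) {
  gc <- stringr::str_count(sequence, "[GC]")
  at <- stringr::str_count(sequence, "[AT]")
  if (any(gc + at == 0)) {
    stop("G+C content undefined: sequence has no unambiguous bases", call. = FALSE)
  }
  gc / (gc + at)
}

#' Translate a coding sequence
#'
#' Bacterial-style translation: the terminal stop codon is dropped; internal
#' stops are rendered as `*` (use [has_internal_stop()] to flag them);
#' alternative start codons (GTG/TTG) are rendered as `M` when
#' `alt_start = TRUE`.
#'
#' @param cds DNA string (vectorised); length must be divisible by 3.
#' @param alt_start Treat GTG/TTG first codons as methionine starts.
#' @return Character vector of protein sequences.
#' @export
translate_cds <- function(cds, alt_start = TRUE) {
  vapply(cds, function(s) {
    n <- nchar(s)
    if (n %% 3 != 0) {
      stop("CDS length not divisible by 3", call. = FALSE)
    }
    if (n == 0) return("")
    codons <- substring(s, seq(1, n, 3), seq(3, n, 3))
    aa <- unname(CODON_TABLE[codons])
    aa[is.na(aa)] <- "X"
    if (alt_start && codons[1] %in% START_CODONS) aa[1] <- "M"
    if (length(aa) > 1 && aa[length(aa)] == "*") aa <- aa[-length(aa)]
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Flag proteins containing internal stop codons
#'
#' @param protein Protein string(s) as returned by [translate_cds()].
#' @return Logical vector.
#' @export
has_internal_stop <- function(protein) {
  stringr::str_detect(protein, "\\*")
}

#' Read gene models from a GFF3 file
#'
#' Extracts CDS features, slices the coding sequence from the matching FASTA
#' record (reverse-complementing minus-strand features before translation) and
#' translates it. Free-text functional tags are read from a `label=` attribute
#' (comma-separated).
#'
#' @param path Path to a GFF3 file.
#' @param fasta Tibble from [read_fasta()] whose `record_id`s cover the GFF
#'   seqids used by CDS features.
#' @return A gene tibble with columns `gene_id`, `replicon_id`, `start`,
#'   `end` (1-based inclusive), `strand`, `cds`, `protein`, `internal_stop`,
#'   `labels` (list column of character vectors).
#' @export
read_gff3 <- function(path, fasta) {
  assert_that(file.exists(path), paste0("GFF3 file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & lines != ""]
  if (length(lines) == 0) {
    return(empty_gene_tbl())
  }
  fields <- stringr::str_split_fixed(lines, "\t", 9)
  keep <- fields[, 3] == "CDS"
  fields <- fields[keep, , drop = FALSE]
  seqs <- stats::setNames(fasta$sequence, fasta$record_id)
  out <- vector("list", nrow(fields))
  for (i in seq_len(nrow(fields))) {
    seqid <- fields[i, 1]
    if (!seqid %in% names(seqs)) {
      stop(sprintf("GFF3 seqid '%s' absent from FASTA", seqid), call. = FALSE)
    }
    start <- as.integer(fields[i, 4])
    end <- as.integer(fields[i, 5])
    if (is.na(start) || is.na(end) || start < 1 || end < start ||
        end > nchar(seqs[[seqid]])) {
      stop(sprintf("CDS coordinates out of bounds on '%s': %s..%s",
                   seqid, fields[i, 4], fields[i, 5]), call. = FALSE)
    }
    strand <- fields[i, 7]
    attrs <- parse_gff_attributes(fields[i, 9])
    gene_id <- attrs[["ID"]] %||% sprintf("%s_cds%05d", seqid, i)
    cds <- substr(seqs[[seqid]], start, end)
    if (strand == "-") cds <- revcomp(cds)
    labels <- character(0)
    if (!is.null(attrs[["label"]])) {
      labels <- stringr::str_split(attrs[["label"]], ",")[[1]]
    }
    out[[i]] <- tibble::tibble(
      gene_id = gene_id, replicon_id = seqid,
      start = start, end = end, strand = strand,
      cds = cds, labels = list(labels)
    )
  }
  genes <- dplyr::bind_rows(out)
  genes$protein <- translate_cds(genes$cds)
  genes$internal_stop <- has_internal_stop(genes$protein)
  genes[, c("gene_id", "replicon_id", "start", "end", "strand",
            "cds", "protein", "internal_stop", "labels")]
}

empty_gene_tbl <- function() {
  tibble::tibble(
    gene_id = character(0), replicon_id = character(0),
    start = integer(0), end = integer(0), strand = character(0),
    cds = character(0), protein = character(0),
    internal_stop = logical(0), labels = list()
  )
}

parse_gff_attributes <- function(x) {
  if (is.na(x) || x == "" || x == ".") return(list())
  parts <- stringr::str_split(x, ";")[[1]]
  parts <- parts[parts != ""]
  kv <- stringr::str_split_fixed(parts, "=", 2)
  stats::setNames(as.list(utils::URLdecode(kv[, 2])), kv[, 1])
}

#' Write gene models to a GFF3 file
#'
#' @param genes Gene tibble (see [read_gff3()]).
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path, source = "panreplicon") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(genes) > 0) {
    labels <- vapply(genes$labels %||% rep(list(character(0)), nrow(genes)),
                     paste, character(1), collapse = ",")
    attr_col <- paste0("ID=", genes$gene_id,
                       ifelse(labels == "", "", paste0(";label=", labels)))
    writeLines(paste(genes$replicon_id, source, "CDS", genes$start, genes$end,
                     ".", genes$strand, "0", attr_col, sep = "\t"), con)
  }
  invisible(path)
}

#' Assign replicon classes by similarity to a labelled reference strain
#'
#' Each query replicon is assigned the class of the reference replicon with
#' which it shares the greatest total length of exact anchors (shared-anchor
#' -length majority vote). Small replicons with no anchor above `min_anchor`
#' to any main reference replicon are labelled `accessory`.
#'
#' @param query_replicons Replicon tibble (`replicon_id`, `sequence`).
#' @param reference_replicons Replicon tibble with `rep_class` labels.
#' @param min_anchor Minimum exact-anchor length considered (bp).
#' @return Tibble `replicon_id`, `rep_class`, `anchor_bp`.
#' @export
classify_replicons <- function(query_replicons, reference_replicons,
                               min_anchor = 100) {
  purrr::map_dfr(seq_len(nrow(query_replicons)), function(i) {
    q <- query_replicons$sequence[[i]]
    totals <- vapply(seq_len(nrow(reference_replicons)), function(j) {
      m <- maximal_exact_matches(q, reference_replicons$sequence[[j]],
                                 min_length = min_anchor)
      sum(m$length)
    }, numeric(1))
    best <- which.max(totals)
    cls <- if (length(totals) == 0 || totals[best] == 0) "accessory" else {
      reference_replicons$rep_class[[best]]
    }
    tibble::tibble(
      replicon_id = query_replicons$replicon_id[[i]],
      rep_class = cls,
      anchor_bp = if (length(totals)) totals[best] else 0
    )
  })
}
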