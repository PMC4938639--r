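#' Read a FASTA file into a sequence tibble
#'
#' Parses a (possibly line-wrapped) multi-record FASTA file. Sequences are
#' uppercased and validated against the declared alphabet: protein sequences
#' may use the 20 standard residues plus `X` (undetermined), nucleotide
#' sequences `ACGTN`. The gap character `-` is tolerated in both alphabets so
#' that alignment FASTA files load directly; use `strip_gaps = TRUE` to remove
#' it on input.
#'
#' @param path Path to a FASTA text file.
#' @param alphabet One of `"auto"`, `"protein"`, `"nucleotide"`. With
#'   `"auto"` a record whose residues all lie in `ACGTN-` is treated as
#'   nucleotide, anything else as protein.
#' @param strip_gaps Remove `-` characters from the parsed sequences.
#'
#' @return A tibble with one row per record and columns `id` (first
#'   whitespace-delimited word of the header), `description` (remainder of the
#'   header, `""` if absent) and `seq` (uppercase sequence string). An empty
#'   file yields a zero-row tibble.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "AC", "GT", ">b some description", "TTTT"), tf)
#' read_fasta(tf, alphabet = "nucleotide")
#' @export
read_fasta <- function(path, alphabet = c("auto", "protein", "nucleotide"),
                       strip_gaps = FALSE) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  nonblank <- lines[nzchar(trimws(lines))]
  if (length(nonblank) == 0L) {
    return(tibble(id = character(), description = character(),
                  seq = character()))
  }
  if (!startsWith(nonblank[[1]], ">")) {
    abort("FASTA format error: sequence line before any header")
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  seq <- toupper(as.character(set))
  names(seq) <- NULL
  if (strip_gaps) seq <- gsub("-", "", seq, fixed = TRUE)
  if (any(!nzchar(id))) abort("FASTA format error: empty record id")
  if (any(!nzchar(seq))) {
    abort(paste0("FASTA format error: empty sequence for record \"",
                 id[!nzchar(seq)][[1]], "\""))
  }
  out <- tibble(id = id, description = description, seq = seq)
  validate_alphabet(out, alphabet)
  out
}

# validation error names the record and the 1-based offending position
validate_alphabet <- function(records, alphabet) {
  if (alphabet == "auto") return(invisible(records))
  allowed <- switch(alphabet,
    protein    = c(AA20, "X", "-"),
    nucleotide = c("A", "C", "G", "T", "N", "-"))
  for (i in seq_len(nrow(records))) {
    ch <- seq_chars(records$seq[[i]])
    bad <- which(!ch %in% allowed)
    if (length(bad)) {
      abort(sprintf(
        "invalid %s residue '%s' in record \"%s\" at position %d",
        alphabet, ch[bad[[1]]], records$id[[i]], bad[[1]]))
    }
  }
  invisible(records)
}

#' Write a sequence tibble to FASTA
#'
#' @param records Tibble with columns `id`, `seq` and optionally
#'   `description`.
#' @param path Output file path.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  desc <- if ("description" %in% names(records)) records$description else ""
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- if (nzchar(desc[[min(i, length(desc))]])) {
      paste0(">", records$id[[i]], " ", desc[[min(i, length(desc))]])
    } else {
      paste0(">", records$id[[i]])
    }
    writeLines(hdr, con)
    s <- records$seq[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Translate a nucleotide sequence in all six reading frames
#'
#' Standard genetic code; the trailing partial codon of each frame is
#' dropped; any codon containing `N` translates to `X`; stop codons are
#' rendered `*` and do not terminate the translation. Minus frames translate
#' the reverse complement, so frame `-1` starts at the last base of the input
#' (BLAST convention).
#'
#' @param dna Nucleotide string over `ACGTN` (case-insensitive).
#' @return A named character vector of six proteins, names
#'   `"+1","+2","+3","-1","-2","-3"`.
#' @examples
#' six_frame_translate("ATGGCC")
#' @export
six_frame_translate <- function(dna) {
  dna <- toupper(dna)
  fwd <- Biostrings::DNAString(dna)
  rev <- Biostrings::reverseComplement(fwd)
  one <- function(x, off) {
    n <- length(x) - off
    n <- n - n %% 3L
    if (n <= 0L) return("")
    as.character(Biostrings::translate(
      Biostrings::subseq(x, start = off + 1L, width = n),
      if.fuzzy.codon = "X"))
  }
  out <- c(one(fwd, 0L), one(fwd, 1L), one(fwd, 2L),
           one(rev, 0L), one(rev, 1L), one(rev, 2L))
  names(out) <- c("+1", "+2", "+3", "-1", "-2", "-3")
  out
}

#' Write features as GFF3
#'
#' @param features Data frame with columns `seqid`, `source`, `type`,
#'   `start`, `end` (1-based inclusive, per GFF3), and optionally `score`,
#'   `strand`, `attributes` (character, already in `key=value` form or plain
#'   text; reserved characters are percent-encoded).
#' @param path Optional file to write to.
#' @return The GFF3 text as a character vector of lines (invisibly when
#'   `path` is given).
#' @export
write_gff3 <- function(features, path = NULL) {
  header <- "##gff-version 3"
  if (is.null(features) || nrow(features) == 0L) {
    out <- header
  } else {
    stopifnot(all(c("seqid", "source", "type", "start", "end") %in%
                    names(features)))
    if (any(features$start > features$end)) {
      abort("GFF3 error: start > end")
    }
    score  <- features$score %||% rep(".", nrow(features))
    strand <- features$strand %||% rep(".", nrow(features))
    attrs  <- features$attributes %||% rep(".", nrow(features))
    score[is.na(score)] <- "."
    body <- sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%s\t.\t%s",
                    gff3_escape(features$seqid), gff3_escape(features$source),
                    features$type, as.integer(features$start),
                    as.integer(features$end), as.character(score), strand,
                    gff3_escape_attr(attrs))
    out <- c(header, body)
  }
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

# percent-encode GFF3 reserved characters in free-text fields
gff3_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub("\t", "%09", x, fixed = TRUE)
  gsub(" ", "%20", x, fixed = TRUE)
}

gff3_escape_attr <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub("\t", "%09", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  gsub(",", "%2C", x, fixed = TRUE)
}

#' Convert motif hits to GFF3 feature rows
#'
#' Internal hit coordinates are 0-based half-open; GFF3 is 1-based inclusive,
#' so a hit on `[start, end)` becomes `start + 1 .. end`.
#'
#' @param hits A hit tibble from [scan_pattern()] (columns `id`,
#'   `pattern`, `start`, `end`).
#' @return A feature tibble suitable for [write_gff3()].
#' @export
hits_to_gff3 <- function(hits) {
  tibble(seqid = hits$id, source = "mucinscan",
         type = "protein_match",
         start = hits$start + 1L, end = hits$end,
         score = NA_character_, strand = ".",
         attributes = paste0("Name=", hits$pattern))
}
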