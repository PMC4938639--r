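#' Compile a variable-gap residue-class pattern
#'
#' Parses PROSITE-style motif notation into a gap pattern object. The grammar:
#' a single letter is a literal residue; `[...]` is a residue class; `X(n)` a
#' fixed-length wildcard run; `X(m,n)` a ranged wildcard run; a bare `X` is
#' `X(1)`; `-` separators are optional and ignored. Undetermined residues
#' (`X`) in a *subject* sequence never satisfy any element, wildcard
#' included, so undetermined stretches cannot create motifs.
#'
#' @param text Pattern notation, e.g. `"P[ED][ED][ST][ST][ST]"` or
#'   `"C-X(2)-G-X(9)-C"` or `"C-X(13,20)-C"`.
#' @param name Name to attach to hits from this pattern.
#' @return An object of class `gap_pattern`: a list with `name` and
#'   `elements`, a tibble with columns `residues` (list of allowed residues,
#'   `NA` for wildcard), `min`, `max`.
#' @examples
#' parse_pattern("P[ED][ED][ST][ST][ST]", "pattern1")
#' @export
parse_pattern <- function(text, name = "pattern") {
  if (is.null(text) || !nzchar(text)) abort("empty pattern")
  chars <- seq_chars(text)
  n <- length(chars)
  i <- 1L
  residues <- list(); mins <- integer(); maxs <- integer()
  perr <- function(msg, pos) {
    abort(sprintf("pattern parse error at position %d: %s", pos, msg))
  }
  while (i <= n) {
    ch <- chars[[i]]
    if (ch == "-") { i <- i + 1L; next }
    if (ch == "[") {
      j <- i + 1L
      cls <- character()
      while (j <= n && chars[[j]] != "]") {
        if (!chars[[j]] %in% AA20) {
          perr(sprintf("'%s' is not one of the 20 amino acids", chars[[j]]), j)
        }
        cls <- c(cls, chars[[j]])
        j <- j + 1L
      }
      if (j > n) perr("unbalanced '['", i)
      if (length(cls) == 0L) perr("empty residue class", i)
      residues <- c(residues, list(unique(cls)))
      mins <- c(mins, 1L); maxs <- c(maxs, 1L)
      i <- j + 1L
    } else if (ch == "X") {
      if (i < n && chars[[i + 1L]] == "(") {
        j <- i + 2L
        num <- ""
        while (j <= n && chars[[j]] != ")") { num <- paste0(num, chars[[j]]); j <- j + 1L }
        if (j > n) perr("unbalanced '('", i + 1L)
        parts <- strsplit(num, ",", fixed = TRUE)[[1]]
        if (!length(parts) %in% 1:2 ||
            any(!grepl("^\\s*[0-9]+\\s*$", parts))) {
          perr(sprintf("bad wildcard run '%s'", num), i)
        }
        lo <- as.integer(trimws(parts[[1]]))
        hi <- if (length(parts) == 2L) as.integer(trimws(parts[[2]])) else lo
        if (hi < lo) perr(sprintf("wildcard range %d > %d", lo, hi), i)
        residues <- c(residues, list(NA_character_))
        mins <- c(mins, lo); maxs <- c(maxs, hi)
        i <- j + 1L
      } else {
        residues <- c(residues, list(NA_character_))
        mins <- c(mins, 1L); maxs <- c(maxs, 1L)
        i <- i + 1L
      }
    } else if (ch %in% AA20) {
      residues <- c(residues, list(ch))
      mins <- c(mins, 1L); maxs <- c(maxs, 1L)
      i <- i + 1L
    } else {
      perr(sprintf("unexpected character '%s'", ch), i)
    }
  }
  if (length(mins) == 0L) abort("empty pattern")
  structure(list(name = name,
                 elements = tibble(residues = residues,
                                   min = mins, max = maxs)),
            class = "gap_pattern")
}

#' @export
print.gap_pattern <- function(x, ...) {
  cat("<gap_pattern> ", x$name, ": ", nrow(x$elements), " elements, match length ",
      sum(x$elements$min), "..", sum(x$elements$max), "\n", sep = "")
  invisible(x)
}

#' Built-in motif patterns
#'
#' Named patterns shipped with the package: `"pattern1"`, the
#' `P[ED][ED][ST][ST][ST]` motif conserved in the PTS repeat region of Muc68E
#' proteins (a generalization of the PEEST motif); `"peest"`, the literal
#' PEEST string; `"cbt2_strict"`, the chitin-binding type-2 / peritrophin-A
#' motif `CX(2)GX(9)CX(5)CX(9)CX(5)WX(6)CX(6)C` characteristic of Muc68E;
#' and `"perA_general"`, the relaxed six-cysteine peritrophin-A motif
#' `CX(13,20)CX(5,6)CX(9,19)CX(10,14)CX(4,14)C`.
#'
#' @param name One of `"pattern1"`, `"peest"`, `"cbt2_strict"`,
#'   `"perA_general"`, or arbitrary pattern text (compiled on the fly).
#' @return A `gap_pattern`.
#' @export
muc_pattern <- function(name) {
  if (inherits(name, "gap_pattern")) return(name)
  builtin <- c(
    pattern1     = "P[ED][ED][ST][ST][ST]",
    peest        = "PEEST",
    cbt2_strict  = "C-X(2)-G-X(9)-C-X(5)-C-X(9)-C-X(5)-W-X(6)-C-X(6)-C",
    perA_general = "C-X(13,20)-C-X(5,6)-C-X(9,19)-C-X(10,14)-C-X(4,14)-C")
  if (name %in% names(builtin)) {
    parse_pattern(builtin[[name]], name)
  } else {
    parse_pattern(name, name)
  }
}

# encode residues; X, gaps and anything non-standard get code 0 and never match
aa_codes <- function(seq) {
  m <- match(seq_chars(seq), AA20)
  m[is.na(m)] <- 0L
  m
}

# all match end positions (0-based, exclusive) for a match of elements j..end
# beginning at 0-based position pos; codes = encoded subject, okx = logical
# "matchable position" vector
scan_ends <- function(codes, okx, elems_res, elems_min, elems_max, j, pos) {
  if (j > length(elems_min)) return(pos)
  n <- length(codes)
  res <- elems_res[[j]]
  if (!is.na(res[[1]])) {               # residue class, width 1
    if (pos >= n || !okx[pos + 1L]) return(integer())
    if (!AA20[codes[pos + 1L]] %in% res) return(integer())
    return(scan_ends(codes, okx, elems_res, elems_min, elems_max, j + 1L, pos + 1L))
  }
  # wildcard run: every spanned position must be a determinate residue
  out <- integer()
  hi <- min(elems_max[[j]], n - pos)
  lo <- elems_min[[j]]
  if (lo > hi && lo > 0L) return(integer())
  for (l in lo:hi) {
    if (l > 0L && !all(okx[(pos + 1L):(pos + l)])) break
    out <- c(out, scan_ends(codes, okx, elems_res, elems_min, elems_max,
                            j + 1L, pos + l))
  }
  unique(out)
}

#' Scan sequences for a variable-gap pattern
#'
#' Reports every distinct `(start, end)` interval for which some assignment
#' of wildcard lengths matches the pattern. Overlapping hits are reported;
#' coordinates are 0-based half-open. `X` in the subject never matches any
#' element.
#'
#' @param records A sequence tibble (columns `id`, `seq`) as returned by
#'   [read_fasta()], or a single sequence string.
#' @param pattern A `gap_pattern`, a built-in pattern name, or pattern text
#'   (see [muc_pattern()]).
#' @return A tibble with columns `id`, `pattern`, `start`, `end`, `matched`,
#'   sorted by `id`, `start`, `end`.
#' @examples
#' scan_pattern("APEESTSQ", "pattern1")
#' @export
scan_pattern <- function(records, pattern) {
  pattern <- muc_pattern(pattern)
  records <- as_seq_tbl(records)
  out <- purrr::map(seq_len(nrow(records)), function(i) {
    h <- scan_one(records$seq[[i]], pattern)
    if (nrow(h)) h$id <- records$id[[i]]
    h
  })
  out <- bind_rows(out)
  if (nrow(out) == 0L) {
    return(tibble(id = character(), pattern = character(),
                  start = integer(), end = integer(), matched = character()))
  }
  arrange(select(out, "id", "pattern", "start", "end", "matched"),
          .data$id, .data$start, .data$end)
}

# accept a bare string or a data frame of sequences
as_seq_tbl <- function(records) {
  if (is.character(records)) {
    ids <- names(records) %||% paste0("seq", seq_along(records))
    return(tibble(id = ids, seq = unname(records)))
  }
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  as_tibble(records)
}

scan_one <- function(seq, pattern) {
  codes <- aa_codes(seq)
  okx <- codes > 0L
  n <- length(codes)
  lmin <- sum(pattern$elements$min)
  empty <- tibble(pattern = character(), start = integer(),
                  end = integer(), matched = character())
  if (n < lmin || lmin == 0L) return(empty)
  fixed <- all(pattern$elements$min == pattern$elements$max)
  starts <- integer(); ends <- integer()
  if (fixed) {
    # fully vectorized sliding-window check for fixed-width patterns
    L <- lmin
    ns <- n - L + 1L
    ok <- rep(TRUE, ns)
    cumx <- cumsum(!okx)
    ok <- ok & (cumx[seq_len(ns) + L - 1L] -
                  c(0L, cumx)[seq_len(ns)]) == 0L
    off <- 0L
    for (j in seq_len(nrow(pattern$elements))) {
      res <- pattern$elements$residues[[j]]
      w <- pattern$elements$min[[j]]
      if (!is.na(res[[1]])) {
        memb <- codes %in% match(res, AA20)
        ok <- ok & memb[seq_len(ns) + off]
      }
      off <- off + w
    }
    starts <- which(ok) - 1L
    ends <- starts + L
  } else {
    er <- pattern$elements$residues
    em <- pattern$elements$min
    ex <- pattern$elements$max
    for (s in 0:(n - lmin)) {
      e <- scan_ends(codes, okx, er, em, ex, 1L, s)
      if (length(e)) {
        starts <- c(starts, rep(s, length(e)))
        ends <- c(ends, sort(e))
      }
    }
  }
  if (length(starts) == 0L) return(empty)
  tibble(pattern = pattern$name, start = starts, end = ends,
         matched = substring(seq, starts + 1L, ends))
}

#' Count pattern occurrences per sequence
#'
#' An occurrence is a distinct match *start* position: a start with several
#' end variants (possible under ranged wildcards) counts once.
#'
#' @inheritParams scan_pattern
#' @return A tibble with columns `id`, `count`.
#' @export
count_occurrences <- function(records, pattern) {
  pattern <- muc_pattern(pattern)
  records <- as_seq_tbl(records)
  hits <- scan_pattern(records, pattern)
  counts <- summarise(group_by(hits, .data$id),
                      count = length(unique(.data$start)), .groups = "drop")
  out <- tibble(id = records$id)
  out$count <- counts$count[match(out$id, counts$id)]
  out$count[is.na(out$count)] <- 0L
  out
}

#' Screen a proteome for multi-occurrence proteins
#'
#' Returns the proteins in which the pattern occurs strictly more than
#' `min_count` times (distinct starts), sorted by count descending with ties
#' broken lexicographically by id. This is the screen used to ask which
#' proteins carry a motif "more than twice".
#'
#' @inheritParams scan_pattern
#' @param min_count Retain proteins with `count > min_count`; must be >= 0.
#' @return A tibble with columns `id`, `count`.
#' @export
screen_proteome <- function(records, pattern, min_count = 2L) {
  if (min_count < 0) abort("min_count must be >= 0")
  records <- as_seq_tbl(records)
  if (nrow(records) == 0L) abort("empty proteome")
  counts <- count_occurrences(records, pattern)
  out <- filter(counts, .data$count > min_count)
  arrange(out, desc(.data$count), .data$id)
}
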