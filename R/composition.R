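#' Serine/threonine fraction of a protein
#'
#' Fraction of residues in `{S, T}` (optionally `{P, S, T}`); undetermined
#' `X` residues count in the denominator, giving a conservative estimate.
#'
#' @inheritParams estimate_period
#' @param include_proline Also count prolines (P+S+T fraction).
#' @return Fraction in `[0, 1]`.
#' @examples
#' st_fraction("PAST")
#' @export
st_fraction <- function(protein, include_proline = FALSE) {
  seq <- single_seq(protein)
  if (!nzchar(seq)) abort("empty protein")
  ch <- seq_chars(seq)
  set <- if (include_proline) c("P", "S", "T") else c("S", "T")
  sum(ch %in% set) / length(ch)
}

#' Sliding-window residue composition
#'
#' Fraction of residues belonging to `residues` in every window of length
#' `window` at step 1. Used to localize the PTS-rich region.
#'
#' @inheritParams estimate_period
#' @param window Window length (must be `>= 1` and `<=` protein length).
#' @param residues Character vector of residues to count.
#' @return A tibble with columns `start` (0-based window start) and
#'   `fraction`; `length(seq) - window + 1` rows.
#' @export
sliding_composition <- function(protein, window, residues = c("P", "S", "T")) {
  seq <- single_seq(protein)
  n <- nchar(seq)
  if (window <= 0L) abort("window must be positive")
  if (window > n) abort("window longer than protein")
  hit <- as.integer(seq_chars(seq) %in% residues)
  cs <- c(0L, cumsum(hit))
  starts <- 0:(n - window)
  tibble(start = starts,
         fraction = (cs[starts + window + 1L] - cs[starts + 1L]) / window)
}

#' Positions of candidate translation-start methionines
#'
#' @inheritParams estimate_period
#' @return Ascending 1-based positions of `M`; empty (with a warning) when
#'   the protein has none.
#' @export
find_start_candidates <- function(protein) {
  seq <- single_seq(protein)
  pos <- which(seq_chars(seq) == "M")
  if (length(pos) == 0L) warn("protein contains no methionine")
  pos
}

#' Hydropathy-based signal-peptide heuristic
#'
#' A transparent stand-in for a signal-peptide predictor: the score is the
#' maximum mean Kyte-Doolittle hydropathy over all windows of length
#' `window` lying within residues 3..25 of the candidate N-terminus, and the
#' call is positive when the score reaches `threshold`. This captures the
#' hydrophobic h-region of a classical signal peptide; it is a declared
#' heuristic, not a re-implementation of a trained predictor, and
#' externally computed calls can be supplied to [classify_mucin()] instead.
#' `X` residues contribute a hydropathy of 0.
#'
#' @param nterm N-terminal segment starting at the candidate initiator
#'   methionine (the first ~30 residues; at least 12 required for a call).
#' @param window Hydropathy window length.
#' @param threshold Score at or above which the call is positive.
#' @return A list with `score` and `call`.
#' @examples
#' signal_peptide_score(paste0("M", strrep("L", 29)))
#' @export
signal_peptide_score <- function(nterm, window = 8L, threshold = 1.6) {
  seq <- single_seq(nterm)
  ch <- head(seq_chars(seq), 30L)
  if (length(ch) < 12L) {
    warn("N-terminal segment shorter than 12 residues; no signal call")
    return(list(score = NA_real_, call = FALSE))
  }
  h <- unname(KD_SCALE[ch])
  h[is.na(h)] <- 0                      # X and gaps
  lo <- 3L; hi <- min(25L, length(h))
  if (hi - window + 1L < lo) {
    warn("hydropathy window does not fit in residues 3..25; no signal call")
    return(list(score = NA_real_, call = FALSE))
  }
  starts <- lo:(hi - window + 1L)
  means <- vapply(starts, function(s) mean(h[s:(s + window - 1L)]), numeric(1))
  score <- max(means)
  list(score = score, call = score >= threshold)
}

#' Reconcile the translation start with the signal-peptide heuristic
#'
#' Walks the methionines in the first `max_start` residues in ascending
#' order and returns the first whose downstream segment yields a positive
#' signal-peptide call. When none qualifies, the first methionine is
#' returned flagged `signal = FALSE`. This mirrors the reconciliation by
#' which an internal methionine (position 24 in D. melanogaster Muc68E) is
#' identified as the true initiator because only from there is a signal
#' peptide predicted.
#'
#' @inheritParams estimate_period
#' @inheritParams signal_peptide_score
#' @param max_start Only methionines within the first `max_start` residues
#'   are considered.
#' @return A list with `start` (1-based position, always holding `M`),
#'   `signal` (logical), `score`.
#' @export
reconcile_start <- function(protein, max_start = 60L, window = 8L,
                            threshold = 1.6) {
  seq <- single_seq(protein)
  mets <- find_start_candidates(seq)
  if (length(mets) == 0L) abort("protein contains no methionine")
  cand <- mets[mets <= max_start]
  if (length(cand) == 0L) cand <- mets[[1]]
  for (m in cand) {
    sp <- suppressWarnings(
      signal_peptide_score(substring(seq, m, m + 29L), window, threshold))
    if (isTRUE(sp$call)) {
      return(list(start = m, signal = TRUE, score = sp$score))
    }
  }
  sp1 <- suppressWarnings(
    signal_peptide_score(substring(seq, mets[[1]], mets[[1]] + 29L),
                         window, threshold))
  list(start = mets[[1]], signal = FALSE, score = sp1$score)
}

#' Classify a protein against the mucin criteria
#'
#' Applies the operational mucin definition: at least 25% of residues are
#' serine or threonine, a signal peptide is present (heuristic or externally
#' supplied call), and a tandem PTS repeat region occupies between 30% and
#' 90% of the protein length. Proteins passing the composition and signal
#' criteria but with repeat occupancy outside `[0.30, 0.90]` (or no
#' detectable repeat region) are called `mucin-related`; everything else
#' `non-mucin`. Chitin-binding (CBT2/PerA) domain counts are reported but
#' not required — only a minority of mucins carry one.
#'
#' @inheritParams estimate_period
#' @param region A `repeat_region`, `NULL`, or missing to auto-detect with
#'   [find_repeat_region()] defaults.
#' @param signal Optional externally computed signal-peptide call (logical);
#'   default uses [reconcile_start()].
#' @param st_cutoff Ser/Thr composition cut-off (default 0.25).
#' @param occupancy Length-2 numeric: admissible repeat-occupancy range.
#' @param include_proline Apply the composition cut-off to P+S+T instead of
#'   S+T.
#' @return A one-row tibble: `id`, `st_fraction`, `repeat_fraction`,
#'   `signal`, `start` (chosen initiator), `n_pattern1`, `n_cbt2_strict`,
#'   `n_perA_general`, `label`.
#' @export
classify_mucin <- function(protein, region, signal = NULL,
                           st_cutoff = 0.25, occupancy = c(0.30, 0.90),
                           include_proline = FALSE) {
  tb <- if (is.character(protein) && length(protein) == 1L) {
    tibble(id = names(protein) %||% "protein", seq = unname(protein))
  } else {
    as_seq_tbl(protein)
  }
  if (nrow(tb) != 1L) abort("classify_mucin takes a single protein")
  seq <- toupper(tb$seq[[1]])
  if (!nzchar(seq)) abort("empty protein")
  if (missing(region)) region <- find_repeat_region(seq)
  stf <- st_fraction(seq, include_proline = include_proline)
  rf <- if (is.null(region)) 0 else repeat_fraction(seq, region)
  if (is.null(signal)) {
    rs <- tryCatch(reconcile_start(seq), error = function(e) NULL)
    signal <- !is.null(rs) && rs$signal
    start <- if (is.null(rs)) NA_integer_ else rs$start
  } else {
    start <- NA_integer_
  }
  n_p1   <- count_occurrences(tibble(id = "q", seq = seq), "pattern1")$count
  n_cbt2 <- count_occurrences(tibble(id = "q", seq = seq), "cbt2_strict")$count
  n_perA <- count_occurrences(tibble(id = "q", seq = seq), "perA_general")$count
  in_range <- !is.null(region) && rf >= occupancy[[1]] && rf <= occupancy[[2]]
  label <- if (stf >= st_cutoff && signal && in_range) {
    "mucin"
  } else if (stf >= st_cutoff && signal) {
    "mucin-related"
  } else {
    "non-mucin"
  }
  tibble(id = tb$id[[1]], st_fraction = stf, repeat_fraction = rf,
         signal = signal, start = start,
         n_pattern1 = n_p1, n_cbt2_strict = n_cbt2,
         n_perA_general = n_perA, label = label)
}

#' Classify every protein in a sequence set
#'
#' Vectorized [classify_mucin()] over a sequence tibble; repeat regions are
#' auto-detected per protein.
#'
#' @param records Sequence tibble (columns `id`, `seq`).
#' @param ... Passed on to [classify_mucin()].
#' @return A tibble with one classification row per protein.
#' @export
classify_mucins <- function(records, ...) {
  records <- as_seq_tbl(records)
  bind_rows(purrr::map(seq_len(nrow(records)), function(i) {
    classify_mucin(records[i, c("id", "seq")], ...)
  }))
}
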