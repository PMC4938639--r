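#' Scoring matrix for translated searches
#'
#' BLOSUM62 with the stop symbol `*` scored -4 against everything
#' (including itself) and `X` scored -1 against everything (Biostrings'
#' BLOSUM62 already encodes the latter).
#'
#' @return A square integer matrix.
#' @export
translated_search_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62
  m["*", ] <- -4L
  m[, "*"] <- -4L
  m
}

#' Optimal local protein alignment (Smith-Waterman, affine gaps)
#'
#' Full (non-heuristic) local alignment; appropriate at single-gene scale.
#' Default scoring is BLOSUM62 with gap open 11 / extend 1 (a gap of length
#' `k` costs `11 + k`), stop codons -4 and `X` -1 against everything.
#' When the best local score is negative the empty alignment with score 0
#' is returned.
#'
#' @param query,target Protein strings (may contain `X` and `*`).
#' @param matrix Substitution matrix (default [translated_search_matrix()]).
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @return A one-row tibble: `score`, `q_start`, `q_end`, `t_start`, `t_end`
#'   (0-based half-open), `q_aln`, `t_aln` (aligned strings with `-` gaps).
#' @examples
#' local_align("MKV", "MKV")$score  # 5 + 5 + 4 = 14
#' @export
local_align <- function(query, target, matrix = translated_search_matrix(),
                        gap_open = 11, gap_extend = 1) {
  if (!nzchar(query) || !nzchar(target)) abort("empty sequence")
  bad_q <- setdiff(unique(seq_chars(toupper(query))), rownames(matrix))
  bad_t <- setdiff(unique(seq_chars(toupper(target))), rownames(matrix))
  if (length(c(bad_q, bad_t))) {
    abort(paste0("residue(s) absent from substitution matrix: ",
                 paste(unique(c(bad_q, bad_t)), collapse = ", ")))
  }
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(toupper(query)), Biostrings::AAString(toupper(target)),
    substitutionMatrix = matrix, gapOpening = gap_open,
    gapExtension = gap_extend, type = "local")
  sc <- Biostrings::score(al)
  if (sc <= 0) {
    return(tibble(score = 0, q_start = 0L, q_end = 0L,
                  t_start = 0L, t_end = 0L, q_aln = "", t_aln = ""))
  }
  p <- Biostrings::pattern(al); s <- Biostrings::subject(al)
  tibble(score = sc,
         q_start = Biostrings::start(p) - 1L, q_end = Biostrings::end(p),
         t_start = Biostrings::start(s) - 1L, t_end = Biostrings::end(s),
         q_aln = as.character(p), t_aln = as.character(s))
}

# genomic (0-based half-open) interval of a protein interval in a frame
frame_to_genomic <- function(p_start, p_end, frame, dna_len) {
  off <- abs(frame) - 1L
  nt_start <- off + 3L * p_start
  nt_end <- off + 3L * p_end
  if (frame > 0L) {
    c(nt_start, nt_end)
  } else {
    c(dna_len - nt_end, dna_len - nt_start)
  }
}

#' Search a protein query against the six frames of a DNA sequence
#'
#' Each frame of the target is translated (stops as `*`, N-codons as `X`)
#' and locally aligned to the query. One best alignment per frame is
#' reported (use [detect_frameshifts()] for multi-segment chaining).
#'
#' @param query Protein string.
#' @param dna Nucleotide string (length >= 3).
#' @param min_score Drop frames whose best local score is below this.
#' @inheritParams local_align
#' @return A tibble sorted by score descending: `frame`, `score`,
#'   `q_start`, `q_end` (protein, 0-based half-open), `t_start`, `t_end`
#'   (frame translation coordinates), `g_start`, `g_end` (genomic
#'   nucleotide coordinates, 0-based half-open on the forward strand).
#' @export
search_six_frames <- function(query, dna, min_score = 0,
                              matrix = translated_search_matrix(),
                              gap_open = 11, gap_extend = 1) {
  if (nchar(dna) < 3L) abort("dna shorter than one codon")
  tr <- six_frame_translate(dna)
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  L <- nchar(dna)
  rows <- purrr::map(seq_along(frames), function(i) {
    prot <- tr[[i]]
    if (!nzchar(prot)) return(NULL)
    al <- local_align(query, prot, matrix, gap_open, gap_extend)
    if (al$score < min_score || al$score == 0) return(NULL)
    g <- frame_to_genomic(al$t_start, al$t_end, frames[[i]], L)
    tibble(frame = frames[[i]], score = al$score,
           q_start = al$q_start, q_end = al$q_end,
           t_start = al$t_start, t_end = al$t_end,
           g_start = g[[1]], g_end = g[[2]])
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble(frame = integer(), score = numeric(),
                  q_start = integer(), q_end = integer(),
                  t_start = integer(), t_end = integer(),
                  g_start = integer(), g_end = integer()))
  }
  arrange(out, desc(.data$score))
}

# per-column scores of an alignment (gap columns carry the affine cost)
alignment_column_scores <- function(q_aln, t_aln, matrix, gap_open,
                                    gap_extend) {
  qc <- seq_chars(q_aln); tc <- seq_chars(t_aln)
  n <- length(qc)
  sc <- numeric(n)
  in_gap <- FALSE
  for (i in seq_len(n)) {
    if (qc[i] == "-" || tc[i] == "-") {
      sc[i] <- -gap_extend - if (in_gap) 0 else gap_open
      in_gap <- TRUE
    } else {
      sc[i] <- matrix[qc[i], tc[i]]
      in_gap <- FALSE
    }
  }
  sc
}

# disjoint maximal-scoring column runs >= min_score (recursive Kadane split):
# a frameshift leaves a long negative "bridge" in a single local alignment,
# which this decomposition cuts into the true co-frame segments
max_scoring_runs <- function(sc, min_score) {
  n <- length(sc)
  if (n == 0L) return(NULL)
  best <- -Inf; bi <- 0L; bj <- 0L
  cur <- 0; ci <- 1L
  for (i in seq_len(n)) {
    if (cur <= 0) { cur <- sc[i]; ci <- i } else cur <- cur + sc[i]
    if (cur > best) { best <- cur; bi <- ci; bj <- i }
  }
  if (best < min_score) return(NULL)
  rbind(if (bi > 1L) max_scoring_runs(sc[seq_len(bi - 1L)], min_score),
        cbind(bi, bj, best),
        {
          right <- if (bj < n) max_scoring_runs(sc[(bj + 1L):n], min_score)
          if (!is.null(right)) {
            right[, 1:2] <- right[, 1:2] + bj
          }
          right
        })
}

# all local segments >= min_score in one frame: iterative masking of the
# matched target stretch, each alignment decomposed into its
# maximal-scoring subsegments so frameshift bridges are split
frame_segments <- function(query, prot, frame, dna_len, min_score, matrix,
                           gap_open, gap_extend, max_segments = 8L) {
  segs <- NULL
  masked <- prot
  for (k in seq_len(max_segments)) {
    al <- local_align(query, masked, matrix, gap_open, gap_extend)
    if (al$score < min_score || al$t_end <= al$t_start) break
    sc <- alignment_column_scores(al$q_aln, al$t_aln, matrix,
                                  gap_open, gap_extend)
    qc <- seq_chars(al$q_aln); tc <- seq_chars(al$t_aln)
    q_off <- al$q_start + c(0L, cumsum(qc != "-"))   # query pos before col i
    t_off <- al$t_start + c(0L, cumsum(tc != "-"))
    # decompose within gapless stretches only: a true co-frame segment of a
    # coding sequence is gapless, so inside a run q <-> t is exactly linear
    gap <- qc == "-" | tc == "-"
    runs <- NULL
    for (st in split(which(!gap), cumsum(gap)[!gap])) {
      r <- max_scoring_runs(sc[st], min_score)
      if (!is.null(r)) {
        r[, 1:2] <- r[, 1:2] + st[[1]] - 1L
        runs <- rbind(runs, r)
      }
    }
    if (!is.null(runs)) {
      for (r in seq_len(nrow(runs))) {
        i <- runs[r, 1]; j <- runs[r, 2]
        g <- frame_to_genomic(t_off[i], t_off[j + 1L], frame, dna_len)
        segs <- bind_rows(segs, tibble(
          frame = frame, score = runs[r, 3],
          q_start = q_off[i], q_end = q_off[j + 1L],
          t_start = t_off[i], t_end = t_off[j + 1L],
          g_start = g[[1]], g_end = g[[2]]))
      }
    }
    substr(masked, al$t_start + 1L, al$t_end) <-
      strrep("*", al$t_end - al$t_start)
  }
  segs
}

#' Detect reading-frame breaks and propose minimal N-insertions
#'
#' Finds high-scoring local segments of the query in all six frames
#' (several per frame, via iterative masking), chains same-strand segments
#' along the query, and for every adjacent pair that sits in different
#' frames proposes an insertion of 1 or 2 undetermined nucleotides (`N`)
#' that puts the downstream segment back into the upstream frame — the
#' manual repair applied when an indel sequencing error breaks an open
#' reading frame. The breakpoint is placed at the genomic midpoint between
#' the two segments and should be treated as approximate. Adjacent segments
#' on opposite strands are not repaired and are flagged `complex`.
#'
#' @inheritParams search_six_frames
#' @param min_segment_score Minimum local-alignment score for a segment to
#'   enter the chain.
#' @return A tibble with one row per proposed repair: `breakpoint` (0-based
#'   genomic coordinate of the insertion point), `inserted_n` (1 or 2),
#'   `left_frame`, `right_frame`, `complex` (logical). Zero rows for an
#'   intact coding sequence.
#' @export
detect_frameshifts <- function(query, dna, min_segment_score = 30,
                               matrix = translated_search_matrix(),
                               gap_open = 11, gap_extend = 1) {
  tr <- six_frame_translate(dna)
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  L <- nchar(dna)
  segs <- bind_rows(purrr::map(seq_along(frames), function(i) {
    if (!nzchar(tr[[i]])) return(NULL)
    frame_segments(query, tr[[i]], frames[[i]], L, min_segment_score,
                   matrix, gap_open, gap_extend)
  }))
  empty <- tibble(breakpoint = integer(), inserted_n = integer(),
                  left_frame = integer(), right_frame = integer(),
                  complex = logical())
  if (is.null(segs) || nrow(segs) < 2L) return(empty)
  qlen <- nchar(query)
  # resolve query coverage: each query position is owned by the covering
  # segment with the highest score density, so a frameshifted stretch
  # bridged by a weaker same-frame alignment is reassigned to the frame
  # that truly encodes it
  segs$density <- segs$score / pmax(segs$q_end - segs$q_start, 1L)
  owner <- rep(0L, qlen)
  dens <- rep(-Inf, qlen)
  for (i in seq_len(nrow(segs))) {
    span <- (segs$q_start[[i]] + 1L):segs$q_end[[i]]
    take <- segs$density[[i]] > dens[span]
    owner[span][take] <- i
    dens[span][take] <- segs$density[[i]]
  }
  min_run <- 4L
  pieces <- NULL
  for (i in seq_len(nrow(segs))) {
    r <- rle(owner == i)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values & r$lengths >= min_run)) {
      q0 <- starts[[j]] - 1L; q1 <- ends[[j]]      # 0-based half-open
      seg <- segs[i, ]
      if (seg$frame > 0L) {
        g0 <- seg$g_start + 3L * (q0 - seg$q_start)
        g1 <- seg$g_start + 3L * (q1 - seg$q_start)
      } else {
        g1 <- seg$g_end - 3L * (q0 - seg$q_start)
        g0 <- seg$g_end - 3L * (q1 - seg$q_start)
      }
      pieces <- bind_rows(pieces, tibble(
        frame = seg$frame, q_start = q0, q_end = q1,
        g_start = g0, g_end = g1,
        t_anchor_q = seg$q_start, t_anchor = seg$t_start))
    }
  }
  if (is.null(pieces) || nrow(pieces) < 2L) return(empty)
  chain <- arrange(pieces, .data$q_start)
  qch <- seq_chars(toupper(query))
  frame_names <- c("+1", "+2", "+3", "-1", "-2", "-3")
  tr_of <- function(f) tr[[frame_names[[match(f, frames)]]]]
  out <- NULL
  for (i in seq_len(nrow(chain) - 1L)) {
    left <- chain[i, ]; right <- chain[i + 1L, ]
    if (sign(left$frame) != sign(right$frame)) {
      out <- bind_rows(out, tibble(
        breakpoint = NA_integer_, inserted_n = NA_integer_,
        left_frame = left$frame, right_frame = right$frame, complex = TRUE))
      next
    }
    if (left$frame == right$frame) next   # co-frame: no repair needed
    qstar <- refine_split(qch, left, right, tr_of(left$frame),
                          tr_of(right$frame), matrix)
    minus <- left$frame < 0L
    o_l <- abs(left$frame) - 1L; o_r <- abs(right$frame) - 1L
    # translation coordinate of the split in each flanking frame
    t_l <- left$t_anchor + (qstar - left$t_anchor_q)
    t_r <- right$t_anchor + (qstar - right$t_anchor_q)
    pos_l <- o_l + 3L * t_l               # end of left segment
    pos_r <- o_r + 3L * t_r               # start of right segment
    bp <- (pos_l + pos_r) %/% 2L
    if (minus) bp <- L - bp               # positions were in rc coordinates
    n_ins <- ((o_l - o_r) %% 3L)
    if (n_ins == 0L) next
    out <- bind_rows(out, tibble(
      breakpoint = as.integer(bp), inserted_n = as.integer(n_ins),
      left_frame = left$frame, right_frame = right$frame, complex = FALSE))
  }
  if (is.null(out)) empty else out
}

# choose the query position where coding switches from the left frame to the
# right frame: argmax over split points of (score left of split in the left
# frame) + (score right of split in the right frame), scanning a window
# around the piece junction
refine_split <- function(qch, left, right, tr_l, tr_r, matrix) {
  qlo <- max(left$q_start + 1L, right$q_start - 12L)
  qhi <- min(right$q_end - 1L, left$q_end + 12L)
  fallback <- (left$q_end + right$q_start) %/% 2L
  if (qhi <= qlo) return(fallback)
  score_at <- function(i, piece, trx) {     # i: 0-based query position
    t <- piece$t_anchor + (i - piece$t_anchor_q)
    if (t < 0L || t >= nchar(trx)) return(-4)
    a <- qch[[i + 1L]]; b <- substring(trx, t + 1L, t + 1L)
    if (a %in% rownames(matrix) && b %in% rownames(matrix)) matrix[a, b] else -4
  }
  idx <- qlo:qhi
  sl <- vapply(idx, score_at, numeric(1), piece = left, trx = tr_l)
  sr <- vapply(idx, score_at, numeric(1), piece = right, trx = tr_r)
  # split before idx[k]: positions < split scored in left frame
  tot <- vapply(seq_along(idx), function(k) {
    sum(sl[seq_len(k - 1L)]) + sum(sr[k:length(idx)])
  }, numeric(1))
  # near the junction both frames often score equally (synonymous-codon
  # ambiguity): take the centre of the optimal plateau, not its left edge
  best <- which(tot >= max(tot) - 1e-9)
  idx[[best[[ceiling(length(best) / 2)]]]]
}

#' Apply frameshift repairs to a nucleotide sequence
#'
#' Inserts `inserted_n` literal `N` characters at each (non-complex) repair
#' breakpoint; after repair, re-searching should yield a single-frame hit
#' spanning the union of the segment query intervals.
#'
#' @param dna Nucleotide string.
#' @param repairs Tibble from [detect_frameshifts()].
#' @return The repaired nucleotide string.
#' @export
apply_repairs <- function(dna, repairs) {
  reps <- filter(repairs, !.data$complex)
  if (nrow(reps) == 0L) return(dna)
  reps <- arrange(reps, desc(.data$breakpoint))
  for (i in seq_len(nrow(reps))) {
    bp <- reps$breakpoint[[i]]
    dna <- paste0(substring(dna, 1L, bp), strrep("N", reps$inserted_n[[i]]),
                  substring(dna, bp + 1L))
  }
  dna
}
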