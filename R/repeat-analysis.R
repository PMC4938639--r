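#' Estimate the tandem-repeat period of a protein
#'
#' Self-identity autocorrelation: for each lag `k` the score
#' `A(k) = #\{i : seq[i] == seq[i+k]\} / (len - k)` is computed, and the
#' smallest lag in `[min_period, max_period]` with `A(k) >= min_identity`
#' that is a local maximum over its immediate neighbours is returned.
#' Positions holding `X` never count as matches.
#'
#' @param protein Protein sequence string, or a one-row sequence tibble.
#' @param min_period,max_period Search range for the repeat-unit length
#'   (amino acids).
#' @param min_identity Minimum self-identity `A(k)` for a lag to qualify.
#' @return The period as an integer, or `NA_integer_` when no lag qualifies
#'   (including proteins shorter than `2 * min_period`).
#' @examples
#' estimate_period(strrep("ACDEFGHIKLMNPQRSTVWYACDA", 8), min_period = 4)
#' @export
estimate_period <- function(protein, min_period = 4L, max_period = 60L,
                            min_identity = 0.5) {
  seq <- single_seq(protein)
  ch <- seq_chars(seq)
  n <- length(ch)
  if (n < 2L * min_period) return(NA_integer_)
  ok <- ch %in% AA20
  kmax <- min(max_period + 1L, n - 1L)
  kmin <- max(1L, min_period - 1L)
  A <- rep(NA_real_, kmax)
  for (k in kmin:kmax) {
    i <- seq_len(n - k)
    A[k] <- sum(ch[i] == ch[i + k] & ok[i] & ok[i + k]) / (n - k)
  }
  av <- function(k) if (k >= 1L && k <= kmax && !is.na(A[k])) A[k] else -Inf
  for (k in min_period:min(max_period, kmax)) {
    if (av(k) >= min_identity && av(k) >= av(k - 1L) && av(k) >= av(k + 1L)) {
      return(as.integer(k))
    }
  }
  NA_integer_
}

single_seq <- function(protein) {
  if (is.character(protein) && length(protein) == 1L) return(toupper(protein))
  tb <- as_seq_tbl(protein)
  if (nrow(tb) != 1L) abort("expected a single sequence")
  toupper(tb$seq[[1]])
}

# identity of a frame (residue vector) to a consensus built from count matrix
frame_identity <- function(frame_codes, counts) {
  cons <- apply(counts, 2L, function(col) {
    if (all(col == 0)) 0L else which.max(col)
  })
  w <- seq_along(frame_codes)
  comparable <- frame_codes > 0L & cons[w] > 0L
  if (!any(comparable)) return(0)
  sum(frame_codes[w][comparable] == cons[w][comparable]) / sum(comparable)
}

#' Segment a tandem-repeat region into blocks
#'
#' Greedy consensus-anchored tiling: starting from each candidate anchor the
#' protein is read in consecutive `period`-length frames; a frame is accepted
#' while its identity to the running consensus (per-column mode of the
#' accepted frames) is at least `min_block_identity`. The maximal such window
#' over all anchors is returned. A trailing partial block (< period) is
#' appended only if its identity to the consensus prefix passes the same
#' threshold.
#'
#' @inheritParams estimate_period
#' @param period Repeat-unit length, typically from [estimate_period()].
#' @param min_copies Minimum number of full-length blocks required.
#' @param min_block_identity Identity threshold of a frame to the running
#'   consensus.
#' @return An object of class `repeat_region`: list with `start`, `end`
#'   (0-based half-open), `period`, `copies` (number of blocks), `blocks`
#'   (tibble `start`, `end`, `block` string), `mean_block_identity`, and the
#'   protein length `protein_length`.
#' @export
segment_blocks <- function(protein, period, min_copies = 3L,
                           min_block_identity = 0.5) {
  seq <- single_seq(protein)
  codes <- aa_codes(seq)
  n <- length(codes)
  period <- as.integer(period)
  if (is.na(period) || period < 1L) abort("no repeat region: invalid period")
  best <- NULL
  s <- 0L
  # chains are ranked by total identity coverage (sum of per-block
  # identities to the final consensus), ties by mean identity, so a
  # mis-phased chain that drags half-flank frames in does not displace the
  # cleanly phased tiling
  better <- function(a, b) {
    sa <- a$copies * a$mean_identity; sb <- b$copies * b$mean_identity
    sa > sb + 1e-9 || (abs(sa - sb) <= 1e-9 &&
                         a$mean_identity > b$mean_identity + 1e-9)
  }
  while (s + min_copies * period <= n) {
    chain <- chain_frames(codes, s, period, min_block_identity)
    if (chain$copies >= min_copies) {
      # compare the phases reachable within one period of this anchor
      for (s2 in (s + 1L):(s + period - 1L)) {
        if (s2 + min_copies * period > n) break
        c2 <- chain_frames(codes, s2, period, min_block_identity)
        if (c2$copies >= min_copies && better(c2, chain)) chain <- c2
      }
      if (is.null(best) || better(chain, best)) best <- chain
      s <- chain$end            # restart past this region
    } else {
      s <- s + 1L
    }
  }
  if (is.null(best)) abort("no repeat region")
  blocks <- tibble(start = best$starts, end = best$starts + period)
  # trailing partial block
  region_end <- best$end
  tail_len <- min(period - 1L, n - best$end)
  if (tail_len > 0L) {
    fr <- codes[(best$end + 1L):(best$end + tail_len)]
    idt <- frame_identity(fr, best$counts[, seq_len(tail_len), drop = FALSE])
    if (idt >= min_block_identity) {
      blocks <- bind_rows(blocks, tibble(start = best$end,
                                         end = best$end + tail_len))
      region_end <- best$end + tail_len
    }
  }
  blocks$block <- substring(seq, blocks$start + 1L, blocks$end)
  structure(list(start = best$start, end = region_end, period = period,
                 copies = nrow(blocks), blocks = blocks,
                 mean_block_identity = best$mean_identity,
                 protein_length = n),
            class = "repeat_region")
}

# greedy forward chaining of period-frames from anchor s (0-based)
chain_frames <- function(codes, s, period, min_id) {
  n <- length(codes)
  counts <- matrix(0L, nrow = length(AA20), ncol = period)
  starts <- integer(); idents <- numeric()
  pos <- s
  first <- TRUE
  while (pos + period <= n) {
    fr <- codes[(pos + 1L):(pos + period)]
    if (first) {
      idt <- 1
    } else {
      idt <- frame_identity(fr, counts)
      if (idt < min_id) break
    }
    keep <- fr > 0L
    counts[cbind(fr[keep], which(keep))] <-
      counts[cbind(fr[keep], which(keep))] + 1L
    starts <- c(starts, pos); idents <- c(idents, idt)
    pos <- pos + period
    first <- FALSE
  }
  list(start = s, end = pos, copies = length(starts), starts = starts,
       counts = counts,
       mean_identity = if (length(starts)) {
         mean(final_identities(codes, starts, period, counts))
       } else 0)
}

# identity of each accepted frame to the final consensus
final_identities <- function(codes, starts, period, counts) {
  vapply(starts, function(st) {
    frame_identity(codes[(st + 1L):(st + period)], counts)
  }, numeric(1))
}

#' @export
print.repeat_region <- function(x, ...) {
  cat(sprintf(
    "<repeat_region> [%d,%d) period %d, %d blocks, mean identity %.3f\n",
    x$start, x$end, x$period, x$copies, x$mean_block_identity))
  invisible(x)
}

#' @rdname segment_blocks
#' @param x A `repeat_region`.
#' @param ... Unused.
#' @method tidy repeat_region
#' @export
tidy.repeat_region <- function(x, ...) x$blocks

#' @rdname segment_blocks
#' @method glance repeat_region
#' @export
glance.repeat_region <- function(x, ...) {
  tibble(start = x$start, end = x$end, period = x$period, copies = x$copies,
         mean_block_identity = x$mean_block_identity,
         repeat_fraction = (x$end - x$start) / x$protein_length)
}

#' Detect the repeat region of a protein in one call
#'
#' Convenience wrapper: [estimate_period()] followed by [segment_blocks()].
#'
#' @inheritParams estimate_period
#' @inheritParams segment_blocks
#' @return A `repeat_region`, or `NULL` when no period qualifies or no
#'   region passes the block filters.
#' @export
find_repeat_region <- function(protein, min_period = 4L, max_period = 60L,
                               min_identity = 0.5, min_copies = 3L,
                               min_block_identity = 0.5) {
  p <- estimate_period(protein, min_period, max_period, min_identity)
  if (is.na(p)) return(NULL)
  tryCatch(segment_blocks(protein, p, min_copies, min_block_identity),
           error = function(e) NULL)
}

#' Fraction of a protein covered by its repeat region
#'
#' @inheritParams estimate_period
#' @param region A `repeat_region`.
#' @return `(end - start) / protein length`.
#' @export
repeat_fraction <- function(protein, region) {
  if (is.null(region)) return(0)
  (region$end - region$start) / nchar(single_seq(protein))
}

#' Build a sequence logo matrix from repeat blocks
#'
#' Per-column residue frequencies and information content, as used for
#' amino-acid logos of repeat units. Frequencies are computed over observed
#' determinate residues (`X` and gaps are excluded from the column count);
#' `ic[j] = log2(20) - H_j` with `H_j` the Shannon entropy of column `j` in
#' bits. By default no small-sample correction is applied; set
#' `small_sample_correction = TRUE` to subtract the `(s-1)/(2 ln 2 n)`
#' correction term.
#'
#' @param blocks Character vector of equal-length block strings (at least 2),
#'   or a `repeat_region` (full-length blocks are used; a trailing partial
#'   block is excluded).
#' @param small_sample_correction Apply the small-sample correction to `ic`.
#' @return Object of class `logo_matrix`: list with `width`, `freq`
#'   (20 x width matrix, columns are probability vectors), `ic` (length
#'   `width`, `NA` where a column holds only `X`/gaps), `n_blocks`.
#' @examples
#' build_logo(c("PEST", "PEST", "PAST"))
#' @export
build_logo <- function(blocks, small_sample_correction = FALSE) {
  if (inherits(blocks, "repeat_region")) {
    b <- blocks$blocks
    blocks <- b$block[(b$end - b$start) == blocks$period]
  }
  if (length(blocks) < 2L) abort("need at least 2 blocks")
  w <- unique(nchar(blocks))
  if (length(w) != 1L) abort("blocks must have equal length")
  mat <- do.call(rbind, strsplit(blocks, "", fixed = TRUE))
  freq <- matrix(0, nrow = length(AA20), ncol = w,
                 dimnames = list(AA20, NULL))
  ic <- rep(NA_real_, w)
  for (j in seq_len(w)) {
    col <- mat[, j]
    col <- col[col %in% AA20]
    if (length(col) == 0L) next        # all X/gap: ic reported missing
    tab <- table(factor(col, levels = AA20))
    p <- as.numeric(tab) / length(col)
    freq[, j] <- p
    H <- -sum(p[p > 0] * log2(p[p > 0]))
    icj <- log2(20) - H
    if (small_sample_correction) {
      icj <- icj - (length(AA20) - 1) / (2 * log(2) * length(col))
    }
    ic[j] <- max(icj, 0)
  }
  structure(list(width = w, freq = freq, ic = ic, n_blocks = length(blocks)),
            class = "logo_matrix")
}

#' @export
print.logo_matrix <- function(x, ...) {
  cat(sprintf("<logo_matrix> width %d, %d blocks, total IC %.2f bits\n",
              x$width, x$n_blocks, sum(x$ic, na.rm = TRUE)))
  cat("consensus:", consensus(x)$consensus, "\n")
  invisible(x)
}

#' @rdname build_logo
#' @param x A `logo_matrix`.
#' @param ... Unused.
#' @return `tidy.logo_matrix`: long tibble with columns `position` (1-based),
#'   `residue`, `freq`, `ic`.
#' @method tidy logo_matrix
#' @export
tidy.logo_matrix <- function(x, ...) {
  out <- as_tibble(as.data.frame.table(x$freq, stringsAsFactors = FALSE))
  names(out) <- c("residue", "pos", "freq")
  out$position <- as.integer(factor(out$pos, levels = unique(out$pos)))
  out$ic <- x$ic[out$position]
  select(filter(out, .data$freq > 0),
         "position", "residue", "freq", "ic")
}

#' @rdname build_logo
#' @method glance logo_matrix
#' @export
glance.logo_matrix <- function(x, ...) {
  tibble(width = x$width, n_blocks = x$n_blocks,
         mean_ic = mean(x$ic, na.rm = TRUE),
         total_ic = sum(x$ic, na.rm = TRUE))
}

#' Consensus string of a logo
#'
#' Per column, the modal residue; ties are broken alphabetically and flagged;
#' columns with no determinate residues are `-`.
#'
#' @param logo A `logo_matrix`.
#' @return A list with `consensus` (string) and `tie` (logical vector).
#' @export
consensus <- function(logo) {
  stopifnot(inherits(logo, "logo_matrix"))
  cons <- character(logo$width)
  tie <- logical(logo$width)
  for (j in seq_len(logo$width)) {
    col <- logo$freq[, j]
    if (all(col == 0)) { cons[j] <- "-"; next }
    mx <- max(col)
    winners <- AA20[col == mx]
    cons[j] <- winners[[1]]            # alphabetical: AA20 is sorted
    tie[j] <- length(winners) > 1L
  }
  list(consensus = paste(cons, collapse = ""), tie = tie)
}

#' Fixed differences between two sets of repeat blocks
#'
#' Columns where set A is invariant for one residue, set B invariant for a
#' different residue. Columns holding only `X`/gaps in either set are
#' ignored. Positions are reported 1-based within the repeat unit.
#'
#' @param blocks_a,blocks_b Character vectors of equal-length blocks
#'   (>= 2 each, same length across the two sets).
#' @return Integer vector of 1-based column positions.
#' @examples
#' fixed_differences(c("PEST", "PEST"), c("PAST", "PAST"))
#' @export
fixed_differences <- function(blocks_a, blocks_b) {
  wa <- unique(nchar(blocks_a)); wb <- unique(nchar(blocks_b))
  if (length(wa) != 1L || length(wb) != 1L || wa != wb) {
    abort("block length mismatch")
  }
  if (length(blocks_a) < 2L || length(blocks_b) < 2L) {
    abort("need at least 2 blocks per set")
  }
  ma <- do.call(rbind, strsplit(blocks_a, "", fixed = TRUE))
  mb <- do.call(rbind, strsplit(blocks_b, "", fixed = TRUE))
  out <- integer()
  for (j in seq_len(wa)) {
    ca <- ma[, j]; ca <- ca[ca %in% AA20]
    cb <- mb[, j]; cb <- cb[cb %in% AA20]
    if (length(ca) == 0L || length(cb) == 0L) next
    if (length(unique(ca)) == 1L && length(unique(cb)) == 1L &&
        ca[[1]] != cb[[1]]) {
      out <- c(out, j)
    }
  }
  out
}

#' Homogenization index of a set of repeat blocks
#'
#' Mean pairwise per-column identity over all block pairs; 1 means the
#' repeats are perfectly homogenized, 0 that every pair differs at every
#' column. Quantifies the repeat homogenization driven by gene conversion
#' and expansion/contraction turnover.
#'
#' @param blocks Character vector of >= 2 equal-length blocks.
#' @return Fraction in `[0, 1]`.
#' @examples
#' homogenization_index(c("PEST", "PEST", "PAST"))
#' @export
homogenization_index <- function(blocks) {
  if (length(blocks) < 2L) abort("need at least 2 blocks")
  w <- unique(nchar(blocks))
  if (length(w) != 1L) abort("blocks must have equal length")
  m <- do.call(rbind, strsplit(blocks, "", fixed = TRUE))
  pairs <- combn(length(blocks), 2L)
  mean(apply(pairs, 2L, function(p) mean(m[p[1], ] == m[p[2], ])))
}
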