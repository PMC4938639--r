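# Independent oracles used across the suite. These deliberately do not share
# code with the package: the pattern oracle tests every substring against the
# pattern definition by enumeration, and the alignment oracle is a direct
# Smith-Waterman dynamic program.

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(n, alphabet = AA) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# does chars[i..] match elements j.. exactly to the end of chars?
oracle_match <- function(chars, elems, i, j) {
  if (j > nrow(elems)) return(i == length(chars) + 1L)
  el <- elems[j, ]
  res <- el$residues[[1]]
  if (!is.na(res[[1]])) {
    if (i > length(chars) || !chars[[i]] %in% res) return(FALSE)
    return(oracle_match(chars, elems, i + 1L, j + 1L))
  }
  for (l in el$min:el$max) {
    if (i + l - 1L > length(chars)) break
    if (l > 0L && any(!chars[seq(i, length.out = l)] %in% AA)) break
    if (oracle_match(chars, elems, i + l, j + 1L)) return(TRUE)
  }
  FALSE
}

# every (start, end) 0-based half-open interval whose substring matches
oracle_scan <- function(seq, pattern) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  elems <- pattern$elements
  lmin <- sum(elems$min); lmax <- sum(elems$max)
  out <- NULL
  n <- length(chars)
  for (s in seq_len(max(n - lmin + 1L, 0L)) - 1L) {
    for (e in (s + lmin):min(s + lmax, n)) {
      if (oracle_match(chars[seq(s + 1L, e)], elems, 1L, 1L)) {
        out <- rbind(out, c(s, e))
      }
    }
  }
  out
}

# random variable-gap pattern with <= max_elems elements
random_pattern <- function(max_elems = 6L, alphabet = c("P", "E", "D", "S",
                                                        "T", "A")) {
  k <- sample(2:max_elems, 1L)
  parts <- vapply(seq_len(k), function(i) {
    kind <- sample(c("lit", "class", "wild"), 1L,
                   prob = c(0.4, 0.3, 0.3))
    if (kind == "lit") {
      sample(alphabet, 1L)
    } else if (kind == "class") {
      paste0("[", paste(sample(alphabet, sample(2:3, 1L)), collapse = ""),
             "]")
    } else {
      m <- sample(0:2, 1L); n <- m + sample(0:2, 1L)
      paste0("X(", m, ",", n, ")")
    }
  }, character(1))
  txt <- paste(parts, collapse = "")
  p <- parse_pattern(txt, "rnd")
  if (sum(p$elements$min) < 1L) return(random_pattern(max_elems, alphabet))
  p
}

# brute-force affine-gap Smith-Waterman score (gap of length k costs
# open + k * ext), floor at zero
sw_score <- function(q, t, mat, open = 11, ext = 1) {
  qc <- strsplit(q, "", fixed = TRUE)[[1]]
  tc <- strsplit(t, "", fixed = TRUE)[[1]]
  n <- length(qc); m <- length(tc)
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(-Inf, n + 1, m + 1)   # gap in target (consumes query)
  Iy <- matrix(-Inf, n + 1, m + 1)   # gap in query (consumes target)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
      Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
      M[i, j] <- max(0,
                     max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                         Iy[i - 1, j - 1]) + mat[qc[i - 1], tc[j - 1]])
      best <- max(best, M[i, j])
    }
  }
  best
}

# two-sided exact Mann-Whitney p by counting query-beats-target pairs over
# all labellings (pair-counting formulation, independent of midranks)
mw_perm_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a); nb <- length(b)
  u_of <- function(x, y) {
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- u_of(a, b)
  mu <- na * nb / 2
  idx <- utils::combn(na + nb, na)
  us <- apply(idx, 2, function(k) u_of(pooled[k], pooled[-k]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}
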