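test_that("pattern notation compiles to the expected elements", {
  p1 <- parse_pattern("P[ED][ED][ST][ST][ST]", "pattern1")
  expect_equal(nrow(p1$elements), 6L)
  expect_true(all(p1$elements$min == 1L & p1$elements$max == 1L))
  expect_setequal(p1$elements$residues[[2]], c("E", "D"))
  expect_setequal(p1$elements$residues[[4]], c("S", "T"))

  cbt <- parse_pattern("C-X(2)-G-X(9)-C-X(5)-C-X(9)-C-X(5)-W-X(6)-C-X(6)-C",
                       "cbt2")
  expect_equal(nrow(cbt$elements), 15L)
  expect_equal(sum(cbt$elements$min), 50L)     # 1+2+1+9+1+5+1+9+1+5+1+6+1+6+1
  expect_equal(sum(cbt$elements$max), 50L)

  rng <- parse_pattern("C-X(13,20)-C", "r")
  expect_equal(nrow(rng$elements), 3L)
  expect_equal(sum(rng$elements$min), 15L)
  expect_equal(sum(rng$elements$max), 22L)

  expect_equal(nrow(parse_pattern("X", "w")$elements), 1L)  # bare X = X(1)
})

test_that("malformed pattern text is rejected with a position", {
  expect_error(parse_pattern(""), "empty")
  expect_error(parse_pattern("P[ED", "x"), "unbalanced")
  expect_error(parse_pattern("X(3,2)", "x"), "3 > 2")
  expect_error(parse_pattern("[PB]", "x"), "position 3")
  expect_error(parse_pattern("P1E", "x"), "position 2")
})

test_that("scan reports all and only the matching intervals", {
  h <- scan_pattern("APEESTSQ", "pattern1")
  expect_equal(nrow(h), 1L)
  expect_equal(c(h$start, h$end), c(1L, 7L))
  expect_equal(h$matched, "PEESTS")

  expect_equal(nrow(scan_pattern("PEEST", "pattern1")), 0L)  # too short

  cbt50 <- paste0("C", "AA", "G", strrep("A", 9), "C", strrep("A", 5),
                  "C", strrep("A", 9), "C", strrep("A", 5), "W",
                  strrep("A", 6), "C", strrep("A", 6), "C")
  h <- scan_pattern(cbt50, "cbt2_strict")
  expect_equal(nrow(h), 1L)
  expect_equal(c(h$start, h$end), c(0L, 50L))

  h <- scan_pattern("CACAC", parse_pattern("C-X(1,2)-C", "r"))
  expect_equal(h$start, c(0L, 2L))
  expect_equal(h$end, c(3L, 5L))
})

test_that("occurrences are counted as distinct start positions", {
  expect_equal(count_occurrences("PEESTSPEESTS", "pattern1")$count, 2L)
  expect_equal(count_occurrences("PEESTSSS", "pattern1")$count, 1L)
  # two end variants from one start collapse to a single occurrence
  expect_equal(count_occurrences("CACC", parse_pattern("C-X(1,2)-C", "r"))$count,
               1L)
})

test_that("undetermined residues never create or join motifs", {
  expect_equal(nrow(scan_pattern("PEXSTS", "pattern1")), 0L)
  # X inside a wildcard stretch also blocks a match
  expect_equal(nrow(scan_pattern("CAXAC", parse_pattern("C-X(3)-C", "r"))), 0L)
  set.seed(21)
  for (i in 1:50) {
    seq <- random_protein(30, c("P", "E", "D", "S", "T", "A", "X"))
    hits <- scan_pattern(seq, "pattern1")
    if (nrow(hits)) {
      xpos <- which(strsplit(seq, "")[[1]] == "X") - 1L
      for (k in seq_len(nrow(hits))) {
        expect_false(any(xpos >= hits$start[k] & xpos < hits$end[k]))
      }
    }
  }
})

test_that("proteome screen selects multi-occurrence proteins deterministically", {
  prots <- tibble::tibble(
    id = c("three", "one"),
    seq = c(strrep("PEESTSAAA", 3), paste0("PEESTS", strrep("A", 20))))
  out <- screen_proteome(prots, "pattern1", min_count = 2L)
  expect_equal(out$id, "three")
  expect_equal(out$count, 3L)

  expect_equal(nrow(screen_proteome(prots, "cbt2_strict", 0L)), 0L)
  expect_error(screen_proteome(prots, "pattern1", -1L), "min_count")

  # ties on count break lexicographically by id
  tied <- tibble::tibble(id = c("b", "a"),
                         seq = rep(strrep("PEESTSAAA", 3), 2))
  expect_equal(screen_proteome(tied, "pattern1", 0L)$id, c("a", "b"))
})

test_that("scan agrees with the exhaustive substring oracle", {
  set.seed(31)
  for (case in 1:250) {
    pat <- random_pattern()
    seq <- random_protein(sample(5:40, 1), c("P", "E", "D", "S", "T", "A"))
    got <- scan_pattern(seq, pat)
    want <- oracle_scan(seq, pat)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      want <- want[order(want[, 1], want[, 2]), , drop = FALSE]
      expect_equal(cbind(got$start, got$end), unname(want))
    }
  }
})

test_that("widening a wildcard range never removes hits", {
  set.seed(41)
  for (case in 1:40) {
    seq <- random_protein(40, c("P", "E", "D", "S", "T", "A"))
    m <- sample(0:2, 1); n <- m + sample(0:2, 1)
    narrow <- parse_pattern(sprintf("[PE]X(%d,%d)[ST]", m, n), "n")
    wide <- parse_pattern(sprintf("[PE]X(%d,%d)[ST]", max(m - 1, 0), n + 1),
                          "w")
    hn <- scan_pattern(seq, narrow)
    hw <- scan_pattern(seq, wide)
    if (nrow(hn)) {
      key_n <- paste(hn$start, hn$end)
      key_w <- paste(hw$start, hw$end)
      expect_true(all(key_n %in% key_w))
    }
  }
})
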