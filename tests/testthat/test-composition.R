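test_that("serine/threonine fraction counts X in the denominator", {
  expect_equal(st_fraction("SSTT"), 1)
  expect_equal(st_fraction("PAST"), 0.5)
  expect_equal(st_fraction("STXX"), 0.5)
  expect_equal(st_fraction("PAST", include_proline = TRUE), 0.75)
  expect_error(st_fraction(""), "empty")
  # complement identity
  set.seed(14)
  for (i in 1:20) {
    seq <- random_protein(sample(10:100, 1))
    ch <- strsplit(seq, "")[[1]]
    expect_equal(st_fraction(seq) + mean(!ch %in% c("S", "T")), 1)
  }
})

test_that("sliding composition windows slide at step one", {
  out <- sliding_composition("SSSSAAAA", 4, c("S", "T"))
  expect_equal(out$fraction, c(1, 0.75, 0.5, 0.25, 0))
  expect_equal(out$start, 0:4)
  expect_equal(nrow(sliding_composition("SSSS", 4, "S")), 1L)
  expect_equal(sliding_composition("PAST", 4, AA)$fraction, 1)
  expect_error(sliding_composition("PAST", 0), "positive")
  expect_error(sliding_composition("PAST", 5), "longer")
})

test_that("start candidates are the ascending methionine positions", {
  expect_equal(find_start_candidates("MAAM"), c(1L, 4L))
  expect_warning(pos <- find_start_candidates("AAAA"), "no methionine")
  expect_length(pos, 0L)
})

test_that("hydropathy windows drive the signal-peptide call", {
  sp <- signal_peptide_score(paste0("M", strrep("L", 29)))
  expect_equal(sp$score, 3.8)                 # all-leucine window
  expect_true(sp$call)

  sp <- signal_peptide_score(paste0("M", strrep("D", 29)))
  expect_equal(sp$score, -3.5)
  expect_false(sp$call)

  sp <- signal_peptide_score(paste0("M", strrep("LD", 14)))
  expect_equal(sp$score, (3.8 - 3.5) / 2)     # alternating L/D
  expect_false(sp$call)

  expect_warning(sp <- signal_peptide_score("MLLLL"), "shorter")
  expect_false(sp$call)
})

test_that("start reconciliation walks methionines until a signal is called", {
  expect_equal(reconcile_start(paste0("M", strrep("L", 40)))$start, 1L)

  # only the Met at position 24 is followed by a hydrophobic h-region
  prot <- paste0("M", strrep("DE", 11), "M", strrep("L", 20), strrep("A", 60))
  rs <- reconcile_start(prot)
  expect_equal(rs$start, 24L)
  expect_true(rs$signal)

  # no qualifying Met: first Met returned with signal = FALSE
  rs <- reconcile_start(paste0("M", strrep("DE", 30)))
  expect_equal(rs$start, 1L)
  expect_false(rs$signal)

  expect_error(suppressWarnings(reconcile_start("AAAA")), "no methionine")

  # the chosen start always holds M
  set.seed(15)
  for (i in 1:20) {
    seq <- paste0(random_protein(sample(30:80, 1)), "M", random_protein(40))
    rs <- suppressWarnings(tryCatch(reconcile_start(seq),
                                    error = function(e) NULL))
    if (!is.null(rs)) {
      expect_equal(substring(seq, rs$start, rs$start), "M")
    }
  }
})

test_that("mucin classification applies the composition and occupancy rules", {
  # signal-positive N-terminus + ST-rich repeats occupying ~73% -> mucin
  prot <- paste0("M", strrep("L", 20), "QA", strrep("PEESTSAA", 20),
                 random_protein(37, setdiff(AA, c("P", "E", "S", "T"))))
  call <- classify_mucin(prot)
  expect_equal(call$label, "mucin")
  expect_gte(call$st_fraction, 0.25)
  expect_true(call$signal)
  expect_true(call$repeat_fraction >= 0.30 && call$repeat_fraction <= 0.90)

  # composition below the 25% cut-off -> non-mucin regardless of signal
  frost <- synthetic_frost_like()
  expect_equal(st_fraction(frost$seq), 0.241)
  expect_equal(classify_mucin(frost)$label, "non-mucin")

  expect_equal(suppressWarnings(classify_mucin(strrep("A", 100))$label),
               "non-mucin")

  # repeat occupancy outside [0.30, 0.90] -> mucin-related
  whole <- paste0("M", strrep("L", 20), "QA", strrep("ST", 300))
  call <- classify_mucin(whole)
  expect_equal(call$label, "mucin-related")
  expect_gt(call$repeat_fraction, 0.90)

  # raising the ST fraction never demotes a mucin
  demoted <- classify_mucin(prot, st_cutoff = 0.20)
  expect_equal(demoted$label, "mucin")
})

test_that("externally supplied signal calls override the heuristic", {
  prot <- paste0(strrep("DE", 12), strrep("PEESTSAA", 20), strrep("A", 30))
  expect_equal(classify_mucin(prot, signal = TRUE)$label, "mucin")
  expect_equal(classify_mucin(prot, signal = FALSE)$label, "non-mucin")
})

test_that("classify_mucins vectorizes over a sequence set", {
  out <- classify_mucins(dplyr::bind_rows(synthetic_muc68e(),
                                          synthetic_frost_like()))
  expect_equal(out$label, c("mucin", "non-mucin"))
  expect_equal(out$n_cbt2_strict, c(3L, 0L))
})
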