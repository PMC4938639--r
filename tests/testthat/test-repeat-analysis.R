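test_that("self-identity autocorrelation recovers planted periods", {
  expect_equal(estimate_period(strrep("ACDE", 8)), 4L)
  expect_equal(estimate_period(strrep("PEESTSAA", 10)), 8L)

  # planted 24-mer unit, 10 copies, 5% substitutions
  set.seed(5)
  for (i in 1:10) {
    unit <- random_protein(24)
    sim <- make_mucin(mucin_spec(unit = unit, copies = 10, sub_rate = 0.05,
                                 signal = FALSE, seed = i))
    expect_equal(estimate_period(sim$protein$seq), 24L)
  }

  # random proteins essentially never show a qualifying period
  set.seed(6)
  n_none <- sum(vapply(1:50, function(i) {
    is.na(estimate_period(random_protein(200)))
  }, logical(1)))
  expect_gte(n_none, 49L)

  expect_true(is.na(estimate_period("PEESTS")))   # shorter than 2*min_period
})

test_that("block segmentation tiles the repeat region and excludes flanks", {
  reg <- segment_blocks(strrep("PEESTSAA", 10), 8L)
  expect_s3_class(reg, "repeat_region")
  expect_equal(c(reg$start, reg$end), c(0L, 80L))
  expect_equal(reg$copies, 10L)
  expect_true(all(reg$blocks$end - reg$blocks$start == 8L))
  expect_equal(reg$mean_block_identity, 1)

  set.seed(7)
  flank <- function() random_protein(20, setdiff(AA, c("P", "E", "S", "T")))
  prot <- paste0(flank(), strrep("PEESTSAA", 10), flank())
  reg2 <- segment_blocks(prot, 8L)
  expect_equal(c(reg2$start, reg2$end), c(20L, 100L))

  expect_error(segment_blocks(random_protein(30), 8L), "no repeat region")
})

test_that("a heavily substituted terminal block is excluded below threshold", {
  set.seed(8)
  unit <- random_protein(20)
  uch <- strsplit(unit, "")[[1]]
  bad <- uch
  idx <- sample(20, 8)                       # 40% substituted copy
  for (i in idx) bad[i] <- sample(setdiff(AA, uch[i]), 1)
  prot <- paste0(strrep(unit, 6), paste(bad, collapse = ""))
  reg <- segment_blocks(prot, 20L, min_block_identity = 0.7)
  expect_equal(reg$copies, 6L)
  expect_equal(reg$end, 120L)
})

test_that("logo frequencies and information content follow the entropy formula", {
  logo <- build_logo(rep("A", 10))
  expect_equal(logo$ic[[1]], log2(20), tolerance = 1e-10)

  logo <- build_logo(c("S", "S", "T", "T"))
  expect_equal(logo$ic[[1]], log2(20) - 1, tolerance = 1e-10)

  logo <- build_logo(AA)                      # uniform over all 20 residues
  expect_equal(logo$ic[[1]], 0, tolerance = 1e-10)

  expect_true(is.na(build_logo(c("XA", "XA"))$ic[[1]]))  # all-X column
  expect_error(build_logo("PEST"), "at least 2")
  expect_error(build_logo(c("PE", "PEST")), "equal length")

  # bounds hold for arbitrary block sets; mixing lowers ic
  set.seed(9)
  for (i in 1:20) {
    blocks <- replicate(sample(2:20, 1), random_protein(12))
    logo <- build_logo(blocks)
    expect_true(all(logo$ic >= -1e-12 & logo$ic <= log2(20) + 1e-12))
    expect_equal(unname(colSums(logo$freq)), rep(1, 12), tolerance = 1e-12)
  }
  pure <- build_logo(rep("A", 6))$ic[[1]]
  mixed <- build_logo(c(rep("A", 3), rep("C", 2), "D"))$ic[[1]]
  expect_lt(mixed, pure)
})

test_that("consensus takes the modal residue with alphabetical tie-breaks", {
  logo <- build_logo(c("PEST", "PEST", "PAST"))
  cons <- consensus(logo)
  expect_equal(cons$consensus, "PEST")
  logo2 <- build_logo(c("ST", "TS"))          # 50/50 both columns
  cons2 <- consensus(logo2)
  expect_equal(cons2$consensus, "SS")         # alphabetical
  expect_true(all(cons2$tie))
  expect_equal(substring(consensus(build_logo(c("XA", "XA")))$consensus,
                         1, 1), "-")
})

test_that("fixed differences require invariance in both sets", {
  expect_equal(fixed_differences(c("PEST", "PEST"), c("PAST", "PAST")), 2L)
  expect_equal(fixed_differences(c("PEST", "PEST"), c("PEST", "PEST")),
               integer(0))
  # polymorphic column in set B excluded even though A is invariant
  expect_equal(fixed_differences(c("PEST", "PEST", "PEST"),
                                 c("PAST", "PDST", "PAST")), integer(0))
  expect_error(fixed_differences(c("PEST", "PEST"), c("PES", "PES")),
               "mismatch")
})

test_that("homogenization index is the mean pairwise identity", {
  expect_equal(homogenization_index(c("PEST", "PEST")), 1)
  expect_equal(homogenization_index(c("PEST", "AKYV")), 0)
  expect_equal(homogenization_index(c("PEST", "PEST", "PAST")),
               (1 + 0.75 + 0.75) / 3)
  # decreases in expectation with substitution rate
  set.seed(10)
  mean_h <- vapply(c(0, 0.1, 0.3), function(rate) {
    mean(vapply(1:20, function(i) {
      sim <- make_mucin(mucin_spec(unit = random_protein(20), copies = 8,
                                   sub_rate = rate, signal = FALSE,
                                   seed = i))
      reg <- segment_blocks(sim$protein$seq, 20L, min_block_identity = 0.3)
      homogenization_index(
        reg$blocks$block[reg$blocks$end - reg$blocks$start == 20L])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_h) < 0))
})

test_that("repeat fraction is the region share of protein length", {
  prot <- random_protein(100)
  reg <- list(start = 20L, end = 100L)
  class(reg) <- "repeat_region"
  expect_equal(repeat_fraction(prot, reg), 0.8)
  reg2 <- list(start = 0L, end = 100L); class(reg2) <- "repeat_region"
  expect_equal(repeat_fraction(prot, reg2), 1)
  expect_equal(repeat_fraction(prot, NULL), 0)
})

test_that("period and copy number are recovered from seeded planted repeats", {
  set.seed(12)
  ok <- 0L
  for (i in 1:40) {
    ulen <- sample(16:48, 1); copies <- sample(5:82, 1)
    sim <- make_mucin(mucin_spec(unit = random_protein(ulen), copies = copies,
                                 sub_rate = runif(1, 0, 0.05), seed = i))
    per <- estimate_period(sim$protein$seq)
    if (!is.na(per) && per == ulen) {
      reg <- tryCatch(segment_blocks(sim$protein$seq, per),
                      error = function(e) NULL)
      nfull <- if (is.null(reg)) {
        -99L
      } else {
        sum(reg$blocks$end - reg$blocks$start == per)
      }
      if (abs(nfull - copies) <= 1L) ok <- ok + 1L
    }
  }
  expect_gte(ok, 38L)
})

test_that("region and logo objects expose tidy/glance summaries", {
  reg <- segment_blocks(strrep("PEESTSAA", 10), 8L)
  g <- glance(reg)
  expect_equal(g$repeat_fraction, 1)
  expect_equal(nrow(tidy(reg)), 10L)
  logo <- build_logo(reg)
  expect_equal(glance(logo)$width, 8L)
  expect_s3_class(autoplot(logo), "ggplot")
})
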