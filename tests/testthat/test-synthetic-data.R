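test_that("generators are pure functions of their specs", {
  sp <- mucin_spec(unit = "PEESTSAA", copies = 12, sub_rate = 0.05,
                   indel_rate = 0.01, n_cbt2 = 2, seed = 99)
  expect_identical(make_mucin(sp), make_mucin(sp))

  g <- make_genomic("MKVPEESTSAA", data.frame(codon = 4L, del = 1L),
                    seed = 7)
  expect_identical(g, make_genomic("MKVPEESTSAA",
                                   data.frame(codon = 4L, del = 1L),
                                   seed = 7))

  ps <- pheno_spec(n_per_strain = 20, seed = 3)
  expect_identical(make_pheno(ps), make_pheno(ps))

  # the caller's RNG stream is untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(make_mucin(sp)); after <- runif(1)
  expect_identical(before, after)
})

test_that("make_mucin plants the architecture its truth describes", {
  sim <- make_mucin(mucin_spec(unit = "PEESTSAA", copies = 10, signal = FALSE,
                               seed = 1))
  expect_equal(sim$truth$period, 8L)
  expect_equal(sim$truth$copies, 10L)
  expect_equal(sim$truth$region_end - sim$truth$region_start, 80L)
  expect_equal(substring(sim$protein$seq, sim$truth$region_start + 1L,
                         sim$truth$region_end),
               strrep("PEESTSAA", 10))

  sim3 <- make_mucin(mucin_spec(unit = "PEESTSAA", copies = 10, n_cbt2 = 3,
                                seed = 2))
  hits <- scan_pattern(sim3$protein, "cbt2_strict")
  expect_equal(nrow(hits), 3L)
  expect_equal(hits$start, sim3$truth$cbt2_starts)

  expect_error(mucin_spec(unit = "PEXST"), "must not contain X")
})

test_that("back-translation round-trips and plants breakpoints faithfully", {
  set.seed(29)
  prot <- random_protein(120)
  g0 <- make_genomic(prot, seed = 11)
  expect_equal(six_frame_translate(g0$dna$seq)[["+1"]], prot)

  g1 <- make_genomic(prot, data.frame(codon = 60L, del = 1L), seed = 11)
  expect_equal(nchar(g1$dna$seq), 3L * 120L - 1L)
  expect_equal(g1$truth$breakpoint, 180L)

  expect_error(make_genomic(prot, data.frame(codon = c(5L, 5L),
                                             del = c(1L, 1L))),
               "overlapping")
  expect_error(make_genomic(prot, data.frame(codon = 500L, del = 1L)),
               "outside")
})

test_that("signal-positive ST-rich simulated mucins classify as mucins", {
  set.seed(32)
  labels_on <- character(0); labels_off <- character(0)
  for (i in 1:25) {
    unit <- paste0("PEESTS", random_protein(sample(12:20, 1),
                                            c("S", "T", "S", "T", "A", "P")))
    copies <- sample(8:30, 1)
    on <- make_mucin(mucin_spec(unit = unit, copies = copies,
                                sub_rate = 0.02, signal = TRUE,
                                n_cbt2 = 2, seed = i))
    off <- make_mucin(mucin_spec(unit = unit, copies = copies,
                                 sub_rate = 0.02, signal = FALSE,
                                 n_cbt2 = 2, seed = i))
    labels_on <- c(labels_on, suppressWarnings(classify_mucin(on$protein)$label))
    labels_off <- c(labels_off,
                    suppressWarnings(classify_mucin(off$protein)$label))
  }
  expect_true(all(labels_on %in% c("mucin", "mucin-related")))
  expect_gte(mean(labels_on == "mucin"), 0.9)
  expect_true(all(labels_off == "non-mucin"))
})

test_that("phenotype tables carry the planted contrasts and valid weights", {
  sim <- make_pheno(pheno_spec(seed = 5))
  expect_equal(nrow(sim$pheno), 300L)
  expect_setequal(unique(sim$pheno$strain), c("control", "mutant"))
  expect_true(all(sim$weights$lfree_dw <= sim$weights$dw))
  expect_true(all(sim$weights$n_flies == 10L))
  expect_true(all(sim$pheno$starvation_time %% 12 == 0))
  expect_true(all(sim$pheno$lifespan %% 2 == 0))
  expect_equal(sim$truth$effect_pct[sim$truth$variable == "ccrt"], -12,
               tolerance = 1e-9)

  # planted CCRT effect recovered across seeds (unbiased estimator)
  devs <- vapply(1:25, function(s) {
    p <- make_pheno(pheno_spec(seed = s))$pheno
    group_contrast(p, "ccrt", "strain", ref = "control")$pct_difference
  }, numeric(1))
  expect_equal(mean(devs), -12, tolerance = 2)

  # null calibration: with all effects 1 the test rejects at ~5%
  null_effects <- list(ccrt = 1, abdomen_area = 1, tibia_t1 = 1,
                       tibia_t2 = 1, tibia_t3 = 1, wing_area = 1,
                       lifespan = 1, starvation = 1,
                       dw = list("0d" = 1, "4d" = 1, "5d" = 1,
                                 "5d_ACCR" = 1))
  rej <- mean(vapply(1:200, function(s) {
    p <- make_pheno(pheno_spec(n_per_strain = 30, effects = null_effects,
                               seed = s))$pheno
    group_contrast(p, "ccrt", "strain", ref = "control")$p_value < 0.05
  }, logical(1)))
  expect_gte(rej, 0.01)
  expect_lte(rej, 0.10)

  expect_error(pheno_spec(n_per_strain = 0), "positive")
})

test_that("synthetic stand-ins encode their documented architecture", {
  m <- synthetic_muc68e()
  expect_equal(find_start_candidates(m$seq)[1:2], c(1L, 24L))
  expect_equal(reconcile_start(m$seq)$start, 24L)
  expect_equal(nrow(scan_pattern(m, "cbt2_strict")), 3L)
  reg <- find_repeat_region(m$seq)
  expect_equal(reg$period, 39L)
  expect_equal(repeat_fraction(m$seq, reg), 0.82, tolerance = 0.05)

  cc <- synthetic_concat16()
  expect_equal(nchar(cc$seq), 11988L)

  pr <- synthetic_proteome()
  expect_gt(nrow(pr), 20L)
})
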