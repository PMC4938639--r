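# All generators are pure functions of their spec (seed included): the RNG
# state is saved and restored so repeated calls are byte-identical and the
# caller's RNG stream is untouched.
with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# residues used to pad motif domains and spacers: no C/W/M so that padding
# can neither create cysteine motifs nor initiator methionines
FILL_RESIDUES <- c("A", "S", "T", "N", "D", "E", "P", "Q", "V", "G")

# one chitin-binding type-2 domain matching the strict motif exactly
cbt2_domain <- function() {
  fill <- function(n) paste(sample(FILL_RESIDUES, n, replace = TRUE),
                            collapse = "")
  paste0("C", fill(2), "G", fill(9), "C", fill(5), "C", fill(9),
         "C", fill(5), "W", fill(6), "C", fill(6), "C")
}

#' Specification for a synthetic mucin-like protein
#'
#' @param unit Repeat-unit string (length 4-60, no `X`).
#' @param copies Number of repeat copies (>= 1).
#' @param sub_rate,indel_rate Per-residue substitution / indel probabilities
#'   applied to the repeat region (in `[0, 1)`).
#' @param signal Prepend an initiator methionine plus a hydrophobic
#'   h-region so that the signal-peptide heuristic calls positive.
#' @param n_cbt2 Number of strict chitin-binding type-2 domains appended
#'   C-terminally (with short spacers).
#' @param seed Integer seed; the generator is deterministic given the spec.
#' @return A list of class `mucin_spec`.
#' @export
mucin_spec <- function(unit = "PEESTSAA", copies = 10L, sub_rate = 0,
                       indel_rate = 0, signal = TRUE, n_cbt2 = 0L,
                       seed = 1L) {
  if (grepl("X", unit, fixed = TRUE)) abort("repeat unit must not contain X")
  stopifnot(nchar(unit) >= 4L, nchar(unit) <= 60L, copies >= 1L,
            sub_rate >= 0, sub_rate < 1, indel_rate >= 0, indel_rate < 1)
  structure(list(unit = toupper(unit), copies = as.integer(copies),
                 sub_rate = sub_rate, indel_rate = indel_rate,
                 signal = isTRUE(signal), n_cbt2 = as.integer(n_cbt2),
                 seed = as.integer(seed)),
            class = "mucin_spec")
}

# substitutions then indels on a residue vector
mutate_residues <- function(ch, sub_rate, indel_rate) {
  n <- length(ch)
  if (sub_rate > 0) {
    hit <- runif(n) < sub_rate
    if (any(hit)) {
      ch[hit] <- vapply(ch[hit], function(r) {
        sample(setdiff(AA20, r), 1L)
      }, character(1))
    }
  }
  if (indel_rate > 0) {
    out <- character(0)
    for (i in seq_along(ch)) {
      if (runif(1) < indel_rate) {
        if (runif(1) < 0.5) next                 # deletion
        out <- c(out, sample(AA20, 1L), ch[i])   # insertion
      } else {
        out <- c(out, ch[i])
      }
    }
    ch <- out
  }
  ch
}

#' Generate a mucin-like protein with known ground truth
#'
#' Builds `[signal segment] + unit x copies (mutated) + [CBT2 domains]` and
#' returns the protein together with the planted truth: repeat-region
#' bounds, period, copy number, and motif coordinates.
#'
#' @param spec A [mucin_spec()].
#' @return A list with `protein` (one-row sequence tibble) and `truth`
#'   (list: `region_start`, `region_end`, `period`, `copies`,
#'   `cbt2_starts` — all 0-based).
#' @examples
#' make_mucin(mucin_spec(copies = 5, seed = 42))
#' @export
make_mucin <- function(spec) {
  stopifnot(inherits(spec, "mucin_spec"))
  with_local_seed(spec$seed, {
    nterm <- if (spec$signal) {
      paste0("M", paste(sample(c("L", "A", "V", "I", "F"), 19,
                               replace = TRUE), collapse = ""),
             paste(sample(c("S", "T", "N", "Q"), 4, replace = TRUE),
                   collapse = ""))
    } else {
      paste(sample(setdiff(FILL_RESIDUES, "M"), 24, replace = TRUE),
            collapse = "")
    }
    rep_ch <- mutate_residues(
      seq_chars(strrep(spec$unit, spec$copies)),
      spec$sub_rate, spec$indel_rate)
    repeat_seg <- paste(rep_ch, collapse = "")
    region_start <- nchar(nterm)
    region_end <- region_start + nchar(repeat_seg)
    cterm <- ""
    cbt2_starts <- integer()
    if (spec$n_cbt2 > 0L) {
      pos <- region_end
      parts <- character()
      for (k in seq_len(spec$n_cbt2)) {
        spacer <- paste(sample(FILL_RESIDUES, 5, replace = TRUE),
                        collapse = "")
        dom <- cbt2_domain()
        cbt2_starts <- c(cbt2_starts, pos + nchar(spacer))
        parts <- c(parts, spacer, dom)
        pos <- pos + nchar(spacer) + nchar(dom)
      }
      cterm <- paste(parts, collapse = "")
    }
    seq <- paste0(nterm, repeat_seg, cterm)
    list(protein = tibble(id = sprintf("synthetic_mucin_seed%d", spec$seed),
                          description = "synthetic mucin-like protein",
                          seq = seq),
         truth = list(region_start = region_start, region_end = region_end,
                      period = nchar(spec$unit), copies = spec$copies,
                      cbt2_starts = cbt2_starts))
  })
}

#' Back-translate a protein and plant frameshift-causing deletions
#'
#' Codons are sampled uniformly among the synonymous codons of each residue
#' (`X` becomes `NNN`); the planted deletions of 1 or 2 nt then break the
#' reading frame, emulating indel sequencing errors. Truth breakpoints are
#' reported in the coordinates of the *returned* (mutated) sequence.
#'
#' @param protein Protein string or one-row sequence tibble.
#' @param frameshift_positions Data frame (or NULL) with columns `codon`
#'   (0-based codon index, strictly increasing) and `del` (1 or 2).
#' @param seed Integer seed.
#' @return A list with `dna` (one-row nucleotide tibble) and `truth`
#'   (tibble: `breakpoint` 0-based genomic coordinate in the mutated
#'   sequence, `del`).
#' @export
make_genomic <- function(protein, frameshift_positions = NULL, seed = 1L) {
  seq <- single_seq(protein)
  ch <- seq_chars(seq)
  gc <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc), unname(gc))
  with_local_seed(seed, {
    codons <- vapply(ch, function(r) {
      if (r == "X" || is.null(by_aa[[r]])) "NNN"
      else sample(by_aa[[r]], 1L)
    }, character(1))
    dna <- paste(codons, collapse = "")
    truth <- tibble(breakpoint = integer(), del = integer())
    if (!is.null(frameshift_positions) && nrow(frameshift_positions) > 0L) {
      fp <- arrange(as_tibble(frameshift_positions), .data$codon)
      if (any(diff(fp$codon) < 1L)) abort("overlapping deletions")
      if (any(!fp$del %in% 1:2)) abort("deletion length must be 1 or 2")
      if (any(fp$codon < 0L | fp$codon >= length(ch))) {
        abort("deletion codon index outside protein")
      }
      removed <- 0L
      for (i in seq_len(nrow(fp))) {
        pos <- 3L * fp$codon[[i]] - removed     # mutated-sequence coordinate
        dna <- paste0(substring(dna, 1L, pos),
                      substring(dna, pos + fp$del[[i]] + 1L))
        truth <- bind_rows(truth,
                           tibble(breakpoint = pos, del = fp$del[[i]]))
        removed <- removed + fp$del[[i]]
      }
    }
    list(dna = tibble(id = sprintf("synthetic_gene_seed%d", seed),
                      description = "synthetic back-translated gene",
                      seq = dna),
         truth = truth)
  })
}

#' Specification for a synthetic two-strain phenotype experiment
#'
#' Control-strain measurements are drawn from log-normal distributions at
#' the stated means and coefficients of variation; mutant-strain means are
#' the control means multiplied by the effect sizes. The shipped default
#' effect profile (`default_effects()`) encodes the contrasts observed
#' between a mucin-null strain and its co-isogenic control: -12% chill-coma
#' recovery time, +6.3% abdominal area, -3.3% wing area, -1.3..-2.1%
#' tibia lengths, -10.2% dry weight at eclosion and +8.3% at 4 d.
#'
#' @param n_per_strain Flies per strain (individual measurements).
#' @param n_sets Weight sets (of 10 flies) per strain and age class.
#' @param means Named list of control means: `ccrt` (s), `abdomen_area`
#'   (mm2), `tibia_t1`..`tibia_t3` (mm), `wing_area` (mm2), `dw` per age
#'   class (mg per set of 10), `lipid_fraction` per age class.
#' @param effects Named list of multiplicative mutant effects (see
#'   [default_effects()]).
#' @param cvs Named list of coefficients of variation.
#' @param seed Integer seed.
#' @return A list of class `pheno_spec`.
#' @export
pheno_spec <- function(n_per_strain = 150L, n_sets = 9L,
                       means = NULL, effects = NULL, cvs = NULL,
                       seed = 1L) {
  if (n_per_strain <= 0L || n_sets <= 0L) abort("n must be positive")
  defaults <- default_effects()
  structure(list(
    n_per_strain = as.integer(n_per_strain), n_sets = as.integer(n_sets),
    means = utils::modifyList(defaults$means, means %||% list()),
    effects = utils::modifyList(defaults$effects, effects %||% list()),
    cvs = utils::modifyList(defaults$cvs, cvs %||% list()),
    seed = as.integer(seed)), class = "pheno_spec")
}

#' Default effect-size profile for the phenotype generator
#'
#' Reads `inst/extdata/default_effects.json`: multiplicative mutant/control
#' effects, control means and noise CVs used by [make_pheno()] defaults.
#' These are generator inputs for demonstration and calibration runs, not
#' validation targets.
#'
#' @return A list with components `means`, `effects`, `cvs`.
#' @export
default_effects <- function() {
  path <- system.file("extdata", "default_effects.json",
                      package = "mucinscan")
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

rln <- function(n, mean, cv) {
  s2 <- log(1 + cv^2)
  rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Generate two-strain phenotype and weight tables with known truth
#'
#' @param spec A [pheno_spec()].
#' @return A list with `pheno` (tibble: `strain`, `fly`, `ccrt`,
#'   `abdomen_area`, `tibia_t1`..`tibia_t3`, `wing_area`, `lifespan`,
#'   `starvation_time`), `weights` (tibble: `strain`, `age_class`, `set`,
#'   `n_flies`, `dw`, `lfree_dw`) and `truth` (tibble of the planted
#'   percent effects).
#' @export
make_pheno <- function(spec) {
  stopifnot(inherits(spec, "pheno_spec"))
  m <- spec$means; ef <- spec$effects; cv <- spec$cvs
  with_local_seed(spec$seed, {
    one_strain <- function(strain, mult) {
      n <- spec$n_per_strain
      ls_raw <- rln(n, m$lifespan * mult("lifespan"), cv$lifespan)
      st_raw <- rln(n, m$starvation * mult("starvation"), cv$starvation)
      tibble(
        strain = strain, fly = seq_len(n),
        ccrt = rln(n, m$ccrt * mult("ccrt"), cv$ccrt),
        abdomen_area = rln(n, m$abdomen_area * mult("abdomen_area"),
                           cv$abdomen_area),
        tibia_t1 = rln(n, m$tibia_t1 * mult("tibia_t1"), cv$tibia),
        tibia_t2 = rln(n, m$tibia_t2 * mult("tibia_t2"), cv$tibia),
        tibia_t3 = rln(n, m$tibia_t3 * mult("tibia_t3"), cv$tibia),
        wing_area = rln(n, m$wing_area * mult("wing_area"), cv$wing_area),
        lifespan = 2 * ceiling(ls_raw / 2),      # checked every other day
        starvation_time = 12 * ceiling(st_raw / 12))  # checked every 12 h
    }
    ctrl <- one_strain("control", function(k) 1)
    mut <- one_strain("mutant",
                      function(k) ef[[k]] %||% 1)
    ages <- c("0d", "4d", "5d", "5d_ACCR")
    weights <- bind_rows(purrr::map(ages, function(age) {
      dwm <- m$dw[[age]]; lf <- m$lipid_fraction[[age]]
      bind_rows(purrr::map(c("control", "mutant"), function(strain) {
        emult <- if (strain == "mutant") ef$dw[[age]] %||% 1 else 1
        dw <- rln(spec$n_sets, dwm * emult, cv$dw)
        frac <- pmin(pmax(rnorm(spec$n_sets, lf, cv$lipid_fraction * lf),
                          0.01), 0.6)
        tibble(strain = strain, age_class = age, set = seq_len(spec$n_sets),
               n_flies = 10L, dw = dw, lfree_dw = dw * (1 - frac))
      }))
    }))
    truth <- tibble(
      variable = c("ccrt", "abdomen_area", "tibia_t1", "tibia_t2",
                   "tibia_t3", "wing_area", paste0("dw_", ages)),
      effect_pct = 100 * (unname(c(ef$ccrt, ef$abdomen_area, ef$tibia_t1,
                                   ef$tibia_t2, ef$tibia_t3, ef$wing_area,
                                   vapply(ages, function(a) ef$dw[[a]] %||% 1,
                                          numeric(1)))) - 1))
    list(pheno = bind_rows(ctrl, mut), weights = weights, truth = truth)
  })
}
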