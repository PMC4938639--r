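---
title: "Methods: mucin sequence architecture, frameshift repair, and phenotype statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mucin sequence architecture, frameshift repair, and phenotype statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mucinscan)
```

`mucinscan` analyses the three-part architecture of insect gut mucins —
signal peptide, central Pro/Ser/Thr-rich (PTS) tandem repeats, optional
C-terminal chitin-binding type-2 (CBT2 / peritrophin-A) domains — and the
nonparametric statistics used when such genes are linked to organismal
phenotypes (chill-coma recovery, starvation survival, weight and lipid
partitions). This vignette records the models, the tunable parameters, the
numerical conventions, and the design choices that were genuinely open.

## Coordinates and alphabets

All internal coordinates are 0-based half-open; the single conversion to
1-based inclusive happens at GFF3 emission (`write_gff3()`,
`hits_to_gff3()`). Proteins use the 20 standard residues plus `X` for
undetermined stretches; `X` is accepted everywhere on input but never
satisfies a motif element (class or wildcard) and never counts as a match
in repeat statistics — undetermined sequence must not create structure.
`X` does count in composition denominators, making `st_fraction()`
deliberately conservative. Stop codons translate to `*` and terminate
nothing automatically; callers decide what a stop means.

## Motif scanning

Patterns are ordered elements: literal residues, residue classes `[...]`,
and wildcard runs `X(n)` / `X(m,n)`. A hit is any interval for which *some*
assignment of wildcard lengths matches, so ranged patterns can yield
overlapping hits and several end points per start. Occurrence counting
collapses to distinct start positions: this is stable under ranged gaps and
coincides with the intuitive count for fixed-width patterns such as
pattern 1 (`P[ED][ED][ST][ST][ST]`). Fixed-width patterns are scanned with
a vectorized sliding window; ranged patterns fall back to a frontier
enumeration. The engine is deliberately exhaustive rather than heuristic —
at proteome scale that is still cheap for the short patterns used here —
and the test suite holds it equal to an independent brute-force substring
oracle over a thousand seeded random cases.

Anchors and exclusion classes of the full PROSITE grammar are out of
scope, as is any scored or approximate matching. One consequence of
encoding the printed motifs exactly: the strict CBT2 motif spaces its
first two cysteines 12 residues apart (`C-X(2)-G-X(9)-C`), which the
general peritrophin-A motif (first spacer 13–20) does not admit, so the
two built-in counts are independent readouts, and classification reports
both.

## Repeat decomposition

No standard algorithm exists for "the" repeat region of a mucin; curation
is usually by eye. The package uses a deterministic, oracle-testable
two-step procedure:

1. **Period.** `estimate_period()` computes the self-identity
   autocorrelation `A(k) = #{i : s[i] = s[i+k]}/(n−k)` and returns the
   smallest lag in `[min_period, max_period]` (defaults 4–60, spanning the
   observed 16–48 residue block sizes with margin) with `A(k) ≥
   min_identity` (default 0.5) that is a local maximum over `k ± 1`.
   Taking the smallest qualifying lag avoids harmonics (`A(2p)` is as high
   as `A(p)` for a perfect repeat).
2. **Segmentation.** `segment_blocks()` greedily tiles period-length
   frames from candidate anchors, accepting a frame while its identity to
   the running consensus (per-column mode of accepted frames) is at least
   `min_block_identity` (default 0.5, `min_copies` default 3). Chains are
   ranked by total identity coverage with ties broken by mean identity, so
   a mis-phased chain that drags half-flank frames in cannot displace a
   cleanly phased tiling. A trailing partial block is appended only if it
   passes the same identity threshold against the consensus prefix,
   matching the observation that highly degenerated terminal repeats are
   hard to recognize and are best left out unless clearly homologous.

Two accuracy notes. The anchor phase is identified only up to the period
when flanks happen to resemble the unit, so region boundaries can be off
by up to one period; planted-truth recovery is therefore asserted on the
period (exact) and the copy number (±1), which the suite verifies in ≥95%
of 200 seeded replicates spanning units of 16–48 residues and 5–82 copies
at ≤5% substitution. And with substantial divergence between copies the
greedy consensus can fragment a region; thresholds are exposed rather than
adaptive.

Logo statistics follow the standard information-content convention
`IC_j = log2(20) − H_j` bits, computed over observed determinate residues
(`X`/gaps excluded from the column count; an all-missing column reports
`IC = NA`). The small-sample correction `(s−1)/(2 ln 2 · n)` is off by
default — block counts range from 5 to over 80, and the correction
materially changes small sets, so the default must be the reproducible
uncorrected value — and can be enabled with a flag. Logos are built from
full-length blocks only; whether curated logos include partial terminal
blocks is unknowable from outside, and excluding them is the conservative
choice. Fixed differences between species' repeat units (columns invariant
within each set, different between sets) are reported 1-based within the
unit, the convention used when repeat positions are quoted.
`homogenization_index()` (mean pairwise per-column block identity)
quantifies repeat homogenization by gene conversion and
expansion/contraction turnover.

## Mucin classification

`classify_mucin()` operationalizes the standard criteria: Ser+Thr fraction
≥ 25% (the cut-off that famously excludes Frost at 24.1%), a signal
peptide, and a PTS repeat region occupying 30–90% of the protein. All
three met → `mucin`; composition and signal met but occupancy outside the
band (or no detectable region) → `mucin-related`; otherwise `non-mucin`.
CBT2/PerA domain counts are reported but not required, since only about a
quarter of mucins carry one. Whether the 25% cut-off should count prolines
is ambiguous in the literature's phrasing; S+T is implemented as the
default with `include_proline = TRUE` available.

The signal-peptide call is a declared heuristic, not a trained predictor:
the maximum mean Kyte–Doolittle hydropathy over windows of length 8 within
residues 3–25 of the candidate N-terminus, called positive at ≥ 1.6.
Window and threshold are configurable, and externally computed calls
(e.g. from a real predictor) can be passed to `classify_mucin(signal = )`,
bypassing the heuristic entirely. The threshold sits between the
strongly hydrophobic h-regions of true signal peptides (leucine-rich
windows score ≈ 3.8) and mixed or charged N-termini (≤ 0.2), and is not
meant to reproduce any particular predictor's decisions.
`reconcile_start()` walks methionines in the first 60 residues and takes
the first with a positive call — the reconciliation that identifies an
internal methionine (position 24 in the modelled protein) as the true
initiator when the annotated start yields no signal.

## Translated search and frameshift repair

`local_align()` is full Smith–Waterman (via `Biostrings::pairwiseAlignment`)
with BLOSUM62, gap open 11 / extend 1 — inputs are single genes, so no
seeding heuristics are needed. `X` scores −1 and `*` −4 against
everything; the `*`-vs-`*` score is also −4 (a stop aligned to a stop is
still evidence against coding here), a deliberate departure from the +1
found in some matrix distributions, and configurable via the matrix
argument. Frames follow the BLAST convention: `+1` starts at base 1, `−1`
at the last base of the reverse complement.

`detect_frameshifts()` reconstructs a broken reading frame in four steps:
(i) per frame, all local segments above `min_segment_score` (default 30,
roughly the score of a 7-residue identity) are collected by iterative
masking; (ii) each alignment is decomposed into maximal-scoring *gapless*
runs, because a single local alignment happily bridges a frameshifted
stretch with mismatches or a gap, and within a gapless run the
query-to-target mapping is exactly linear; (iii) query coverage is
resolved by score density, each position going to the best covering frame,
and surviving runs of ≥ 4 residues become chain pieces; (iv) for adjacent
same-strand pieces in different frames, the switch point is the argmax of
(left-frame score before the split + right-frame score after it), taking
the centre of the optimal plateau since synonymous-codon ambiguity makes
several splits equivalent. The insertion size is `(offset_left −
offset_right) mod 3 ∈ {1, 2}` undetermined nucleotides, placed at the
genomic midpoint implied by the refined split. Adjacent pieces on opposite
strands are flagged `complex` and never repaired.

Breakpoints are approximate by construction (reported to ±6 nt in the
recovery tests), and inside a long tandem-repeat region they are
intrinsically ambiguous: a shifted downstream segment can re-anchor one
repeat unit over with an equally good score. The planted-truth recovery
suite therefore uses non-repetitive queries; on repeat-rich queries the
repair count and insertion sizes remain meaningful but breakpoint
positions should be treated as one-of-several-equivalent. Spliced
alignment and E-value statistics are out of scope (the genes modelled are
intronless; putative introns in them are argued to be artifacts).

## Phenotype statistics

`group_contrast()` reports the percent difference relative to the first
(control) group, `100·(mean_b − mean_a)/mean_a`, with a Mann–Whitney test:
exact by full enumeration of labellings (midranks for ties — the reason
`wilcox.test`'s exact path cannot be used) when `n_a + n_b ≤ 12`,
otherwise the normal approximation with tie and continuity corrections
(which *is* delegated to `wilcox.test`). `fisher_exact_2x2()` uses the
probability-mass two-sided definition — the sum of hypergeometric
probabilities of tables at most as probable as the observed one — which is
exactly what `stats::fisher.test` implements; the odds ratio reported is
the sample `ad/bc`, not the conditional MLE, because that is what a 2×2
table's printed OR conventionally means. `correlations()` gives Pearson r
and Spearman rho (midranks) with both p-values from the t distribution on
`n − 2` df; for Spearman this is an approximation chosen for uniformity
over `cor.test`'s mixed exact/AS89 behaviour. `survival_summary()` assigns
interval-censored deaths to the right endpoint of the observation interval
(matching "dead after 36 h" phrasing for 12-h starvation checks and
every-other-day lifespan checks); this overestimates individual death
times by half an interval on average, visible as lifespan means slightly
above the generating mean, and is reported as the convention rather than
corrected. Kaplan–Meier/Cox modelling and multiple-testing correction are
out of scope: raw p-values are the interface.

## Synthetic data: what it emulates and what it does not

The generators define the conditions under which the pipeline is
validated. `make_mucin()` plants a repeat unit (length 4–60) with
per-residue substitution/indel noise, an optional signal segment
(methionine plus a hydrophobic h-region), and strict CBT2 domains with
non-cysteine spacer fill so the planted domain count is exact.
`make_genomic()` back-translates with uniformly sampled synonymous codons
(codon-usage bias is out of scope) and applies planted 1–2 nt deletions.
`make_pheno()` draws positive-valued measurements from log-normal
distributions — control means at realistic laboratory values (CCRT 1500 s,
abdomen 2.2 mm², wing 2.0 mm², tibiae 0.55–0.68 mm, dry weight 2.4–3.4 mg
per set of ten flies), CVs 0.04–0.41 by trait — and multiplies mutant
means by the effect profile in `inst/extdata/default_effects.json`
(−12% CCRT, +6.3% abdomen, −3.3% wing, −1.3/−1.7/−2.1% tibiae, −10.2% dry
weight at eclosion, +8.3% at 4 d, lifespans 33.9 vs 35.9 d). With
150 flies per strain and CV 0.25, the recovered CCRT contrast has a
sampling sd of about 2.6 percentage points; recovery is asserted as
unbiasedness of the mean over replicates plus significance in ≥95% of
replicates, which is what those parameters support.

What the simulations do not capture: phylogenetic correlation between
species' repeats, gene-conversion tract structure, codon bias, real
signal-peptide diversity, assembler-specific error modes, and the
correlation structure among phenotypes of a single fly (traits are drawn
independently). Passing tests therefore demonstrate that the algorithms
recover what they are defined to recover under clean planted structure —
not that any particular biological dataset meets those assumptions.

Reference molecules that cannot be redistributed are represented by
deterministic stand-ins, labelled `_synthetic` in their ids
(`synthetic_muc68e()`, `synthetic_frost_like()`, `synthetic_proteome()`,
`synthetic_concat16()`). They encode documented architecture — a
methionine at position 24 followed by an h-region, ~82% repeat occupancy,
three strict CBT2 domains, a 24.1% S+T composition, planted multi-occurrence
motif counts, an 11,988 bp concatenated coding set — not real residues, so
checks against them validate the operations, not the original sequences.

## Problem sizes

The shipped test-and-validation runs use: 1000 random cases for the
pattern-engine oracle, 200 replicates for repeat recovery (units 16–48,
copies 5–82), 100 replicates for frameshift recovery (200-residue genes,
1–3 shifts spaced ≥ 60 nt), 2000 null replicates (n = 30 per group) for
the Mann–Whitney size check, and 50–100 replicates for phenotype-contrast
recovery. These sizes put Monte-Carlo error comfortably below the asserted
tolerances while keeping a full run in the minutes range on one CPU.

## Known limitations

* Repeat-region boundaries are phase-accurate only up to one period next
  to unit-like flanks; copy number is the robust readout.
* The greedy consensus segmentation can split highly diverged repeat
  regions; it does not implement profile-HMM style alignment-based repeat
  finding.
* The signal-peptide heuristic is a hydropathy filter; it knows nothing of
  cleavage sites or charge topology.
* Frameshift breakpoints inside repeats are one of several equivalent
  placements.
* The exact Mann–Whitney enumerates all `C(n_a+n_b, n_a)` labellings and
  is intended for the small-sample regime only (`exact_limit` default 12).
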