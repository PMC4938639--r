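# Deterministic synthetic stand-ins for reference sequences that are not
# redistributable with the package. Each encodes the published architecture
# of the real molecule (not its residues) so that the pipeline's behaviour
# on that architecture can be exercised offline. All are labelled synthetic
# in their ids.

#' Synthetic stand-in for the D. melanogaster Muc68E protein
#'
#' A deterministic protein with the documented Muc68E architecture: an
#' initiator methionine at position 1 from which no signal peptide is
#' called, a second conserved methionine at position 24 followed by a
#' hydrophobic h-region (the reconciled translation start), a central PTS
#' tandem-repeat region of 25 copies of a 39-residue unit carrying the
#' P[ED][ED][ST][ST][ST] motif twice per block and occupying ~82% of the
#' protein, and three strict chitin-binding type-2 domains at the
#' C-terminus. It is a synthetic stand-in, not the real sequence.
#'
#' @return A one-row sequence tibble (`id`, `description`, `seq`).
#' @export
synthetic_muc68e <- function() {
  leader <- "MDESNTPDSEQNTPDSETNQSDP"            # 23 aa, hydrophilic, one M
  start24 <- "M"
  hregion <- "ALLAVLLLVALLLAVSA"                 # 17 aa hydrophobic core
  linker <- "QAGNDT"                             # 6 aa
  unit <- "PEESTSAQTGVNDAPSTAQPEDSTTGANQVSTAGDQSVA"  # 39 aa, pattern1 x2
  stopifnot(nchar(unit) == 39L)
  repeats <- strrep(unit, 25L)
  with_local_seed(680001L, {
    spacers <- replicate(3, paste(sample(FILL_RESIDUES, 5, replace = TRUE),
                                  collapse = ""))
    doms <- replicate(3, cbt2_domain())
    cterm <- paste0(spacers[1], doms[1], spacers[2], doms[2],
                    spacers[3], doms[3], "GNDSA")
  })
  tibble(id = "Muc68E_synthetic",
         description = "synthetic stand-in with Muc68E architecture",
         seq = paste0(leader, start24, hregion, linker, repeats, cterm))
}

#' Synthetic stand-in for the Frost protein
#'
#' A deterministic 1000-residue protein with a positive signal-peptide
#' call, four P[ED][ED][ST][ST][ST] motifs not embedded in larger conserved
#' repeat blocks, and a serine+threonine fraction of exactly 24.1% — just
#' under the 25% mucin composition cut-off, the documented reason Frost is
#' not classified as a mucin despite resembling one.
#'
#' @return A one-row sequence tibble.
#' @export
synthetic_frost_like <- function() {
  nterm <- paste0("M", "ALLLVALLVALALLVSA")      # signal-positive start
  motifs <- c("PEESTS", "PDDSTT", "PEDSST", "PDESTS")
  with_local_seed(680002L, {
    # P-free, S/T-free filler so motif and composition counts stay planted
    filler <- function(n) paste(sample(c("A", "G", "N", "D", "E", "Q", "V",
                                         "K", "R", "L"), n, replace = TRUE),
                                collapse = "")
    body <- paste0(filler(120), motifs[1], filler(150), motifs[2],
                   filler(180), motifs[3], filler(160), motifs[4],
                   filler(100))
  })
  partial <- paste0(nterm, body)
  n_st <- sum(seq_chars(partial) %in% c("S", "T"))
  need_st <- 241L - n_st
  pad <- 1000L - nchar(partial) - need_st
  stopifnot(need_st >= 0L, pad >= 0L)
  seq <- paste0(partial, strrep("S", need_st), strrep("A", pad))
  tibble(id = "Fst_synthetic",
         description = "synthetic stand-in with Frost-like composition (24.1% S+T)",
         seq = seq)
}

#' Synthetic proteome with planted pattern-1 counts
#'
#' A small stand-in proteome for the multi-occurrence screen: the Muc68E
#' and Frost stand-ins, two proteins with exactly three planted pattern-1
#' motifs each (mimicking the two other multi-occurrence genes, a
#' mucin-related protein and a gut lipase), two proteins with one or two
#' motifs, and proline-free background proteins that cannot match.
#'
#' @param n_background Number of background proteins.
#' @param seed Integer seed.
#' @return A sequence tibble; only the first four entries carry pattern 1
#'   more than twice.
#' @export
synthetic_proteome <- function(n_background = 20L, seed = 680003L) {
  with_local_seed(seed, {
    pfree <- function(n) paste(sample(setdiff(AA20, c("P", "S", "T")), n,
                                      replace = TRUE), collapse = "")
    planted <- function(id, k) {
      segs <- replicate(k + 1L, pfree(80))
      mot <- sample(c("PEESTS", "PDDSTT", "PEDSTS"), k, replace = TRUE)
      tibble(id = id, description = "synthetic planted-motif protein",
             seq = paste0(paste0(segs[seq_len(k)], mot, collapse = ""),
                          segs[k + 1L]))
    }
    bg <- bind_rows(purrr::map(seq_len(n_background), function(i) {
      tibble(id = sprintf("bg%02d_synthetic", i),
             description = "synthetic background protein",
             seq = pfree(sample(200:400, 1L)))
    }))
    bind_rows(synthetic_muc68e(), synthetic_frost_like(),
              planted("Mur18B_synthetic", 3L),
              planted("CG6296_synthetic", 3L),
              planted("one_motif_synthetic", 1L),
              planted("two_motif_synthetic", 2L),
              bg)
  })
}

#' Synthetic stand-in for the concatenated 16-gene data set
#'
#' One record per species (default one), each the concatenation of 16
#' synthetic intronless coding sequences whose lengths sum to 11,988 bp —
#' the documented length of the real concatenated set in D. melanogaster.
#' Sequences are random coding-style DNA (ATG start per gene, no planted
#' homology); the record is a synthetic stand-in for loader and length
#' checks, not biological sequence.
#'
#' @param species Character vector of species labels.
#' @param seed Integer seed.
#' @return A nucleotide sequence tibble.
#' @export
synthetic_concat16 <- function(species = "Dmel", seed = 680004L) {
  gene_lens <- c(1230, 903, 612, 747, 1089, 666, 735, 564,
                 810, 693, 459, 531, 882, 441, 369, 1257)
  stopifnot(sum(gene_lens) == 11988L, all(gene_lens %% 3 == 0))
  with_local_seed(seed, {
    bind_rows(purrr::map(species, function(sp) {
      genes <- vapply(gene_lens, function(L) {
        paste0("ATG", paste(sample(c("A", "C", "G", "T"), L - 3L,
                                   replace = TRUE), collapse = ""))
      }, character(1))
      tibble(id = paste0(sp, "_16gene_concat_synthetic"),
             description = "synthetic concatenated 16-gene coding set (11988 bp)",
             seq = paste(genes, collapse = ""))
    }))
  })
}
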