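#' Reverse-complement a character vector of DNA sequences
#'
#' Thin wrapper around [Biostrings::reverseComplement()] that keeps plain
#' character vectors as the working currency of the package.
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Linker and primer set for the asymmetric end-capture protocol
#'
#' Holds the oligonucleotides of the two branched linkers, the bridge
#' amplification primers, and the type IIS (Mme I) cutting geometry. The
#' defaults are the published protocol oligos. Linker A carries the Mme I
#' recognition site (TCCGAC) at its ligation end so that digestion releases
#' about 20 bp of genomic DNA with a 2-nt 3' overhang; linker B is a pool of
#' molecules differing only in the NN overhang.
#'
#' @param linkerA_top,linkerA_bottom Linker A strands (5'->3').
#' @param linkerB_top,linkerB_bottom Linker B strands (5'->3'); `linkerB_top`
#'   ends in `"NN"`, the degenerate 2-nt overhang.
#' @param bridge_primers Character vector of the two PCR bridge primers.
#' @param mme_offset Modal top-strand cut distance of Mme I from its site, in
#'   genomic bases captured (default 20).
#' @param mme_slop Named numeric vector of probabilities over captured
#'   top-strand lengths, modelling Mme I cut-distance heterogeneity.
#' @return An object of class `dalec_linkers`.
#' @export
linker_set <- function(linkerA_top = "CAAGCAGAAGACGGCATACGATCCTGAGTACACTATGTTCCGAC",
                       linkerA_bottom = "GTCGGAACATAGTGTAGCA",
                       linkerB_top = "TCATCTTTCCCTACACGACGCTCTTCCGATCTNN",
                       linkerB_bottom = "AGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGTCGGTGGTCGCCGTATCATT",
                       bridge_primers = c("AATGATACGGCGACCACCGA",
                                          "CAAGCAGAAGACGGCATACGA"),
                       mme_offset = 20L,
                       mme_slop = c(`19` = 0.15, `20` = 0.70, `21` = 0.15)) {
  stopifnot(length(bridge_primers) == 2L,
            abs(sum(mme_slop) - 1) < 1e-8,
            all(as.integer(names(mme_slop)) > 0L))
  structure(list(
    linkerA_top = linkerA_top,
    linkerA_bottom = linkerA_bottom,
    linkerB_top = linkerB_top,
    linkerB_bottom = linkerB_bottom,
    bridge_primers = bridge_primers,
    mme_offset = as.integer(mme_offset),
    mme_slop = mme_slop,
    # the read's 3' side: reverse complement of linker A's top strand
    read_linker_suffix = revcomp(linkerA_top)
  ), class = "dalec_linkers")
}

#' Assemble the doubly-linkered library molecule around a captured tag
#'
#' Reconstructs the two strands of the final library molecule from a captured
#' genomic insert: the top strand is linker A's top strand, the genomic
#' top-strand insert, and the reverse complement of linker B's bottom strand;
#' the bottom strand is linker B's top strand (its degenerate NN resolved to
#' the complement of the insert's 2-nt 3' overhang), the genomic bottom-strand
#' portion (2 nt shorter than the top, reflecting the 20/18 type IIS cut), and
#' linker A's bottom strand. With the default oligos and a 20-nt insert this
#' yields a 116-nt top strand and a 71-nt bottom strand.
#'
#' @param insert_top Genomic insert as it appears on the library top strand
#'   (typically 19-21 nt).
#' @param linkers A [linker_set()].
#' @return List with elements `top_strand`, `bottom_strand`, `amplicon_length`
#'   (= top-strand length), and `amplifiable` (both bridge primers anneal).
#' @export
assemble_library_molecule <- function(insert_top, linkers = linker_set()) {
  stopifnot(is.character(insert_top), length(insert_top) == 1L, nchar(insert_top) >= 2L)
  top <- paste0(linkers$linkerA_top, insert_top, revcomp(linkers$linkerB_bottom))
  # bottom-strand genomic portion: complement of the insert minus the 2-nt
  # 3' overhang left by the type IIS cut
  insert_bottom <- revcomp(substr(insert_top, 1L, nchar(insert_top) - 2L))
  overhang <- substr(insert_top, nchar(insert_top) - 1L, nchar(insert_top))
  b_top <- sub("NN$", revcomp(overhang), linkers$linkerB_top)
  bottom <- paste0(b_top, insert_bottom, linkers$linkerA_bottom)
  amplifiable <- bridge_primers_anneal(top, linkers)
  list(top_strand = top, bottom_strand = bottom,
       amplicon_length = nchar(top), amplifiable = amplifiable)
}

#' Do both bridge primers anneal to a library top strand?
#'
#' Primer 2 must be a prefix of the top strand (it primes synthesis of the
#' complementary strand); primer 1 must occur in forward orientation at the
#' top strand's 3' linker so that it primes top-sense synthesis off the
#' complementary strand.
#'
#' @param top_strand Single-stranded library molecule (character).
#' @param linkers A [linker_set()].
#' @return Logical scalar.
#' @export
bridge_primers_anneal <- function(top_strand, linkers = linker_set()) {
  p1 <- linkers$bridge_primers[1]
  p2 <- linkers$bridge_primers[2]
  startsWith(top_strand, p2) &&
    grepl(p1, top_strand, fixed = TRUE) &&
    startsWith(revcomp(linkers$linkerB_bottom), p1)
}
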