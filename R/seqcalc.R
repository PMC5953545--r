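# Sequence-derived quantities: molar extinction coefficients for
# proteins (280 nm) and DNA (260 nm), and residue counts.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Trp / Tyr / cystine contributions at 280 nm (M^-1 cm^-1)
E280_TRP <- 5500
E280_TYR <- 1490
E280_CYSTINE <- 125

# Single-strand DNA nearest-neighbor extinction table at 260 nm
# (Cantor-Warshaw-Shapiro dimer values) and base (monomer) values,
# M^-1 cm^-1.
NN_E260 <- c(
  AA = 27400, AC = 21200, AG = 25000, AT = 22800,
  CA = 21200, CC = 14600, CG = 18000, CT = 15200,
  GA = 25200, GC = 17600, GG = 21600, GT = 20000,
  TA = 23400, TC = 16200, TG = 19000, TT = 16800)
BASE_E260 <- c(A = 15400, C = 7400, G = 11500, T = 8700)

# Duplex hypochromicity at 260 nm as a function of base-pair fractions
# (Tataurov-You-Owczarzy): h = 0.287 f_AT + 0.059 f_GC.
H_AT <- 0.287
H_GC <- 0.059

clean_seq <- function(seq, alphabet, name) {
  seq <- toupper(gsub("[[:space:]]", "", paste(seq, collapse = "")))
  chars <- strsplit(seq, "")[[1]]
  bad <- setdiff(unique(chars), alphabet)
  if (length(bad)) {
    stop(sprintf("invalid %s letter(s): %s", name,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  chars
}

#' Protein molar extinction coefficient at 280 nm
#'
#' Chromophore counting: `5500 nW + 1490 nY + 125 n_cystine`. By default
#' cysteines are treated as reduced (free thiols, zero contribution),
#' which matches quantification practice for constructs kept in
#' reducing buffer — including zinc-coordinating domains whose cysteines
#' are ligated, not disulfide-bonded.
#'
#' @param seq one-letter amino-acid sequence (string or character
#'   vector; whitespace ignored).
#' @param reduced if `FALSE`, every cysteine pair is counted as a
#'   cystine.
#' @return Extinction coefficient in M^-1 cm^-1.
#' @examples
#' protein_e280("ARTKQTARKSTGGKAPRKQLATKAARKSAPATGGVKKPHRYRPG")  # 1490
#' @export
protein_e280 <- function(seq, reduced = TRUE) {
  chars <- clean_seq(seq, AA_ALPHABET, "amino-acid")
  n_w <- sum(chars == "W")
  n_y <- sum(chars == "Y")
  n_ss <- if (reduced) 0L else sum(chars == "C") %/% 2L
  E280_TRP * n_w + E280_TYR * n_y + E280_CYSTINE * n_ss
}

#' Single-strand DNA extinction coefficient at 260 nm
#'
#' Nearest-neighbor sum: the dimer values of all adjacent pairs minus
#' the monomer values of the internal bases,
#' `sum(eps_pair) - sum(eps_internal_base)`. Order matters (`"AT"` and
#' `"TA"` differ).
#'
#' @param strand sequence 5'->3', alphabet ACGT, length >= 2 (pass
#'   `monomer = TRUE` to get the monomer value of a single base).
#' @param monomer allow length-1 input.
#' @return Extinction coefficient in M^-1 cm^-1.
#' @examples
#' ss_dna_e260("AT")  # 22800
#' @export
ss_dna_e260 <- function(strand, monomer = FALSE) {
  chars <- clean_seq(strand, names(BASE_E260), "DNA")
  n <- length(chars)
  if (n < 2L) {
    if (isTRUE(monomer) && n == 1L) return(unname(BASE_E260[chars]))
    stop("strand must have length >= 2 (or set `monomer = TRUE`)",
         call. = FALSE)
  }
  pairs <- paste0(chars[-n], chars[-1L])
  sum(NN_E260[pairs]) - if (n > 2L)
    sum(BASE_E260[chars[-c(1L, n)]]) else 0
}

#' Reverse complement of a DNA sequence
#'
#' @param strand sequence 5'->3'.
#' @return The reverse complement, 5'->3'.
#' @export
reverse_complement <- function(strand) {
  chars <- clean_seq(strand, names(BASE_E260), "DNA")
  paste(rev(chartr("ACGT", "TGCA", chars)), collapse = "")
}

#' Duplex DNA extinction coefficient at 260 nm
#'
#' Sum of the two single-strand nearest-neighbor coefficients, reduced
#' by duplex hypochromicity taken linear in the base-pair composition:
#' \deqn{\epsilon_{ds} = (1 - h)(\epsilon_{top} + \epsilon_{bottom}),
#'   \quad h = 0.287 f_{AT} + 0.059 f_{GC}}
#' This is the model behind vendor UV duplex calculators.
#'
#' @param top top strand 5'->3'.
#' @param bottom bottom strand 5'->3'; defaults to the reverse
#'   complement of `top`, and is checked for complementarity when
#'   supplied.
#' @return Extinction coefficient in M^-1 cm^-1.
#' @examples
#' duplex_e260("CTCAATTGGTCGTAGACAGCT")  # 333804.5 for the 21-mer
#' @export
duplex_e260 <- function(top, bottom = NULL) {
  topc <- clean_seq(top, names(BASE_E260), "DNA")
  top <- paste(topc, collapse = "")
  if (is.null(bottom)) {
    bottom <- reverse_complement(top)
  } else {
    bottom <- paste(clean_seq(bottom, names(BASE_E260), "DNA"),
                    collapse = "")
    if (!identical(bottom, reverse_complement(top))) {
      stop("strands are not reverse-complementary", call. = FALSE)
    }
  }
  f_at <- mean(topc %in% c("A", "T"))
  h <- H_AT * f_at + H_GC * (1 - f_at)
  (1 - h) * (ss_dna_e260(top) + ss_dna_e260(bottom))
}

#' Count non-proline residues
#'
#' The number of residues that can give rise to a backbone amide peak in
#' a 1H-15N correlation spectrum (prolines lack the amide proton).
#'
#' @param seq one-letter amino-acid sequence.
#' @return Integer count of residues that are not proline.
#' @export
count_non_proline <- function(seq) {
  chars <- clean_seq(seq, AA_ALPHABET, "amino-acid")
  sum(chars != "P")
}

#' Read sequences from FASTA
#'
#' Thin wrapper returning plain uppercase strings named by record.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta_seqs <- function(path) {
  recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  out <- toupper(vapply(recs, function(r) as.character(r)[1], ""))
  names(out) <- names(recs)
  out
}

#' Bundled reference sequences
#'
#' FASTA fixtures shipped with the package: the 44-residue H3 N-terminal
#' tail construct, the 21 bp oligonucleotide duplex strands, and the
#' 147 bp Widom 601 nucleosome-positioning sequence.
#'
#' @param which one of `"h3_tail"`, `"oligo21"`, `"widom601"`.
#' @return Named character vector of sequences.
#' @examples
#' protein_e280(tailscape_sequences("h3_tail"))
#' @export
tailscape_sequences <- function(which = c("h3_tail", "oligo21",
                                          "widom601")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0(which, ".fasta"),
                      package = "tailscape", mustWork = TRUE)
  read_fasta_seqs(path)
}
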