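# Restriction enzymes and IUPAC motif scanning.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Define a restriction enzyme
#'
#' A restriction enzyme is a named IUPAC recognition motif together with a
#' cut offset: the number of bases from the motif start, on the top strand,
#' at which the backbone is cleaved. `EcoRI` cuts G/AATTC, i.e. motif
#' `GAATTC` with `cut_offset = 1`.
#'
#' @param name enzyme name.
#' @param recognition recognition motif, 4-8 bases, IUPAC ambiguity codes
#'   allowed.
#' @param cut_offset integer in `[0, nchar(recognition)]`; bases from the
#'   motif start to the top-strand cut.
#' @return An object of class `restriction_enzyme`.
#' @seealso [ddgbs_enzymes()] for the built-in registry.
#' @export
#' @examples
#' restriction_enzyme("EcoRI", "GAATTC", 1)
restriction_enzyme <- function(name, recognition, cut_offset) {
  recognition <- toupper(recognition)
  letters <- strsplit(recognition, "", fixed = TRUE)[[1]]
  bad <- setdiff(letters, names(IUPAC_SETS))
  if (length(bad) > 0)
    stop("unknown IUPAC code(s) in recognition motif: ",
         paste(bad, collapse = ", "), call. = FALSE)
  check_that(nchar(recognition) >= 4 && nchar(recognition) <= 8,
             "recognition motif must be 4-8 bases")
  cut_offset <- as.integer(cut_offset)
  check_that(cut_offset >= 0 && cut_offset <= nchar(recognition),
             "cut_offset must lie within [0, motif length]")
  structure(list(name = name, recognition = recognition,
                 cut_offset = cut_offset),
            class = "restriction_enzyme")
}

#' @export
print.restriction_enzyme <- function(x, ...) {
  motif <- x$recognition
  cat(sprintf("<restriction_enzyme> %s: %s/%s\n", x$name,
              substr(motif, 1, x$cut_offset),
              substr(motif, x$cut_offset + 1, nchar(motif))))
  invisible(x)
}

#' Built-in enzyme registry
#'
#' The seven enzymes commonly screened for reduced-representation library
#' design of vertebrate genomes, with their recognition motifs and
#' top-strand cut offsets (slash notation: EcoRI G/AATTC, HinP1I G/CGC,
#' ApeKI G/CWGC, PstI CTGCA/G, MseI T/TAA, MspI C/CGG, BglII A/GATCT).
#' All seven motifs are reverse-complement palindromes under IUPAC
#' ambiguity, so top- and bottom-strand scans yield identical cut sets.
#'
#' @param name optional enzyme name; when given, the single enzyme is
#'   returned (case-insensitive, "EcoRI" or "EcoR I" both accepted).
#' @return A named list of [restriction_enzyme] objects, or one enzyme.
#' @export
#' @examples
#' ddgbs_enzymes("MseI")
#' names(ddgbs_enzymes())
ddgbs_enzymes <- function(name = NULL) {
  reg <- list(
    EcoRI  = restriction_enzyme("EcoRI",  "GAATTC", 1L),
    HinP1I = restriction_enzyme("HinP1I", "GCGC",   1L),
    ApeKI  = restriction_enzyme("ApeKI",  "GCWGC",  1L),
    PstI   = restriction_enzyme("PstI",   "CTGCAG", 5L),
    MseI   = restriction_enzyme("MseI",   "TTAA",   1L),
    MspI   = restriction_enzyme("MspI",   "CCGG",   1L),
    BglII  = restriction_enzyme("BglII",  "AGATCT", 1L)
  )
  if (is.null(name)) return(reg)
  key <- gsub("[ _]", "", name)
  hit <- match(tolower(key), tolower(names(reg)))
  if (is.na(hit)) stop("unknown enzyme: ", name,
                       " (known: ", paste(names(reg), collapse = ", "), ")",
                       call. = FALSE)
  reg[[hit]]
}

as_enzyme <- function(x) {
  if (inherits(x, "restriction_enzyme")) x else ddgbs_enzymes(x)
}

# logical[256] lookup: which raw byte values a motif letter matches.
# Genome ambiguity codes are matched by motif N only; any other motif
# letter matches just the plain bases in its IUPAC set. This keeps
# assembly-gap N runs from producing spurious cut sites.
motif_letter_table <- function(letter) {
  tab <- logical(256)
  chars <- if (letter == "N") names(IUPAC_SETS) else IUPAC_SETS[[letter]]
  tab[as.integer(charToRaw(paste(chars, collapse = ""))) + 1L] <- TRUE
  tab
}

# 1-based start positions of IUPAC `motif` in raw byte vector `sraw`.
scan_motif_raw <- function(sraw, motif) {
  n <- length(sraw)
  letters <- strsplit(motif, "", fixed = TRUE)[[1]]
  L <- length(letters)
  if (n < L) return(integer(0))
  hits <- rep(TRUE, n - L + 1L)
  for (j in seq_len(L)) {
    tab <- motif_letter_table(letters[j])
    hits <- hits & tab[as.integer(sraw[j:(n - L + j)]) + 1L]
  }
  which(hits)
}

#' Locate restriction cut sites in a DNA sequence
#'
#' Scans both strands for the enzyme's recognition motif (IUPAC ambiguity
#' codes expanded) and returns cut positions as 0-based between-base
#' coordinates: position `p` means the backbone is cut between base
#' `p - 1` and base `p`. Each duplex site yields one cut: at `cut_offset`
#' from the motif start for top-strand matches, at the mirrored offset
#' for sites found only on the bottom strand (non-palindromic motifs).
#' For the built-in palindromic enzymes the double-strand scan therefore
#' equals the single-strand scan. Overlapping degenerate matches each
#' contribute a cut; coordinates are deduplicated and sorted. Cuts that
#' would fall exactly on a sequence boundary are dropped (they cleave
#' nothing). Ambiguity letters in the sequence (e.g. `N` runs in assembly
#' gaps) are matched only by motif letter `N`.
#'
#' @param sequence a single DNA string (character).
#' @param enzyme a [restriction_enzyme], or an enzyme name resolved via
#'   [ddgbs_enzymes()].
#' @param both_strands scan the reverse strand as well (default). For the
#'   seven built-in enzymes the motifs are reverse-complement palindromes
#'   and the extra scan changes nothing.
#' @return Sorted integer vector of 0-based cut positions.
#' @export
#' @examples
#' find_cut_sites("GAATTC", "EcoRI") # 1
#' find_cut_sites("CCGAATTCCCTTAACC", "MseI") # 11
find_cut_sites <- function(sequence, enzyme, both_strands = TRUE) {
  enzyme <- as_enzyme(enzyme)
  check_that(is.character(sequence) && length(sequence) == 1 &&
               nchar(sequence) > 0, "sequence must be one non-empty string")
  sraw <- charToRaw(toupper(sequence))
  n <- length(sraw)
  L <- nchar(enzyme$recognition)
  top <- scan_motif_raw(sraw, enzyme$recognition)
  cuts <- top - 1L + enzyme$cut_offset
  if (both_strands) {
    # a duplex site matched on both strands is one site, one cut; only
    # bottom-strand-exclusive matches (non-palindromic motifs) add cuts,
    # mapped through the mirrored offset: start s -> s + (L - cut_offset)
    bottom <- setdiff(scan_motif_raw(sraw, rev_comp(enzyme$recognition)), top)
    cuts <- c(cuts, bottom - 1L + (L - enzyme$cut_offset))
  }
  cuts <- sort(unique(cuts))
  cuts[cuts > 0L & cuts < n]
}
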