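# In silico digestion: fragments, end labels, size selection, histograms.

#' Read a genome from FASTA
#'
#' Loads a (multi-record, wrapped or unwrapped) FASTA file into the plain
#' genome representation used throughout the package: a named character
#' vector of uppercase sequences, one element per record. Record names are
#' truncated at the first whitespace.
#'
#' @param path FASTA file path.
#' @return Named character vector of uppercase DNA sequences.
#' @export
read_genome_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  g <- toupper(as.character(dss))
  names(g) <- sub("\\s.*$", "", names(dss))
  check_that(!anyDuplicated(names(g)), "duplicate sequence names in FASTA")
  g
}

#' Write a genome to FASTA
#'
#' @param genome named character vector of DNA sequences.
#' @param path output path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

as_genome <- function(genome) {
  if (is.null(names(genome)))
    names(genome) <- paste0("seq", seq_along(genome))
  check_that(is.character(genome) && all(nchar(genome) > 0),
             "genome must be a character vector of non-empty sequences")
  check_that(!anyDuplicated(names(genome)), "genome sequence names not unique")
  toupper(genome)
}

size_histogram <- function(lengths, binwidth = 10) {
  if (length(lengths) == 0)
    return(data.frame(bin_start = integer(0), bin_end = integer(0),
                      count = integer(0)))
  bin <- (lengths - 1L) %/% binwidth   # lengths are >= 1
  tab <- table(bin)
  b <- as.integer(names(tab))
  data.frame(bin_start = b * binwidth + 1L,
             bin_end = (b + 1L) * binwidth,
             count = as.integer(tab))
}

new_digest_result <- function(fragments, enzymes, binwidth, size_window = NULL,
                              ab_only = FALSE) {
  cls <- factor(fragments$class, levels = c("AB", "AA", "BB", "terminal"))
  structure(list(
    fragments = fragments,
    class_counts = c(table(cls)),
    size_histogram = size_histogram(fragments$length, binwidth),
    enzymes = enzymes,
    binwidth = binwidth,
    size_window = size_window,
    ab_only = ab_only
  ), class = "digest_result")
}

#' Double-enzyme in silico digestion
#'
#' Digests every sequence of a genome with two restriction enzymes. Cut
#' positions of both enzymes are merged and sorted; consecutive cuts
#' delimit fragments that tile each sequence without gaps or overlaps.
#' Each internal fragment end is labelled with the enzyme that produced
#' its bounding cut; a coordinate cut by both enzymes is labelled by
#' enzyme A (documented precedence) and counted once.
#'
#' Fragment classes:
#' \describe{
#'   \item{AB}{one end from each enzyme -- the sequenceable class, since
#'     the barcode adapter ligates only to enzyme-A overhangs and the
#'     common adapter only to enzyme-B overhangs;}
#'   \item{AA, BB}{both ends from the same enzyme;}
#'   \item{terminal}{touches a sequence boundary (lacks one ligatable
#'     overhang, excluded from library simulation).}
#' }
#'
#' @param genome named character vector of DNA sequences (see
#'   [read_genome_fasta()]), or a single unnamed string.
#' @param enzA,enzB [restriction_enzyme] objects or names. Must differ.
#' @param binwidth width (bp) of the fragment size histogram bins.
#' @return A `digest_result`: list with `fragments` (data frame with
#'   `seq_name`, 0-based half-open `start`/`end`, `left_end`, `right_end`,
#'   `length`, `class`), `class_counts`, and `size_histogram`.
#' @export
#' @examples
#' dd <- double_digest(c(chr = "CCGAATTCCCTTAACC"), "EcoRI", "MseI")
#' dd$fragments
double_digest <- function(genome, enzA, enzB, binwidth = 10) {
  enzA <- as_enzyme(enzA); enzB <- as_enzyme(enzB)
  check_that(enzA$name != enzB$name, "enzA and enzB must be different enzymes")
  digest_genome(genome, list(enzA, enzB), binwidth = binwidth)
}

#' Single-enzyme in silico digestion
#'
#' @inheritParams double_digest
#' @param enzyme the enzyme.
#' @return A `digest_result`; internal fragments are class `AA`.
#' @export
single_digest <- function(genome, enzyme, binwidth = 10) {
  digest_genome(genome, list(as_enzyme(enzyme)), binwidth = binwidth)
}

digest_genome <- function(genome, enzymes, binwidth = 10) {
  genome <- as_genome(genome)
  nmA <- enzymes[[1]]$name
  nmB <- if (length(enzymes) > 1) enzymes[[2]]$name else NULL
  per_seq <- lapply(names(genome), function(sq) {
    seqstr <- genome[[sq]]
    n <- nchar(seqstr)
    cutsA <- find_cut_sites(seqstr, enzymes[[1]])
    if (!is.null(nmB)) {
      cutsB <- setdiff(find_cut_sites(seqstr, enzymes[[2]]), cutsA)
    } else cutsB <- integer(0)
    cuts <- c(cutsA, cutsB)
    labs <- c(rep(nmA, length(cutsA)), rep(nmB %||% nmA, length(cutsB)))
    o <- order(cuts)
    cuts <- cuts[o]; labs <- labs[o]
    bounds <- c(0L, cuts, n)
    blabs <- c("chrom_start", labs, "chrom_end")
    k <- length(bounds) - 1L
    data.frame(
      seq_name = rep(sq, k),
      start = bounds[-length(bounds)],
      end = bounds[-1],
      left_end = blabs[seq_len(k)],
      right_end = blabs[seq_len(k) + 1L],
      stringsAsFactors = FALSE
    )
  })
  frags <- do.call(rbind, per_seq)
  frags$length <- frags$end - frags$start
  frags$class <- fragment_class(frags$left_end, frags$right_end, nmA, nmB)
  rownames(frags) <- NULL
  new_digest_result(frags, enzymes, binwidth)
}

fragment_class <- function(left, right, nmA, nmB) {
  cls <- character(length(left))
  terminal <- left == "chrom_start" | right == "chrom_end"
  cls[terminal] <- "terminal"
  both <- !terminal
  if (is.null(nmB)) {
    cls[both] <- "AA"
  } else {
    cls[both & left == nmA & right == nmA] <- "AA"
    cls[both & left == nmB & right == nmB] <- "BB"
    cls[both & ((left == nmA & right == nmB) |
                (left == nmB & right == nmA))] <- "AB"
  }
  cls
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Size-select fragments from a digestion
#'
#' Restricts a digestion result to fragments with
#' `min_len <= length <= max_len`, emulating library size selection
#' (e.g. a 300-650 bp bead-selection window) as a hard window. By default
#' only class-AB fragments are retained, since only they carry both
#' adapters and are sequenced.
#'
#' @param result a `digest_result`.
#' @param min_len,max_len inclusive length window in bp.
#' @param ab_only keep only class-AB fragments (default `TRUE`).
#' @return A `digest_result` restricted to the selection, with class
#'   counts and size histogram recomputed. An empty selection is valid
#'   and raises a warning.
#' @export
size_select <- function(result, min_len = 300, max_len = 650, ab_only = TRUE) {
  check_that(inherits(result, "digest_result"), "result must be a digest_result")
  check_that(min_len > 0 && min_len <= max_len,
             "need 0 < min_len <= max_len")
  fr <- result$fragments
  keep <- fr$length >= min_len & fr$length <= max_len
  if (ab_only) keep <- keep & fr$class == "AB"
  if (!any(keep)) warning("size selection retained no fragments")
  new_digest_result(fr[keep, , drop = FALSE], result$enzymes,
                    result$binwidth, size_window = c(min_len, max_len),
                    ab_only = ab_only)
}

#' @export
print.digest_result <- function(x, ...) {
  enz <- paste(vapply(x$enzymes, `[[`, "", "name"), collapse = "-")
  cat(sprintf("<digest_result> %s: %d fragments over %d sequence(s)\n",
              enz, nrow(x$fragments), length(unique(x$fragments$seq_name))))
  print(x$class_counts)
  if (!is.null(x$size_window))
    cat(sprintf("size window: %d-%d bp%s\n", x$size_window[1],
                x$size_window[2], if (x$ab_only) " (AB only)" else ""))
  invisible(x)
}

#' @export
plot.digest_result <- function(x, ...) {
  h <- x$size_histogram
  graphics::plot(h$bin_start, h$count, type = "h",
                 xlab = "fragment length (bp)", ylab = "fragments", ...)
  invisible(x)
}

#' Write fragments as BED
#'
#' BED columns: chrom, 0-based start, end, name = fragment class,
#' score = length.
#'
#' @param result a `digest_result`.
#' @param path output path.
#' @export
write_fragments_bed <- function(result, path) {
  fr <- result$fragments
  utils::write.table(
    data.frame(fr$seq_name, fr$start, fr$end, fr$class, fr$length),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a fragment size histogram as TSV
#'
#' @param result a `digest_result`.
#' @param path output path.
#' @export
write_size_histogram <- function(result, path) {
  enz <- paste(vapply(result$enzymes, `[[`, "", "name"), collapse = "-")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fragment size histogram; enzymes=%s binwidth=%d",
                     enz, result$binwidth), con)
  utils::write.table(result$size_histogram, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
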