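# Tag tables: unique trimmed read sequences, counted per sample and
# assigned to fragments. The input of all sequencing-side metrics.

#' Build a tag table
#'
#' A tag is a unique (barcode-trimmed) read sequence; a fragment is the
#' locus a set of tags occupies. A tag table records, per sample, each
#' tag's read count and fragment assignment.
#'
#' @param sample sample identifier per row.
#' @param fragment fragment identifier per row.
#' @param tag tag sequence (or any unique tag key) per row.
#' @param count read count per row (>= 1).
#' @return A `tag_table` data frame.
#' @export
tag_table <- function(sample, fragment, tag, count) {
  check_that(all(count >= 1), "tag counts must be >= 1")
  df <- data.frame(sample = sample, fragment = fragment, tag = tag,
                   count = as.integer(count), stringsAsFactors = FALSE)
  check_that(!anyDuplicated(df[c("sample", "tag")]),
             "duplicate (sample, tag) rows")
  structure(df, class = c("tag_table", "data.frame"))
}

#' Index fragments by their expected read prefix
#'
#' Builds a lookup from the error-free read prefix of each class-AB
#' fragment to the fragment's identity, used to assign observed tags to
#' fragments by exact prefix match (a desk-scale stand-in for alignment).
#' Reads start at the enzyme-A cut of each fragment: on the top strand
#' when the left end is enzyme A, on the reverse strand otherwise.
#'
#' @param digest a `digest_result` (typically size-selected, AB-only).
#' @param genome the genome the digest came from.
#' @param read_length simulated/observed read length after barcode
#'   trimming.
#' @param key_length prefix length used as the lookup key.
#' @return A `fragment_index`: list with `keys` (named character:
#'   key -> fragment id), `templates` (error-free full-length reads),
#'   `fragments` (the fragment table with `fragment_id` and `strand`).
#' @export
fragment_read_index <- function(digest, genome, read_length = 91,
                                key_length = 32) {
  genome <- as_genome(genome)
  enzA <- digest$enzymes[[1]]$name
  fr <- digest$fragments
  fr <- fr[fr$class == "AB", , drop = FALSE]
  check_that(nrow(fr) > 0, "no AB fragments to index")
  fr$fragment_id <- sprintf("%s:%d-%d", fr$seq_name, fr$start, fr$end)
  fr$strand <- ifelse(fr$left_end == enzA, "+", "-")
  tl <- pmin(fr$length, read_length)
  templates <- ifelse(
    fr$strand == "+",
    substring(genome[fr$seq_name], fr$start + 1L, fr$start + tl),
    rev_comp(substring(genome[fr$seq_name], fr$end - tl + 1L, fr$end)))
  keys <- substr(templates, 1, key_length)
  dup <- duplicated(keys) | duplicated(keys, fromLast = TRUE)
  if (any(dup))
    warning(sum(dup), " fragments share a read prefix key; kept first")
  lookup <- structure(fr$fragment_id[!duplicated(keys)],
                      names = keys[!duplicated(keys)])
  structure(list(keys = lookup, templates = templates, fragments = fr,
                 read_length = read_length, key_length = key_length),
            class = "fragment_index")
}

#' Tally tags and assign them to fragments
#'
#' Collapses demultiplexed reads into tags (unique sequences with
#' counts) per sample and assigns each tag to a fragment through a
#' [fragment_read_index()]. Tags whose prefix matches no fragment
#' (sequencing errors in the key window, off-target reads) are dropped
#' and counted in the `unassigned_tags` attribute.
#'
#' @param demux a `demux_result`, or a named list of per-sample character
#'   vectors / data frames of trimmed read sequences.
#' @param index a `fragment_index`.
#' @return A `tag_table` with attribute `unassigned_tags`.
#' @export
tally_tags <- function(demux, index) {
  per_sample <- if (inherits(demux, "demux_result")) demux$reads else demux
  rows <- lapply(names(per_sample), function(s) {
    seqs <- per_sample[[s]]
    if (is.data.frame(seqs)) seqs <- seqs$seq
    if (length(seqs) == 0) return(NULL)
    tab <- table(seqs)
    data.frame(sample = s, tag = names(tab), count = as.integer(tab),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  check_that(!is.null(df) && nrow(df) > 0, "no reads to tally")
  frag <- unname(index$keys[substr(df$tag, 1, index$key_length)])
  dropped <- sum(is.na(frag))
  keep <- !is.na(frag)
  out <- tag_table(df$sample[keep], frag[keep], df$tag[keep], df$count[keep])
  attr(out, "unassigned_tags") <- dropped
  out
}
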