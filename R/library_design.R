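# Barcode design, adapter molar ratios, demultiplexing, FASTQ plumbing.

#' Generate a GBS barcode set
#'
#' Draws random barcodes satisfying the design constraints used for
#' sequencer-friendly GBS barcode sets:
#' \itemize{
#'   \item lengths vary across `length_range` (default 6-9 bases), which
#'     staggers the restriction-site position across the flow cell;
#'   \item no barcode begins with `GG` (two-channel sequencers read G as
#'     a dark base and an initial GG degrades registration);
#'   \item pairwise Hamming distance over the shared prefix length at
#'     least `min_distance` (demultiplexing is prefix-based);
#'   \item no barcode, concatenated to the enzyme-A overhang remnant,
#'     recreates the recognition site of either library enzyme (which
#'     would be cleaved or confuse trimming).
#' }
#'
#' The search is rejection sampling; it stops with an informative error
#' naming the binding constraint if `max_rejects` consecutive candidates
#' fail (the constraint space is exhausted or nearly so).
#'
#' @param n number of barcodes (samples).
#' @param length_range integer vector `c(min, max)` of barcode lengths.
#' @param min_distance minimum pairwise Hamming distance over the shorter
#'   barcode's length.
#' @param seed RNG seed; the set is deterministic given the seed.
#' @param enzA,enzB library enzymes (objects or names) used for the
#'   site-recreation check; defaults EcoRI / MseI.
#' @param sample_ids optional character vector of `n` sample names.
#' @param max_rejects consecutive-rejection budget before giving up.
#' @return A `barcode_set`: data frame with `sample_id` and `barcode`.
#' @export
#' @examples
#' generate_barcodes(4, c(6, 9), min_distance = 3, seed = 1)
generate_barcodes <- function(n, length_range = c(6, 9), min_distance = 3,
                              seed = NULL, enzA = "EcoRI", enzB = "MseI",
                              sample_ids = NULL, max_rejects = 10000) {
  check_that(n >= 1, "n must be >= 1")
  enzA <- as_enzyme(enzA); enzB <- as_enzyme(enzB)
  # overhang remnant left on the read after the enzyme-A cut
  remnant <- substr(enzA$recognition, enzA$cut_offset + 1,
                    nchar(enzA$recognition))
  lens <- seq.int(length_range[1], length_range[2])
  with_seed(seed, {
    accepted <- character(0)
    fails <- c(gg_start = 0L, site_recreated = 0L, min_distance = 0L)
    rejects <- 0L
    while (length(accepted) < n) {
      if (rejects >= max_rejects) {
        top <- names(fails)[which.max(fails)]
        stop(sprintf(paste0(
          "barcode space exhausted after %d consecutive rejections while ",
          "searching for barcode %d of %d (binding constraint: %s; ",
          "rejections: %s)"), rejects, length(accepted) + 1L, n, top,
          paste(sprintf("%s=%d", names(fails), fails), collapse = ", ")),
          call. = FALSE)
      }
      L <- if (length(lens) == 1) lens else sample(lens, 1)
      cand <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                    collapse = "")
      if (startsWith(cand, "GG")) {
        fails["gg_start"] <- fails["gg_start"] + 1L; rejects <- rejects + 1L
        next
      }
      ext <- paste0(cand, remnant)
      if (length(find_cut_sites(ext, enzA)) > 0 ||
          length(find_cut_sites(ext, enzB)) > 0) {
        fails["site_recreated"] <- fails["site_recreated"] + 1L
        rejects <- rejects + 1L
        next
      }
      if (any(vapply(accepted, prefix_hamming, 0L, cand) < min_distance)) {
        fails["min_distance"] <- fails["min_distance"] + 1L
        rejects <- rejects + 1L
        next
      }
      accepted <- c(accepted, cand)
      rejects <- 0L
    }
    ids <- sample_ids %||% sprintf("S%02d", seq_len(n))
    check_that(length(ids) == n, "sample_ids must have length n")
    structure(data.frame(sample_id = ids, barcode = accepted,
                         stringsAsFactors = FALSE),
              class = c("barcode_set", "data.frame"),
              min_distance = min_distance,
              enzymes = c(enzA$name, enzB$name))
  })
}

# Hamming distance over the shared prefix length of two barcodes.
prefix_hamming <- function(a, b) {
  L <- min(nchar(a), nchar(b))
  sum(strsplit(substr(a, 1, L), "")[[1]] != strsplit(substr(b, 1, L), "")[[1]])
}

#' Read / write a barcode file
#'
#' Plain TSV with columns `sample_id` and `barcode`.
#'
#' @param path file path.
#' @return A `barcode_set`.
#' @export
read_barcodes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  check_that(all(c("sample_id", "barcode") %in% names(df)),
             "barcode file needs sample_id and barcode columns")
  df$barcode <- toupper(df$barcode)
  check_that(!anyDuplicated(df$barcode), "barcodes must be unique")
  structure(df[c("sample_id", "barcode")],
            class = c("barcode_set", "data.frame"))
}

#' @rdname read_barcodes
#' @param barcodes a `barcode_set`.
#' @export
write_barcodes <- function(barcodes, path) {
  utils::write.table(as.data.frame(barcodes)[c("sample_id", "barcode")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Adapter molar ratio from predicted cut-end counts
#'
#' In ddGBS library preparation the barcode adapter ligates to enzyme-A
#' overhangs and the common adapter to enzyme-B overhangs, so the two
#' adapters are mixed in proportion to the predicted cut-end counts from
#' in silico digestion. Parts are scaled to sum to `total_parts` and
#' rounded half-up to one decimal place.
#'
#' @param enzA_cut_count,enzB_cut_count predicted cut(-end) counts, > 0.
#' @param total_parts total of the two parts after scaling.
#' @return An `adapter_ratio`: list with `barcode_adapter_parts` and
#'   `common_adapter_parts`.
#' @export
#' @examples
#' compute_adapter_ratio(1, 19, 20) # 1.0 : 19.0
compute_adapter_ratio <- function(enzA_cut_count, enzB_cut_count,
                                  total_parts = 15.8) {
  check_that(enzA_cut_count > 0 && enzB_cut_count > 0,
             "cut counts must be positive")
  check_that(total_parts > 0, "total_parts must be positive")
  tot <- enzA_cut_count + enzB_cut_count
  structure(list(
    barcode_adapter_parts = round_half_up(total_parts * enzA_cut_count / tot, 1),
    common_adapter_parts  = round_half_up(total_parts * enzB_cut_count / tot, 1)
  ), class = "adapter_ratio")
}

#' @export
print.adapter_ratio <- function(x, ...) {
  cat(sprintf("<adapter_ratio> barcode adapter : common adapter = %.1f : %.1f\n",
              x$barcode_adapter_parts, x$common_adapter_parts))
  invisible(x)
}

#' Read / write FASTQ
#'
#' Minimal single-end FASTQ support (4-line records; `.gz` handled
#' transparently). Reads return a data frame with `id`, `seq`, `qual`.
#'
#' @param path file path (`.gz` allowed).
#' @return `read_fastq`: data frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  check_that(length(lines) %% 4 == 0, "truncated FASTQ (lines not multiple of 4)")
  idx <- seq(1, length(lines), by = 4)
  data.frame(id = sub("^@", "", lines[idx]),
             seq = toupper(lines[idx + 1]),
             qual = lines[idx + 3],
             stringsAsFactors = FALSE)
}

#' @rdname read_fastq
#' @param reads data frame with `id`, `seq` and optionally `qual`
#'   (defaults to constant Q40).
#' @export
write_fastq <- function(reads, path) {
  qual <- reads$qual %||% strrep("I", nchar(reads$seq))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", qual), con)
  invisible(path)
}

#' Exact-match barcode demultiplexing
#'
#' Assigns each read to the sample whose barcode is a perfect prefix of
#' the read ("good barcode reads"); any mismatch leaves the read
#' unassigned. When one barcode is a prefix of another and both match,
#' the longest match wins. Assigned reads are returned barcode-trimmed
#' (the residual enzyme overhang is kept; see the package vignette).
#'
#' @param reads character vector of read sequences, or a data frame from
#'   [read_fastq()].
#' @param barcodes a `barcode_set` (or data frame with `sample_id`,
#'   `barcode`).
#' @return A `demux_result`: list with `reads` (named list of per-sample
#'   trimmed read data frames), `counts` (data frame `sample_id`,
#'   `barcode`, `good_barcode_reads`), `unassigned` count, and
#'   `assignment` (per-input-read sample or `NA`).
#' @export
demultiplex <- function(reads, barcodes) {
  if (is.character(reads))
    reads <- data.frame(id = paste0("read", seq_along(reads)), seq = reads,
                        qual = strrep("I", nchar(reads)),
                        stringsAsFactors = FALSE)
  bc <- as.data.frame(barcodes)
  check_that(!anyDuplicated(bc$barcode), "barcodes must be unique")
  assignment <- rep(NA_integer_, nrow(reads))
  # longest-match-first: try lengths in decreasing order
  for (L in sort(unique(nchar(bc$barcode)), decreasing = TRUE)) {
    open <- is.na(assignment)
    if (!any(open)) break
    sub <- which(nchar(bc$barcode) == L)
    hit <- match(substr(reads$seq[open], 1, L), bc$barcode[sub])
    assignment[open][!is.na(hit)] <- sub[hit[!is.na(hit)]]
  }
  per_sample <- lapply(seq_len(nrow(bc)), function(i) {
    sel <- which(assignment == i)
    L <- nchar(bc$barcode[i])
    data.frame(id = reads$id[sel],
               seq = substring(reads$seq[sel], L + 1L),
               qual = substring(reads$qual[sel] %||%
                                  strrep("I", nchar(reads$seq[sel])), L + 1L),
               stringsAsFactors = FALSE)
  })
  names(per_sample) <- bc$sample_id
  counts <- data.frame(sample_id = bc$sample_id, barcode = bc$barcode,
                       good_barcode_reads =
                         vapply(per_sample, nrow, 0L),
                       stringsAsFactors = FALSE, row.names = NULL)
  structure(list(reads = per_sample, counts = counts,
                 unassigned = sum(is.na(assignment)),
                 assignment = bc$sample_id[assignment]),
            class = "demux_result")
}

#' @export
print.demux_result <- function(x, ...) {
  total <- sum(x$counts$good_barcode_reads) + x$unassigned
  cat(sprintf("<demux_result> %d reads: %d good barcode reads over %d samples, %d unassigned\n",
              total, sum(x$counts$good_barcode_reads), nrow(x$counts),
              x$unassigned))
  invisible(x)
}

#' Write demultiplexed reads and the per-sample report
#'
#' Writes one FASTQ per sample into `dir` plus `demux_report.tsv`
#' (sample, barcode, good barcode reads).
#'
#' @param demux a `demux_result`.
#' @param dir output directory (created if needed).
#' @param gzip write gzipped FASTQ.
#' @export
write_demux <- function(demux, dir, gzip = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (gzip) ".fq.gz" else ".fq"
  for (s in names(demux$reads))
    write_fastq(demux$reads[[s]], file.path(dir, paste0(s, ext)))
  utils::write.table(demux$counts, file.path(dir, "demux_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
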