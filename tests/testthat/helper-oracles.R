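# Independent oracles and fixture builders used across the suite.

# quadratic position-by-position IUPAC motif scan, written independently
# of the package's vectorized scanner
naive_iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

naive_motif_starts <- function(sequence, motif) {
  s <- strsplit(toupper(sequence), "")[[1]]
  m <- strsplit(toupper(motif), "")[[1]]
  L <- length(m)
  starts <- integer(0)
  if (length(s) < L) return(starts)
  for (i in 1:(length(s) - L + 1)) {
    ok <- TRUE
    for (j in 1:L) {
      g <- s[i + j - 1]
      if (m[j] == "N") next
      if (!(g %in% naive_iupac_sets[[m[j]]])) { ok <- FALSE; break }
    }
    if (ok) starts <- c(starts, i)
  }
  starts
}

naive_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
                            toupper(x)), "")[[1]]), collapse = "")
}

# brute-force cut sites with the one-cut-per-duplex-site convention
naive_cut_sites <- function(sequence, motif, cut_offset) {
  n <- nchar(sequence)
  L <- nchar(motif)
  top <- naive_motif_starts(sequence, motif)
  bottom <- setdiff(naive_motif_starts(sequence, naive_revcomp(motif)), top)
  cuts <- sort(unique(c(top - 1 + cut_offset, bottom - 1 + (L - cut_offset))))
  cuts[cuts > 0 & cuts < n]
}

random_dna <- function(n, seed, gc = 0.5) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# a hand-constructible saturation curve for the ORP/SRP arithmetic tests
toy_curve <- function(reads, fragments, cost_per_read = 1) {
  structure(data.frame(proportion = reads / max(reads), reads = reads,
                       fragments = fragments, depth = reads / fragments,
                       unit_cost = cost_per_read * reads / fragments),
            class = c("saturation_curve", "data.frame"),
            c = 3, seed = NULL, cost_per_read = cost_per_read)
}

# small snp_matrix fixture builder
toy_snp_matrix <- function(geno, chrom = "chr1", pos = NULL, ref = "A",
                           alt = "G", depth = NULL, gq = NULL) {
  geno <- as.matrix(geno)
  n <- nrow(geno)
  snp_matrix(data.frame(chrom = rep_len(chrom, n),
                        pos = pos %||% (seq_len(n) * 100L),
                        ref = rep_len(ref, n), alt = rep_len(alt, n),
                        stringsAsFactors = FALSE),
             geno, depth, gq)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
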