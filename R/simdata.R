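# ddGBS read simulator: synthetic genome, double-digest library with
# controllable per-fragment abundance dispersion, planted SNPs with truth
# genotypes, and emulated chip data.

#' Simulation configuration
#'
#' Parameters of the ddGBS simulator. The defaults emulate a small
#' chicken-like double-digest screen: 42% GC, an EcoRI-MseI library
#' size-selected to 300-650 bp, three barcoded samples sequenced to a
#' mean per-fragment depth of 30x with 91 bp single-end reads, and one
#' planted biallelic SNP per ~3.7 kb of genome. Per-(fragment, sample)
#' library abundance is lognormal with scale `abundance_sigma`, whose
#' closed-form coefficient of variation `sqrt(exp(sigma^2) - 1)` is what
#' the per-fragment depth CV recovers at high depth; the default 0.4
#' reproduces the ~0.4 mean depth CV of a well-behaved combination.
#'
#' @param genome_length genome length in bp (>= 10 kb).
#' @param gc_fraction target GC content in \[0, 1\].
#' @param n_samples number of barcoded samples.
#' @param barcodes optional `barcode_set`; generated from the seed when
#'   `NULL`.
#' @param enzA,enzB library enzymes (names or objects).
#' @param size_window size-selection window in bp.
#' @param mean_depth mean reads per fragment per sample.
#' @param abundance_sigma lognormal scale of per-(fragment, sample)
#'   abundance; 0 gives uniform abundance.
#' @param read_length read length after barcode trimming (default 91 bp,
#'   a trimmed short-read single-end length).
#' @param base_error_rate per-base substitution error rate.
#' @param n_snps number of planted biallelic SNPs (placed inside the
#'   sequenced fragment ends so they are observable).
#' @param maf_range range of planted minor allele frequencies.
#' @param chip_error_rate independent per-call chip genotyping error.
#' @param seed RNG seed (mandatory): all outputs are deterministic given
#'   the config.
#' @return A `sim_config`.
#' @export
sim_config <- function(genome_length = 1e6, gc_fraction = 0.42,
                       n_samples = 3, barcodes = NULL,
                       enzA = "EcoRI", enzB = "MseI",
                       size_window = c(300, 650), mean_depth = 30,
                       abundance_sigma = 0.4, read_length = 91,
                       base_error_rate = 0.001, n_snps = NULL,
                       maf_range = c(0.1, 0.5), chip_error_rate = 0.005,
                       seed) {
  check_that(!missing(seed) && is.numeric(seed), "seed is mandatory")
  check_that(genome_length >= 1e4, "genome_length must be >= 10 kb")
  for (r in c(gc_fraction, base_error_rate, chip_error_rate))
    check_that(r >= 0 && r <= 1, "rates must lie in [0, 1]")
  check_that(mean_depth > 0 && read_length > 0, "depth/read length positive")
  check_that(abundance_sigma >= 0, "abundance_sigma must be >= 0")
  structure(list(
    genome_length = as.integer(genome_length), gc_fraction = gc_fraction,
    n_samples = as.integer(n_samples), barcodes = barcodes,
    enzA = as_enzyme(enzA), enzB = as_enzyme(enzB),
    size_window = size_window, mean_depth = mean_depth,
    abundance_sigma = abundance_sigma, read_length = as.integer(read_length),
    base_error_rate = base_error_rate,
    n_snps = as.integer(n_snps %||% max(1, round(genome_length / 3700))),
    maf_range = maf_range, chip_error_rate = chip_error_rate,
    seed = as.integer(seed)), class = "sim_config")
}

#' Simulate a random genome
#'
#' Draws an i.i.d. genome at the configured GC content. For sequences of
#' 100 kb and more the realized GC fraction lies within about 1% of the
#' target.
#'
#' @param cfg a [sim_config()].
#' @return Named character vector with one sequence `chr1`.
#' @export
simulate_genome <- function(cfg) {
  p <- c(A = (1 - cfg$gc_fraction) / 2, C = cfg$gc_fraction / 2,
         G = cfg$gc_fraction / 2, T = (1 - cfg$gc_fraction) / 2)
  with_seed(cfg$seed, {
    bases <- sample(names(p), cfg$genome_length, replace = TRUE, prob = p)
    c(chr1 = paste(bases, collapse = ""))
  })
}

COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Simulate a ddGBS sequencing run
#'
#' Digests the genome with the configured enzyme pair, size-selects the
#' class-AB fragments, plants biallelic SNPs inside the sequenced
#' fragment ends, and emits per-sample barcoded single-end reads:
#' \itemize{
#'   \item reads come from the enzyme-A (barcoded) end of each fragment
#'     in one orientation, as in single-end GBS;
#'   \item per-(fragment, sample) read counts are Poisson around
#'     `mean_depth` scaled by a lognormal(0, `abundance_sigma`)
#'     abundance, normalized so the expected depth equals `mean_depth`;
#'   \item heterozygous samples emit either allele with probability 1/2
#'     per read; substitution errors are added at `base_error_rate`.
#' }
#' Everything is deterministic given the config (including its seed).
#'
#' @param genome named character vector (e.g. from [simulate_genome()]).
#' @param cfg a [sim_config()].
#' @return A `ddgbs_sim`: list with `reads` (per-sample data frames
#'   `id`, `seq`, `qual`), `truth` (planted SNP table, genotype matrix,
#'   per-read fragment labels, per-fragment depth matrix), `barcodes`,
#'   `index` (the [fragment_read_index()]), `genome`, `config`.
#' @export
simulate_reads <- function(genome, cfg) {
  genome <- as_genome(genome)
  dd <- double_digest(genome, cfg$enzA, cfg$enzB)
  sel <- suppressWarnings(
    size_select(dd, cfg$size_window[1], cfg$size_window[2], ab_only = TRUE))
  if (nrow(sel$fragments) == 0)
    stop("digestion produced no AB fragments in the size window; ",
         "use a larger genome or a wider window", call. = FALSE)
  index <- fragment_read_index(sel, genome, read_length = cfg$read_length)
  fr <- index$fragments
  nf <- nrow(fr)
  barcodes <- cfg$barcodes %||%
    generate_barcodes(cfg$n_samples, seed = cfg$seed + 1L,
                      enzA = cfg$enzA, enzB = cfg$enzB)
  check_that(nrow(barcodes) == cfg$n_samples,
             "barcode set size must equal n_samples")
  samples <- barcodes$sample_id

  with_seed(cfg$seed + 2L, {
    snps <- plant_snps(genome, index, cfg)
    geno <- matrix(stats::rbinom(nrow(snps) * cfg$n_samples, 2, snps$maf),
                   nrow = nrow(snps), ncol = cfg$n_samples,
                   dimnames = list(NULL, samples))
    sig <- cfg$abundance_sigma
    lam <- cfg$mean_depth *
      matrix(stats::rlnorm(nf * cfg$n_samples, 0, sig), nf) / exp(sig^2 / 2)
    counts <- matrix(stats::rpois(nf * cfg$n_samples, lam), nf,
                     dimnames = list(fr$fragment_id, samples))
    snps_by_frag <- split(seq_len(nrow(snps)),
                          factor(snps$fragment_id, levels = fr$fragment_id))
    reads <- vector("list", cfg$n_samples)
    names(reads) <- samples
    read_frags <- vector("list", cfg$n_samples)
    names(read_frags) <- samples
    for (s in seq_len(cfg$n_samples)) {
      fidx <- rep.int(seq_len(nf), counts[, s])
      seqs <- index$templates[fidx]
      # apply sample genotype at planted sites
      for (k in seq_len(nf)) {
        for (sn in snps_by_frag[[k]]) {
          g <- geno[sn, s]
          if (g == 0L) next
          rows <- which(fidx == k)
          if (g == 1L)
            rows <- rows[stats::runif(length(rows)) < 0.5]
          if (length(rows))
            substr(seqs[rows], snps$template_offset[sn],
                   snps$template_offset[sn]) <- snps$template_alt[sn]
        }
      }
      seqs <- add_substitution_errors(seqs, cfg$base_error_rate)
      reads[[s]] <- data.frame(
        id = sprintf("%s_r%06d", samples[s], seq_along(seqs)),
        seq = paste0(barcodes$barcode[s], seqs),
        qual = strrep("I", nchar(barcodes$barcode[s]) + nchar(seqs)),
        stringsAsFactors = FALSE)
      read_frags[[s]] <- fr$fragment_id[fidx]
    }
    truth <- list(snps = snps, genotypes = geno, read_fragments = read_frags,
                  fragment_depth = counts, abundance = lam)
    structure(list(reads = reads, truth = truth, barcodes = barcodes,
                   index = index, genome = genome, config = cfg),
              class = "ddgbs_sim")
  })
}

# choose n_snps distinct genomic positions inside sequenced templates,
# with their template coordinates and alleles
plant_snps <- function(genome, index, cfg) {
  fr <- index$fragments
  tl <- nchar(index$templates)
  pos_list <- lapply(seq_len(nrow(fr)), function(k) {
    if (fr$strand[k] == "+") seq.int(fr$start[k] + 1L, fr$start[k] + tl[k])
    else seq.int(fr$end[k] - tl[k] + 1L, fr$end[k])
  })
  cand <- data.frame(
    frag = rep.int(seq_len(nrow(fr)), lengths(pos_list)),
    pos = unlist(pos_list))
  n <- cfg$n_snps
  if (n > nrow(cand)) {
    warning("only ", nrow(cand), " sequenced positions available; ",
            "planting that many SNPs instead of ", n)
    n <- nrow(cand)
  }
  pick <- cand[sort(sample.int(nrow(cand), n)), ]
  k <- pick$frag
  chrom <- fr$seq_name[k]
  ref <- substring(genome[chrom], pick$pos, pick$pos)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                character(1), USE.NAMES = FALSE)
  offset <- ifelse(fr$strand[k] == "+",
                   pick$pos - fr$start[k],
                   fr$end[k] - pick$pos + 1L)
  data.frame(chrom = chrom, pos = pick$pos, ref = unname(ref), alt = alt,
             maf = stats::runif(n, cfg$maf_range[1], cfg$maf_range[2]),
             fragment_id = fr$fragment_id[k],
             template_offset = offset,
             template_alt = ifelse(fr$strand[k] == "+", alt, COMP[alt]),
             stringsAsFactors = FALSE, row.names = NULL)
}

add_substitution_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  n_err <- stats::rbinom(length(seqs), nchar(seqs), rate)
  for (i in which(n_err > 0)) {
    pos <- sample.int(nchar(seqs[i]), n_err[i])
    for (p in pos) {
      old <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
    }
  }
  seqs
}

#' @export
print.ddgbs_sim <- function(x, ...) {
  cat(sprintf("<ddgbs_sim> %s-%s library: %d fragments, %d samples, %d reads, %d planted SNPs\n",
              x$config$enzA$name, x$config$enzB$name,
              nrow(x$index$fragments), length(x$reads),
              sum(vapply(x$reads, nrow, 0L)), nrow(x$truth$snps)))
  invisible(x)
}

#' Truth-derived GBS genotype calls
#'
#' Returns the simulator's planted genotypes as a [snp_matrix()] with
#' per-call depth equal to the read count of the SNP's fragment in each
#' sample (every read of a fragment covers its planted sites) and a
#' constant genotype quality. This is the idealized error-free caller
#' used to close the loop between the simulator and the genotype QC
#' operations; a real variant caller is deliberately out of scope.
#'
#' @param sim a `ddgbs_sim`.
#' @param gq constant genotype quality to report (default 99).
#' @return A `snp_matrix`.
#' @export
sim_genotype_calls <- function(sim, gq = 99) {
  snps <- sim$truth$snps
  depth <- sim$truth$fragment_depth[snps$fragment_id, , drop = FALSE]
  geno <- sim$truth$genotypes
  geno[depth == 0] <- NA_integer_   # unsequenced fragments yield no call
  snp_matrix(snps[c("chrom", "pos", "ref", "alt")], geno, depth,
             matrix(gq, nrow(geno), ncol(geno)))
}

#' Simulate chip genotypes from the truth
#'
#' Copies the planted genotypes and flips each call, independently with
#' probability `error_rate`, to one of the two other genotype classes
#' (chosen uniformly). Emulates an independent array-based genotyping of
#' the same individuals.
#'
#' @param sim a `ddgbs_sim`.
#' @param error_rate per-call error rate; defaults to the config's
#'   `chip_error_rate`.
#' @param seed RNG seed; defaults to the config seed + 3.
#' @return A `snp_matrix` (genotypes only).
#' @export
simulate_chip <- function(sim, error_rate = NULL, seed = NULL) {
  error_rate <- error_rate %||% sim$config$chip_error_rate
  seed <- seed %||% (sim$config$seed + 3L)
  geno <- sim$truth$genotypes
  with_seed(seed, {
    err <- stats::runif(length(geno)) < error_rate
    if (any(err)) {
      shift <- sample(1:2, sum(err), replace = TRUE)
      geno[err] <- (geno[err] + shift) %% 3L
    }
    snp_matrix(sim$truth$snps[c("chrom", "pos", "ref", "alt")], geno)
  })
}

#' Inject heterozygote-to-homozygote call errors
#'
#' Flips heterozygous calls to a homozygote (either class, coin flip)
#' independently with probability `rate` -- the dominant GBS genotyping
#' error mode at low depth, where only one allele of a heterozygote is
#' sampled. Used to verify that chip concordance recovers a planted
#' error rate.
#'
#' @param x a `snp_matrix`.
#' @param rate per-heterozygous-call error probability.
#' @param seed RNG seed.
#' @return The perturbed `snp_matrix`, with attribute `n_injected`.
#' @export
inject_het_errors <- function(x, rate, seed = NULL) {
  with_seed(seed, {
    het <- which(!is.na(x$geno) & x$geno == 1L)
    flip <- het[stats::runif(length(het)) < rate]
    x$geno[flip] <- sample(c(0L, 2L), length(flip), replace = TRUE)
    attr(x, "n_injected") <- length(flip)
    x
  })
}

#' Write a simulated run to disk
#'
#' Writes the genome FASTA, one FASTQ per sample, the truth SNP table
#' (TSV), the truth genotypes as a GT-only VCF, the barcode file, and a
#' JSON manifest echoing the full configuration and all paths.
#'
#' @param sim a `ddgbs_sim`.
#' @param dir output directory (created if needed).
#' @param gzip gzip the FASTQ files.
#' @return The manifest path, invisibly.
#' @export
write_sim_run <- function(sim, dir, gzip = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(genome = file.path(dir, "genome.fa"),
                barcodes = file.path(dir, "barcodes.tsv"),
                truth_snps = file.path(dir, "truth_snps.tsv"),
                truth_vcf = file.path(dir, "truth.vcf"))
  write_genome_fasta(sim$genome, paths$genome)
  write_barcodes(sim$barcodes, paths$barcodes)
  utils::write.table(sim$truth$snps, paths$truth_snps, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_snp_vcf(snp_matrix(sim$truth$snps[c("chrom", "pos", "ref", "alt")],
                           sim$truth$genotypes), paths$truth_vcf)
  ext <- if (gzip) ".fq.gz" else ".fq"
  paths$fastq <- file.path(dir, paste0(names(sim$reads), ext))
  for (i in seq_along(sim$reads))
    write_fastq(sim$reads[[i]], paths$fastq[i])
  cfg <- unclass(sim$config)
  cfg$enzA <- unclass(cfg$enzA); cfg$enzB <- unclass(cfg$enzB)
  cfg$barcodes <- NULL
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(config = cfg, paths = paths), manifest,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
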