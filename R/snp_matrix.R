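# Sites x samples genotype container with per-call depth and quality.

#' Construct a SNP matrix
#'
#' Sites x samples genotype container used by the filtering, concordance,
#' missing-rate and LD operations. Genotypes are ALT-allele dosages:
#' 0 = homozygous REF, 1 = heterozygous, 2 = homozygous ALT, `NA` =
#' missing. Positions are 1-based (VCF convention); sites are stored
#' sorted by chromosome (order of first appearance) and position.
#'
#' @param sites data frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt` (comma-separated when multi-allelic).
#' @param geno integer matrix sites x samples of dosages (0/1/2/NA);
#'   column names are sample identifiers.
#' @param depth optional matrix of per-call read depths (same shape).
#' @param gq optional matrix of phred-scaled genotype qualities.
#' @return A `snp_matrix`.
#' @export
snp_matrix <- function(sites, geno, depth = NULL, gq = NULL) {
  check_that(all(c("chrom", "pos", "ref", "alt") %in% names(sites)),
             "sites needs chrom, pos, ref, alt columns")
  geno <- as.matrix(geno)
  check_that(nrow(sites) == nrow(geno), "sites/geno row mismatch")
  if (is.null(colnames(geno)))
    colnames(geno) <- paste0("sample", seq_len(ncol(geno)))
  for (m in list(depth, gq))
    if (!is.null(m))
      check_that(all(dim(m) == dim(geno)), "depth/gq shape mismatch")
  sites$ref <- toupper(sites$ref); sites$alt <- toupper(sites$alt)
  rownames(sites) <- rownames(geno) <- NULL
  if (!is.null(depth)) rownames(depth) <- NULL
  if (!is.null(gq)) rownames(gq) <- NULL
  o <- order(match(sites$chrom, unique(sites$chrom)), sites$pos)
  structure(list(sites = sites[o, , drop = FALSE],
                 geno = geno[o, , drop = FALSE],
                 depth = if (!is.null(depth)) as.matrix(depth)[o, , drop = FALSE],
                 gq = if (!is.null(gq)) as.matrix(gq)[o, , drop = FALSE],
                 samples = colnames(geno)),
            class = "snp_matrix")
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat(sprintf("<snp_matrix> %d sites x %d samples (%s depth, %s GQ); %.1f%% missing\n",
              nrow(x$sites), length(x$samples),
              if (is.null(x$depth)) "no" else "with",
              if (is.null(x$gq)) "no" else "with",
              100 * mean(is.na(x$geno))))
  invisible(x)
}

#' @export
dim.snp_matrix <- function(x) c(nrow(x$sites), length(x$samples))

# subset sites (i) and/or samples (j)
subset_snp_matrix <- function(x, i = NULL, j = NULL) {
  i <- i %||% seq_len(nrow(x$sites)); j <- j %||% seq_along(x$samples)
  snp_matrix(x$sites[i, , drop = FALSE], x$geno[i, j, drop = FALSE],
             if (!is.null(x$depth)) x$depth[i, j, drop = FALSE],
             if (!is.null(x$gq)) x$gq[i, j, drop = FALSE])
}

#' Read genotypes from VCF
#'
#' Loads a VCF (v4.x) with FORMAT fields GT and, when present, DP and GQ
#' into a [snp_matrix()]. Genotype strings other than biallelic
#' diploid calls (e.g. involving allele indices > 1) become missing;
#' multi-allelic sites keep their full ALT string so the biallelic
#' filter can act on them.
#'
#' @param path VCF path (bgzipped or plain).
#' @return A `snp_matrix`.
#' @export
read_snp_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- v@fix
  sites <- data.frame(chrom = fx[, "CHROM"], pos = as.integer(fx[, "POS"]),
                      ref = fx[, "REF"], alt = fx[, "ALT"],
                      stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  geno <- parse_gt(gt)
  fmt <- vcfR::vcf_field_names(v, tag = "FORMAT")$ID
  depth <- if ("DP" %in% fmt)
    vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  gq <- if ("GQ" %in% fmt)
    vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE)
  snp_matrix(sites, geno, depth, gq)
}

parse_gt <- function(gt) {
  map <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L, "0|1" = 1L,
           "1|0" = 1L, "1/1" = 2L, "1|1" = 2L)
  out <- matrix(map[gt], nrow = nrow(gt), dimnames = dimnames(gt))
  storage.mode(out) <- "integer"
  out
}

#' Read / write chip genotypes as a TSV matrix
#'
#' Chip format: columns `chrom`, `pos`, `ref`, `alt`, then one column
#' per sample with genotypes written as base pairs (`"AA"`, `"AG"`,
#' `"GG"`; `"--"`, `"NN"` or empty = missing). Allele pairs are
#' converted to ALT dosage against the site's ref/alt.
#'
#' @param path file path.
#' @return `read_chip_tsv`: a `snp_matrix` (genotypes only).
#' @export
read_chip_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  meta <- c("chrom", "pos", "ref", "alt")
  check_that(all(meta %in% names(df)), "chip TSV needs chrom,pos,ref,alt")
  samples <- setdiff(names(df), meta)
  sites <- data.frame(chrom = df$chrom, pos = as.integer(df$pos),
                      ref = toupper(df$ref), alt = toupper(df$alt),
                      stringsAsFactors = FALSE)
  geno <- vapply(samples, function(s) {
    pair <- toupper(df[[s]])
    a1 <- substr(pair, 1, 1); a2 <- substr(pair, 2, 2)
    ok <- a1 %in% c("A", "C", "G", "T") & a2 %in% c("A", "C", "G", "T")
    d <- (a1 == sites$alt) + (a2 == sites$alt)
    # pairs containing an allele that is neither ref nor alt are missing
    valid <- ok & (a1 == sites$ref | a1 == sites$alt) &
      (a2 == sites$ref | a2 == sites$alt)
    ifelse(valid, d, NA_integer_)
  }, integer(nrow(df)))
  snp_matrix(sites, geno)
}

#' @rdname read_chip_tsv
#' @param x a `snp_matrix`.
#' @export
write_chip_tsv <- function(x, path) {
  s <- x$sites
  pair <- function(d, ref, alt)
    ifelse(is.na(d), "--",
           ifelse(d == 0, paste0(ref, ref),
                  ifelse(d == 1, paste0(ref, alt), paste0(alt, alt))))
  out <- data.frame(chrom = s$chrom, pos = s$pos, ref = s$ref, alt = s$alt,
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (j in seq_along(x$samples))
    out[[x$samples[j]]] <- pair(x$geno[, j], s$ref, s$alt)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write truth genotypes as a minimal GT-only VCF
#'
#' @param x a `snp_matrix`.
#' @param path output path (plain text).
#' @export
write_snp_vcf <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", x$samples), collapse = "\t")), con)
  gt <- matrix(c("0/0", "0/1", "1/1")[x$geno + 1L], nrow = nrow(x$geno))
  gt[is.na(x$geno)] <- "./."
  s <- x$sites
  lines <- paste(s$chrom, s$pos, ".", s$ref, s$alt, ".", "PASS", ".", "GT",
                 apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}
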