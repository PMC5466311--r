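# SNP filtering, chip concordance, missing rates, LD decay.

#' SNP filter configuration
#'
#' Thresholds of the standard GBS post-calling filter: genotype-level
#' depth and quality masks followed by site-level biallelic, minor
#' allele frequency and call-rate filters and a sample call-rate filter.
#'
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param gq_min minimum phred-scaled genotype quality (default 98).
#' @param dp_min minimum per-call read depth (default 5).
#' @param biallelic_only retain only biallelic sites (default `TRUE`).
#' @param site_call_rate_min minimum fraction of non-missing calls per
#'   site (default 0.6).
#' @param sample_call_rate_min minimum fraction of non-missing calls per
#'   sample (default 0.01).
#' @return A `filter_config`.
#' @export
filter_config <- function(maf_min = 0.05, gq_min = 98, dp_min = 5,
                          biallelic_only = TRUE, site_call_rate_min = 0.6,
                          sample_call_rate_min = 0.01) {
  check_that(maf_min >= 0 && maf_min <= 0.5, "maf_min must be in [0, 0.5]")
  check_that(gq_min >= 0 && dp_min >= 0, "gq_min/dp_min must be >= 0")
  check_that(site_call_rate_min >= 0 && site_call_rate_min <= 1 &&
               sample_call_rate_min >= 0 && sample_call_rate_min <= 1,
             "call rates must be in [0, 1]")
  structure(list(maf_min = maf_min, gq_min = gq_min, dp_min = dp_min,
                 biallelic_only = biallelic_only,
                 site_call_rate_min = site_call_rate_min,
                 sample_call_rate_min = sample_call_rate_min),
            class = "filter_config")
}

#' Filter a SNP matrix
#'
#' Applies the filter in a fixed, documented order:
#' \enumerate{
#'   \item genotype-level mask: calls with depth below `dp_min` or
#'     quality below `gq_min` become missing (only when the matrix
#'     carries the corresponding field);
#'   \item biallelic filter: sites with more than one ALT allele are
#'     removed (when `biallelic_only`);
#'   \item MAF filter: allele frequency from the non-missing calls after
#'     masking; sites with minor allele frequency below `maf_min` are
#'     removed;
#'   \item site call-rate filter: sites with fewer than
#'     `site_call_rate_min` non-missing calls are removed;
#'   \item sample call-rate filter: samples with fewer than
#'     `sample_call_rate_min` non-missing calls over the surviving sites
#'     are removed.
#' }
#' The operation is idempotent. An empty result is valid.
#'
#' @param x a `snp_matrix`.
#' @param cfg a [filter_config()].
#' @return The filtered `snp_matrix`, with attribute `filter_summary`
#'   (sites/samples/calls removed at each step).
#' @export
filter_snps <- function(x, cfg = filter_config()) {
  check_that(inherits(x, "snp_matrix"), "x must be a snp_matrix")
  geno <- x$geno
  masked <- 0L
  if (!is.null(x$depth)) {
    drop <- !is.na(geno) & (is.na(x$depth) | x$depth < cfg$dp_min)
    geno[drop] <- NA_integer_; masked <- masked + sum(drop)
  }
  if (!is.null(x$gq)) {
    drop <- !is.na(geno) & (is.na(x$gq) | x$gq < cfg$gq_min)
    geno[drop] <- NA_integer_; masked <- masked + sum(drop)
  }
  n_sites0 <- nrow(x$sites)
  keep <- rep(TRUE, n_sites0)
  if (cfg$biallelic_only)
    keep <- keep & !grepl(",", x$sites$alt, fixed = TRUE) &
      nzchar(x$sites$alt) & x$sites$alt != "."
  n_bi <- sum(!keep)
  called <- rowSums(!is.na(geno))
  p_alt <- rowSums(geno, na.rm = TRUE) / (2 * pmax(called, 1L))
  maf <- pmin(p_alt, 1 - p_alt)
  drop_maf <- keep & (called == 0 | maf < cfg$maf_min)
  keep <- keep & !drop_maf
  drop_cr <- keep & (called / ncol(geno) < cfg$site_call_rate_min)
  keep <- keep & !drop_cr
  geno2 <- geno[keep, , drop = FALSE]
  samp_cr <- colSums(!is.na(geno2)) / pmax(nrow(geno2), 1L)
  keep_s <- if (nrow(geno2) > 0) samp_cr >= cfg$sample_call_rate_min
            else rep(TRUE, ncol(geno2))
  out <- snp_matrix(x$sites[keep, , drop = FALSE],
                    geno2[, keep_s, drop = FALSE],
                    if (!is.null(x$depth)) x$depth[keep, keep_s, drop = FALSE],
                    if (!is.null(x$gq)) x$gq[keep, keep_s, drop = FALSE])
  attr(out, "filter_summary") <- c(
    calls_masked = masked, sites_multiallelic = n_bi,
    sites_low_maf = sum(drop_maf), sites_low_call_rate = sum(drop_cr),
    samples_removed = sum(!keep_s),
    sites_in = n_sites0, sites_out = nrow(out$sites))
  out
}

#' Depth-stratified chip concordance
#'
#' Compares GBS genotype calls against chip genotypes at shared sites
#' and samples, stratified by a minimum GBS call depth. At each depth
#' threshold `d` only GBS calls with depth >= `d` (and non-missing calls
#' on both platforms) are compared. Consistency is reported separately
#' over chip-homozygous and chip-heterozygous calls, plus the
#' call-weighted total.
#'
#' Sites are matched on (chrom, position). Allele orientation is
#' harmonized: sites where chip REF/ALT are swapped relative to GBS have
#' their chip dosages flipped; strand-ambiguous A/T and C/G sites, where
#' a swap cannot be told from a strand flip, are dropped and counted, as
#' are sites whose alleles do not match at all.
#'
#' @param gbs a `snp_matrix` with a depth matrix.
#' @param chip a `snp_matrix` (genotypes only is fine).
#' @param depth_thresholds integer depths to stratify by (default 2:12).
#' @return A `concordance_report` data frame (`depth`, `n_compared`,
#'   `homo_pct`, `het_pct`, `total_pct`) with site-matching counts in
#'   attributes.
#' @export
concordance <- function(gbs, chip, depth_thresholds = 2:12) {
  check_that(!is.null(gbs$depth), "gbs matrix must carry per-call depths")
  key_g <- paste(gbs$sites$chrom, gbs$sites$pos)
  key_c <- paste(chip$sites$chrom, chip$sites$pos)
  hit <- match(key_g, key_c)
  ig <- which(!is.na(hit)); ic <- hit[ig]
  check_that(length(ig) > 0, "no overlapping sites between gbs and chip")
  samples <- intersect(gbs$samples, chip$samples)
  check_that(length(samples) > 0, "no shared samples between gbs and chip")

  rg <- gbs$sites$ref[ig]; ag <- gbs$sites$alt[ig]
  rc <- chip$sites$ref[ic]; ac <- chip$sites$alt[ic]
  pair <- function(a, b) paste(pmin(a, b), pmax(a, b))
  ambiguous <- pair(rg, ag) %in% c("A T", "C G")
  same <- rg == rc & ag == ac
  swapped <- rg == ac & ag == rc & !same
  usable <- !ambiguous & (same | swapped)

  ig2 <- ig[usable]; ic2 <- ic[usable]
  jg <- match(samples, gbs$samples); jc <- match(samples, chip$samples)
  G <- gbs$geno[ig2, jg, drop = FALSE]
  D <- gbs$depth[ig2, jg, drop = FALSE]
  C <- chip$geno[ic2, jc, drop = FALSE]
  flip <- swapped[usable]
  C[flip, ] <- 2L - C[flip, , drop = FALSE]

  rows <- lapply(depth_thresholds, function(d) {
    ok <- !is.na(G) & !is.na(C) & !is.na(D) & D >= d
    hom <- ok & (C == 0L | C == 2L)
    het <- ok & C == 1L
    pct <- function(mask) if (any(mask)) 100 * sum(G[mask] == C[mask]) / sum(mask)
                          else NA_real_
    data.frame(depth = d, n_compared = sum(ok),
               homo_pct = pct(hom), het_pct = pct(het), total_pct = pct(ok))
  })
  structure(do.call(rbind, rows),
            class = c("concordance_report", "data.frame"),
            n_sites_matched = length(ig),
            n_sites_ambiguous = sum(ambiguous),
            n_sites_allele_mismatch = sum(!ambiguous & !(same | swapped)),
            n_sites_compared = length(ig2),
            samples = samples)
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("<concordance_report> %d sites compared (%d ambiguous, %d allele-mismatch dropped), %d samples\n",
              attr(x, "n_sites_compared"), attr(x, "n_sites_ambiguous"),
              attr(x, "n_sites_allele_mismatch"), length(attr(x, "samples"))))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Per-site and per-sample missing rates
#'
#' Missing fractions per site (over samples) and per sample (over
#' sites), before and after depth masking: the "after" variant first
#' sets calls with depth below `dp_min` to missing, mirroring the depth
#' filter applied before genotype use.
#'
#' @param x a `snp_matrix`.
#' @param dp_min depth threshold for the masked variant (default 5).
#'   Ignored (after = before) when the matrix has no depth field.
#' @return A `missing_report`: list with `per_site` and `per_sample`
#'   data frames (`missing_before`, `missing_after`) and overall totals.
#' @export
missing_rates <- function(x, dp_min = 5) {
  before <- is.na(x$geno)
  after <- before
  if (!is.null(x$depth) && dp_min > 0)
    after <- before | is.na(x$depth) | x$depth < dp_min
  structure(list(
    per_site = data.frame(chrom = x$sites$chrom, pos = x$sites$pos,
                          missing_before = rowMeans(before),
                          missing_after = rowMeans(after)),
    per_sample = data.frame(sample = x$samples,
                            missing_before = colMeans(before),
                            missing_after = colMeans(after),
                            row.names = NULL),
    total_before = mean(before), total_after = mean(after),
    dp_min = dp_min), class = "missing_report")
}

#' @export
print.missing_report <- function(x, ...) {
  cat(sprintf("<missing_report> overall missing %.1f%% before, %.1f%% after depth < %g masking\n",
              100 * x$total_before, 100 * x$total_after, x$dp_min))
  invisible(x)
}

#' Linkage-disequilibrium decay
#'
#' Computes pairwise r-squared -- the squared Pearson correlation of
#' ALT-allele dosage vectors over samples with both calls present -- for
#' all same-chromosome site pairs within `max_distance`, bins the pairs
#' by distance and reports bin means. The decay distance is the smallest
#' bin center whose mean r-squared drops to `threshold` or below.
#' Pairs involving a monomorphic dosage vector are excluded and counted.
#'
#' @param x a `snp_matrix`.
#' @param max_distance largest pair distance in bp (default 100 kb).
#' @param bins number of equal-width distance bins.
#' @param threshold r-squared level defining the decay distance
#'   (default 0.1).
#' @return An `ld_decay` data frame (`bin_center`, `mean_r2`, `n_pairs`)
#'   with attributes `decay_distance`, `n_monomorphic_pairs`.
#' @export
ld_decay <- function(x, max_distance = 1e5, bins = 20, threshold = 0.1) {
  dist_all <- numeric(0); r2_all <- numeric(0); mono <- 0L
  for (ch in unique(x$sites$chrom)) {
    sel <- which(x$sites$chrom == ch)
    if (length(sel) < 2) next
    pos <- x$sites$pos[sel]
    G <- x$geno[sel, , drop = FALSE]
    n <- length(sel)
    for (i in seq_len(n - 1)) {
      jmax <- findInterval(pos[i] + max_distance, pos)
      if (jmax <= i) next
      for (j in (i + 1):jmax) {
        both <- !is.na(G[i, ]) & !is.na(G[j, ])
        if (sum(both) < 2) next
        a <- G[i, both]; b <- G[j, both]
        if (stats::sd(a) == 0 || stats::sd(b) == 0) { mono <- mono + 1L; next }
        dist_all <- c(dist_all, pos[j] - pos[i])
        r2_all <- c(r2_all, stats::cor(a, b)^2)
      }
    }
  }
  check_that(length(r2_all) > 0, "no polymorphic site pairs within max_distance")
  edges <- seq(0, max_distance, length.out = bins + 1)
  bin <- cut(dist_all, edges, include.lowest = TRUE, labels = FALSE)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  mean_r2 <- tapply(r2_all, factor(bin, levels = seq_len(bins)), mean)
  n_pairs <- tapply(r2_all, factor(bin, levels = seq_len(bins)), length)
  out <- data.frame(bin_center = centers,
                    mean_r2 = as.numeric(mean_r2),
                    n_pairs = ifelse(is.na(n_pairs), 0L, as.integer(n_pairs)))
  below <- which(!is.na(out$mean_r2) & out$mean_r2 <= threshold)
  structure(out, class = c("ld_decay", "data.frame"),
            decay_distance = if (length(below)) out$bin_center[min(below)]
                             else NA_real_,
            threshold = threshold, n_monomorphic_pairs = mono)
}

#' @export
print.ld_decay <- function(x, ...) {
  dd <- attr(x, "decay_distance")
  cat(sprintf("<ld_decay> %d bins; r2 <= %.2f first reached at %s bp\n",
              nrow(x), attr(x, "threshold"),
              if (is.na(dd)) "no bin (not reached)" else format(dd)))
  invisible(x)
}

#' @export
plot.ld_decay <- function(x, ...) {
  graphics::plot(x$bin_center, x$mean_r2, type = "b", pch = 19,
                 xlab = "distance (bp)", ylab = expression(mean ~ r^2), ...)
  graphics::abline(h = attr(x, "threshold"), lty = 2)
  invisible(x)
}
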