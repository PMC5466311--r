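# Enzyme-combination evaluation statistics.

#' Fragment consistency index (FCI)
#'
#' The FCI of an enzyme combination is the mean per-sample fragment count
#' divided by the fragment count of the pooled (multi-sample) library. It
#' measures how well the set of sequenced loci overlaps across samples:
#' values near 1 mean the same fragments are recovered in every
#' individual, values well below 1 forecast missing data in a population.
#'
#' @param per_sample_fragment_counts fragment counts of the individual
#'   samples (typically three).
#' @param pooled_fragment_count fragment count of the pooled library. A
#'   pooled count smaller than the largest per-sample count is suspicious
#'   and raises a warning.
#' @param digits decimals for half-up report rounding (default 4);
#'   `NULL` returns full precision.
#' @return The FCI, in (0, 1] for nested fragment sets.
#' @export
#' @examples
#' compute_fci(c(351880, 378023, 385716), 414294) # 0.8976
compute_fci <- function(per_sample_fragment_counts, pooled_fragment_count,
                        digits = 4) {
  check_that(length(per_sample_fragment_counts) >= 1 &&
               all(per_sample_fragment_counts > 0),
             "per-sample fragment counts must be positive")
  check_that(length(pooled_fragment_count) == 1 && pooled_fragment_count > 0,
             "pooled fragment count must be a single positive number")
  if (pooled_fragment_count < max(per_sample_fragment_counts))
    warning("pooled fragment count is smaller than a per-sample count")
  fci <- mean(per_sample_fragment_counts) / pooled_fragment_count
  if (is.null(digits)) fci else round_half_up(fci, digits)
}

#' Sequencing depth per fragment
#'
#' Depth is the total good-barcode read count divided by the fragment
#' count: the average number of reads supporting each sequenced locus.
#'
#' @param good_barcode_reads total good barcode reads.
#' @param fragment_count number of fragments (> 0).
#' @param digits decimals for half-up report rounding (default 2);
#'   `NULL` returns the exact quotient.
#' @return Reads per fragment.
#' @export
#' @examples
#' compute_depth(31092630, 974736) # 31.90
compute_depth <- function(good_barcode_reads, fragment_count, digits = 2) {
  check_that(fragment_count > 0, "fragment_count must be > 0")
  check_that(good_barcode_reads >= 0, "good_barcode_reads must be >= 0")
  d <- good_barcode_reads / fragment_count
  if (is.null(digits)) d else round_half_up(d, digits)
}

#' Coefficient of variation
#'
#' Sample standard deviation (n-1 denominator) divided by the mean.
#' Scale-invariant; requires at least two values and a nonzero mean.
#'
#' @param values numeric vector, `n >= 2`.
#' @return SD/mean.
#' @export
cv <- function(values) {
  check_that(length(values) >= 2, "cv needs at least two values")
  m <- mean(values)
  check_that(m != 0, "cv undefined for zero mean")
  stats::sd(values) / m
}

#' Per-fragment depth CV across samples
#'
#' For each fragment (row) of a depth matrix, the coefficient of
#' variation of its sequencing depth across samples (columns). Fragments
#' with zero depth in every sample are excluded and counted. Uneven
#' per-fragment amplification shows up as a heavy right tail of this
#' distribution; combinations with low mean CV genotype more
#' consistently across individuals.
#'
#' @param per_fragment_depths numeric matrix, fragments x samples
#'   (>= 2 samples).
#' @return A `cv_depth` object: list with `cv` (one value per retained
#'   fragment), `mean_cv`, `sd_cv`, `n_fragments`, `n_excluded`.
#' @export
cv_depth_distribution <- function(per_fragment_depths) {
  m <- as.matrix(per_fragment_depths)
  check_that(ncol(m) >= 2, "need at least two samples (columns)")
  all_zero <- rowSums(m != 0) == 0
  m <- m[!all_zero, , drop = FALSE]
  cvs <- apply(m, 1, function(v) stats::sd(v) / mean(v))
  structure(list(cv = cvs,
                 mean_cv = mean(cvs),
                 sd_cv = if (length(cvs) >= 2) stats::sd(cvs) else NA_real_,
                 n_fragments = length(cvs),
                 n_excluded = sum(all_zero)),
            class = "cv_depth")
}

#' @export
print.cv_depth <- function(x, ...) {
  cat(sprintf("<cv_depth> %d fragments (%d all-zero excluded): mean CV %.2f +/- %.2f (SD)\n",
              x$n_fragments, x$n_excluded, x$mean_cv, x$sd_cv))
  invisible(x)
}

#' Per-chromosome SNP density table
#'
#' SNP density is the SNP count divided by chromosome length, reported as
#' SNPs per Mb. In table-comparison mode (`use_rounded = TRUE`, the
#' default) densities are rounded half-up to integers before the mean and
#' CV across chromosomes are taken, matching how such tables are printed;
#' full-precision densities are always retained in the `density_full`
#' column, and `use_rounded = FALSE` computes the summary from them.
#' A low density CV means markers are spread evenly across chromosomes.
#'
#' @param snp_counts named vector of per-chromosome SNP counts.
#' @param chrom_lengths named vector of chromosome lengths in bp
#'   (names matching `snp_counts`).
#' @param use_rounded compute mean/CV from integer-rounded densities.
#' @return A `density_table` data frame (`chrom`, `length_bp`,
#'   `snp_count`, `density`, `density_full`) with attributes
#'   `mean_density` and `cv_density`.
#' @export
snp_density_table <- function(snp_counts, chrom_lengths, use_rounded = TRUE) {
  check_that(all(chrom_lengths > 0), "chromosome lengths must be positive")
  if (!is.null(names(snp_counts)) && !is.null(names(chrom_lengths))) {
    miss <- setdiff(names(snp_counts), names(chrom_lengths))
    check_that(length(miss) == 0,
               paste("chromosome(s) with SNPs but no length:",
                     paste(miss, collapse = ", ")))
    chrom_lengths <- chrom_lengths[names(snp_counts)]
  } else {
    check_that(length(snp_counts) == length(chrom_lengths),
               "counts and lengths must align")
  }
  dens_full <- snp_counts / (chrom_lengths / 1e6)
  dens <- round_half_up(dens_full, 0)
  used <- if (use_rounded) dens else dens_full
  out <- data.frame(chrom = names(snp_counts) %||%
                      paste0("chr", seq_along(snp_counts)),
                    length_bp = unname(chrom_lengths),
                    snp_count = unname(snp_counts),
                    density = unname(dens),
                    density_full = unname(dens_full),
                    stringsAsFactors = FALSE)
  structure(out, class = c("density_table", "data.frame"),
            mean_density = mean(used),
            cv_density = if (length(used) >= 2) cv(used) else NA_real_,
            use_rounded = use_rounded)
}

#' @export
print.density_table <- function(x, ...) {
  cat(sprintf("<density_table> %d chromosomes: mean density %.1f SNPs/Mb, CV %.2f%s\n",
              nrow(x), attr(x, "mean_density"), attr(x, "cv_density"),
              if (attr(x, "use_rounded")) " (from rounded densities)" else ""))
  print.data.frame(x, ...)
  invisible(x)
}

#' Summarize SNP counts by genomic region
#'
#' Turns annotation category counts (upstream, exonic, intronic,
#' intergenic, ...) into percentages of the total, and exonic
#' subcategory counts (missense / nonsense / silent) into percentages of
#' the exonic count. Category percents are reported at 3 decimals and
#' subcategory percents at 2, half-up.
#'
#' @param category_counts named vector of SNP counts per region category.
#' @param exonic_subcounts optional named vector of exonic subcategory
#'   counts; must sum to at most the exonic category count.
#' @param exonic_category name of the exonic category in
#'   `category_counts`.
#' @return A `region_summary`: list with `categories` and `exonic`
#'   data frames (`count`, `percent`) and `total`.
#' @export
summarize_regions <- function(category_counts, exonic_subcounts = NULL,
                              exonic_category = "EXONIC") {
  check_that(all(category_counts >= 0), "counts must be >= 0")
  total <- sum(category_counts)
  check_that(total > 0, "no SNPs to summarize")
  cats <- data.frame(category = names(category_counts),
                     count = unname(category_counts),
                     percent = round_half_up(100 * unname(category_counts) /
                                               total, 3),
                     stringsAsFactors = FALSE)
  exonic <- NULL
  if (!is.null(exonic_subcounts)) {
    check_that(exonic_category %in% names(category_counts),
               paste("no", exonic_category, "category in category_counts"))
    exn <- category_counts[[exonic_category]]
    check_that(sum(exonic_subcounts) <= exn,
               "exonic subcounts exceed the exonic category count")
    exonic <- data.frame(category = names(exonic_subcounts),
                         count = unname(exonic_subcounts),
                         percent = round_half_up(100 * unname(exonic_subcounts) /
                                                   exn, 2),
                         stringsAsFactors = FALSE)
  }
  structure(list(categories = cats, exonic = exonic, total = total),
            class = "region_summary")
}

#' @export
print.region_summary <- function(x, ...) {
  cat(sprintf("<region_summary> %d SNPs\n", x$total))
  print(x$categories, row.names = FALSE)
  if (!is.null(x$exonic)) {
    cat("exonic subcategories (% of exonic):\n")
    print(x$exonic, row.names = FALSE)
  }
  invisible(x)
}
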