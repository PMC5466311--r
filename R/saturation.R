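# Read-subsampling saturation curves and sequencing-volume optimization.

#' Build a saturation curve by nested read subsampling
#'
#' Subsamples the reads of a tag table at increasing proportions,
#' counting at each point the number of fragments discovered. Subsamples
#' are nested (the p% set is a subset of the q% set for p < q) and drawn
#' without replacement, which guarantees the fragment count is
#' non-decreasing along the curve. A fragment is counted at a point when
#' at least one of its tags occurs at least `c` times in the subsample
#' (the minimum-tag-count threshold used by GBS pipelines, default 3).
#'
#' Each point also carries the sequencing depth (reads/fragment) and the
#' unit sequencing cost (cost per discovered fragment,
#' `cost_per_read * reads / fragments`).
#'
#' @param tags a `tag_table` (multiple samples are pooled).
#' @param proportions ascending proportions in (0, 1], last must be 1.
#' @param c minimum tag count for a fragment to be reported (>= 1).
#' @param seed RNG seed; the curve is deterministic given the seed.
#' @param cost_per_read cost of one read in arbitrary units.
#' @return A `saturation_curve` data frame (`proportion`, `reads`,
#'   `fragments`, `depth`, `unit_cost`) with attributes `c`, `seed`,
#'   `cost_per_read`.
#' @export
build_saturation_curve <- function(tags, proportions = c(0.1, 0.2, 0.5, 0.8, 1),
                                   c = 3, seed = NULL, cost_per_read = 1) {
  check_that(all(proportions > 0 & proportions <= 1),
             "proportions must lie in (0, 1]")
  check_that(!is.unsorted(proportions, strictly = TRUE),
             "proportions must be strictly ascending")
  check_that(proportions[length(proportions)] == 1,
             "last proportion must be 1.0")
  check_that(c >= 1, "minimum tag count c must be >= 1")
  N <- sum(tags$count)
  # one permutation of all reads; prefixes give nested subsamples
  shuffled <- with_seed(seed, {
    idx <- rep.int(seq_len(nrow(tags)), tags$count)
    idx[sample.int(N)]
  })
  pts <- lapply(proportions, function(p) {
    m <- max(1L, round(p * N))
    cnt <- tabulate(shuffled[seq_len(m)], nbins = nrow(tags))
    frags <- length(unique(tags$fragment[cnt >= c]))
    data.frame(proportion = p, reads = m, fragments = frags,
               depth = if (frags > 0) m / frags else NA_real_,
               unit_cost = if (frags > 0) cost_per_read * m / frags
                           else NA_real_)
  })
  structure(do.call(rbind, pts),
            class = c("saturation_curve", "data.frame"),
            c = c, seed = seed, cost_per_read = cost_per_read)
}

#' Optimal read-count point (ORP)
#'
#' The ORP is the read volume minimizing the unit sequencing cost (cost
#' per discovered fragment) along a saturation curve. The minimum is
#' located on the observed points, without interpolation. A minimum on
#' the first or last point means the true optimum lies outside the
#' sampled range; it is flagged `boundary` and the boundary value is
#' still reported.
#'
#' @param curve a `saturation_curve` with at least 2 points.
#' @return An `orp_point`: list with `orp_reads`, `orp_fragments`,
#'   `orp_depth`, `orp_unit_cost`, `boundary`.
#' @export
find_orp <- function(curve) {
  check_that(nrow(curve) >= 2, "need at least 2 curve points")
  uc <- curve$unit_cost
  check_that(any(!is.na(uc)), "no point discovered any fragment")
  i <- which.min(uc)
  structure(list(orp_reads = curve$reads[i],
                 orp_fragments = curve$fragments[i],
                 orp_depth = curve$depth[i],
                 orp_unit_cost = uc[i],
                 boundary = i == 1L || i == nrow(curve)),
            class = "orp_point")
}

#' @export
print.orp_point <- function(x, ...) {
  cat(sprintf("<orp_point> ORP at %d reads (%.1fx depth, unit cost %.3f)%s\n",
              x$orp_reads, x$orp_depth, x$orp_unit_cost,
              if (x$boundary) " [boundary: optimum not bracketed]" else ""))
  invisible(x)
}

#' Saturated read-count point (SRP)
#'
#' The SRP is the smallest read volume at which fragment discovery has
#' plateaued: the forward finite-difference slope of the fragment-count
#' curve (new fragments per additional read) has dropped to `slope_tol`
#' or below and stays there. When that holds, the SRP is the smallest
#' read count whose fragment count equals the maximum observed; when the
#' slope never flattens the SRP is absent (`srp_reads = NA`), the common
#' outcome for libraries sequenced below saturation.
#'
#' @param curve a `saturation_curve` with at least 3 points.
#' @param slope_tol plateau tolerance, new fragments per additional read
#'   (default 1 per 1e5 reads).
#' @return An `srp_point`: list with `srp_reads` (or `NA`),
#'   `srp_fragments`, `reached`, `slope_tol`.
#' @export
find_srp <- function(curve, slope_tol = 1e-5) {
  check_that(nrow(curve) >= 3, "need at least 3 curve points")
  f <- curve$fragments; r <- curve$reads
  slopes <- diff(f) / diff(r)
  if (any(slopes < 0))
    stop("fragment counts decreased along the curve; ",
         "subsampling was not nested", call. = FALSE)
  flat_tail <- rev(cumprod(rev(slopes <= slope_tol))) == 1
  if (!any(flat_tail))
    return(structure(list(srp_reads = NA_real_, srp_fragments = NA_real_,
                          reached = FALSE, slope_tol = slope_tol),
                     class = "srp_point"))
  i <- min(which(f == max(f)))
  structure(list(srp_reads = r[i], srp_fragments = f[i], reached = TRUE,
                 slope_tol = slope_tol),
            class = "srp_point")
}

#' @export
print.srp_point <- function(x, ...) {
  if (x$reached)
    cat(sprintf("<srp_point> SRP at %s reads (%s fragments)\n",
                format(x$srp_reads, big.mark = ","),
                format(x$srp_fragments, big.mark = ",")))
  else cat("<srp_point> SRP not reached (fragment discovery still rising)\n")
  invisible(x)
}

#' ORP and SRP in one report
#'
#' @param curve a `saturation_curve`.
#' @param slope_tol passed to [find_srp()].
#' @return An `orp_srp` list combining [find_orp()] and [find_srp()]
#'   fields. When both points exist, `orp_reads <= srp_reads`.
#' @export
sequencing_volume <- function(curve, slope_tol = 1e-5) {
  structure(c(unclass(find_orp(curve)), unclass(find_srp(curve, slope_tol))),
            class = "orp_srp")
}

#' @export
print.orp_srp <- function(x, ...) {
  print(structure(x[c("orp_reads", "orp_fragments", "orp_depth",
                      "orp_unit_cost", "boundary")], class = "orp_point"))
  print(structure(x[c("srp_reads", "srp_fragments", "reached", "slope_tol")],
                  class = "srp_point"))
  invisible(x)
}

#' @export
plot.saturation_curve <- function(x, ...) {
  op <- graphics::par(mar = c(5, 4, 2, 4))
  on.exit(graphics::par(op))
  graphics::plot(x$reads, x$fragments, type = "b", pch = 19,
                 xlab = "good barcode reads", ylab = "fragments", ...)
  graphics::par(new = TRUE)
  graphics::plot(x$reads, x$unit_cost, type = "b", lty = 2, pch = 1,
                 axes = FALSE, xlab = "", ylab = "")
  graphics::axis(4)
  graphics::mtext("unit cost per fragment", side = 4, line = 2.5)
  invisible(x)
}

#' Write a saturation curve as TSV
#'
#' @param curve a `saturation_curve`.
#' @param path output path.
#' @export
write_saturation_curve <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# saturation curve; c=%d cost_per_read=%g seed=%s",
                     attr(curve, "c"), attr(curve, "cost_per_read"),
                     attr(curve, "seed") %||% "NULL"), con)
  utils::write.table(as.data.frame(curve), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
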