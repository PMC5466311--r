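#' Bundled example statistics
#'
#' Small plain-text tables shipped with the package, taken from a
#' published chicken ddGBS enzyme-combination screen, used in examples
#' and in the reproduction script:
#' \describe{
#'   \item{`"enzyme_screen"`}{per-combination good-barcode-read,
#'     fragment and tag counts for three individually sequenced samples
#'     and their 3-plex pool, for eight double-enzyme combinations --
#'     the inputs of [compute_fci()] and [compute_depth()];}
#'   \item{`"snp_density"`}{per-chromosome SNP counts and chromosome
#'     lengths for the EcoRI-MseI combination -- the input of
#'     [snp_density_table()];}
#'   \item{`"snp_regions"`}{SNP counts by annotation category, with
#'     exonic subcategories -- the input of [summarize_regions()].}
#' }
#'
#' @param which one of `"enzyme_screen"`, `"snp_density"`,
#'   `"snp_regions"`.
#' @return A data frame.
#' @export
#' @examples
#' scr <- ddgbs_example("enzyme_screen")
#' em <- scr[scr$combination == "EcoRI-MseI", ]
#' compute_fci(em$fragments[em$unit != "pool"],
#'             em$fragments[em$unit == "pool"])
ddgbs_example <- function(which = c("enzyme_screen", "snp_density",
                                    "snp_regions")) {
  which <- match.arg(which)
  f <- c(enzyme_screen = "chicken_enzyme_screen.tsv",
         snp_density = "chicken_snp_density_ecori_msei.tsv",
         snp_regions = "chicken_snp_regions.tsv")[[which]]
  path <- system.file("extdata", f, package = "ddgbs", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, na.strings = NULL)
}

#' @keywords internal
"_PACKAGE"
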