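#' Published per-genome summary of the MER6/MER6A MITE families
#'
#' Copy counts, genome coverage and mean copy-to-consensus Jukes-Cantor
#' divergence (in percent) reported for the full-length MER6 element in
#' six primate genomes and for its deletion derivative MER6A in eleven
#' boreoeutherian genomes. This table is the calibration input for the
#' family substitution rates: the unweighted mean divergence of each
#' family, anchored to the ~96 Myr Euarchontoglires-Laurasiatheria split,
#' gives the rate via `s = D / T`.
#'
#' @return data frame with columns `species`, `family`, `n_insertions`,
#'   `genome_coverage_pct`, `divergence_pct`.
#' @export
mer6_family_summary <- function() {
  utils::read.table(
    system.file("extdata", "mer6_family_summary.tsv", package = "mitewave",
                mustWork = TRUE),
    sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
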