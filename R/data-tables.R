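#' Published diversity summary for wild and laboratory zebrafish
#'
#' Curated per-population summary statistics for 13 wild zebrafish
#' populations (Nepal, India, Bangladesh) and three laboratory strains:
#' mitochondrial segregating sites (S), haplotype diversity (h),
#' nucleotide diversity (pi, percent) and mean unbiased expected SNP
#' heterozygosity (H_S). Entries not reported for a population are NA.
#' Used as reference input for the lab-vs-wild diversity comparison.
#'
#' @return `data.frame` with columns `population`, `type` (wild/lab),
#'   `S`, `h`, `pi_pct`, `hs_snp`.
#' @export
diversitySummaryTable <- function() {
  path <- system.file("extdata", "zebrafish_diversity_summary.tsv",
                      package = "zfpopgen")
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             na.strings = "NA")
}
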