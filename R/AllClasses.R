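#' @import methods
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<-
#'   assayNames colData colData<- rowRanges
#' @importFrom S4Vectors DataFrame mcols
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start
#' @importFrom stats coef lm median pexp ppois pnorm qnorm quantile rbinom
#'   rnorm runif rpois sd setNames var dpois p.adjust t.test complete.cases
#' @importFrom utils read.table write.table head tail
#' @importFrom Rcpp sourceCpp
#' @useDynLib zfpopgen, .registration = TRUE
NULL

#' Genotype dataset for biallelic SNPs with population structure
#'
#' `GenotypeDataset` extends [SummarizedExperiment::RangedSummarizedExperiment].
#' Rows are loci (a `GRanges` with locus ids, reference and alternate
#' alleles), columns are samples. The single assay `"GT"` holds genotypes
#' coded as the count of the alternate allele (0, 1, 2, or `NA` for
#' missing). Column data carries the sample-to-population map and an
#' optional population-to-group map (hierarchical structure used by the
#' AMOVA and the hierarchical outlier null).
#'
#' @slot .. see [SummarizedExperiment::RangedSummarizedExperiment].
#' @seealso [GenotypeDataset()] for construction from plain matrices,
#'   [readGenotypes()] for construction from a VCF + popmap.
#' @export
setClass("GenotypeDataset",
         contains = "RangedSummarizedExperiment")

.valid_GenotypeDataset <- function(object) {
  msg <- character()
  if (!"GT" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'GT' is required")
  else {
    gt <- SummarizedExperiment::assay(object, "GT")
    bad <- !(is.na(gt) | gt == 0L | gt == 1L | gt == 2L)
    if (any(bad))
      msg <- c(msg, "genotype codes must be 0, 1, 2 or NA")
  }
  cd <- SummarizedExperiment::colData(object)
  if (!"population" %in% colnames(cd))
    msg <- c(msg, "colData must contain a 'population' column")
  else if (any(is.na(cd$population)))
    msg <- c(msg, "every sample must have a population")
  rr <- SummarizedExperiment::rowRanges(object)
  if (length(rr)) {
    if (is.null(names(rr)) || anyDuplicated(names(rr)))
      msg <- c(msg, "locus ids must be present and unique")
    mc <- S4Vectors::mcols(rr)
    if (!all(c("ref", "alt") %in% colnames(mc)))
      msg <- c(msg, "rowRanges must carry 'ref' and 'alt' alleles")
    else if (any(as.character(mc$ref) == as.character(mc$alt)))
      msg <- c(msg, "ref and alt alleles must differ at every locus")
  }
  if (length(msg)) msg else TRUE
}
setValidity("GenotypeDataset", .valid_GenotypeDataset)

#' Construct a GenotypeDataset
#'
#' @param genotypes integer matrix, loci in rows and samples in columns,
#'   coded as alternate-allele counts (0/1/2, `NA` = missing). Row names
#'   are locus ids, column names sample ids.
#' @param loci `data.frame` with columns `locus_id`, `chrom`, `pos`
#'   (1-based basepairs), `ref`, `alt`, one row per genotype row.
#' @param populations named character vector mapping sample id to
#'   population name (names must cover all samples).
#' @param groups optional named character vector mapping population name
#'   to group name.
#' @return a [GenotypeDataset-class] object with loci ordered by
#'   (chrom, pos).
#' @examples
#' gt <- matrix(c(0L, 2L, 1L, 1L), nrow = 2,
#'              dimnames = list(c("L1", "L2"), c("S1", "S2")))
#' loci <- data.frame(locus_id = c("L1", "L2"), chrom = "chr1",
#'                    pos = c(100L, 200L), ref = "A", alt = "G")
#' ds <- GenotypeDataset(gt, loci, c(S1 = "popA", S2 = "popB"))
#' @export
GenotypeDataset <- function(genotypes, loci, populations, groups = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  stopifnot(nrow(genotypes) == nrow(loci))
  if (is.null(colnames(genotypes)))
    colnames(genotypes) <- paste0("S", seq_len(ncol(genotypes)))
  samples <- colnames(genotypes)
  missing_pop <- setdiff(samples, names(populations))
  if (length(missing_pop))
    stop("sample ", missing_pop[[1L]], " not in popmap")
  pop <- unname(populations[samples])
  grp <- if (is.null(groups)) rep(NA_character_, length(samples)) else
    unname(groups[pop])
  if (!is.null(groups) && anyNA(grp))
    stop("population ", pop[is.na(grp)][[1L]], " not in groupmap")
  if (any(loci$pos < 1L)) stop("positions must be >= 1")
  rr <- GenomicRanges::GRanges(
    seqnames = as.character(loci$chrom),
    ranges = IRanges::IRanges(start = as.integer(loci$pos), width = 1L),
    ref = as.character(loci$ref), alt = as.character(loci$alt))
  names(rr) <- as.character(loci$locus_id)
  rownames(genotypes) <- names(rr)
  ord <- order(as.character(GenomicRanges::seqnames(rr)),
               GenomicRanges::start(rr))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(GT = genotypes[ord, , drop = FALSE]),
    rowRanges = rr[ord],
    colData = S4Vectors::DataFrame(population = pop, group = grp,
                                   row.names = samples))
  new("GenotypeDataset", se)
}

#' Mitochondrial haplotype alignment with population labels
#'
#' Wraps a [Biostrings::DNAStringSet] of equal-length aligned sequences
#' (uppercase, alphabet `A C G T N -`) together with a sequence-to-
#' population map.
#'
#' @slot sequences a `DNAStringSet`, all of equal width.
#' @slot population character vector, one population label per sequence.
#' @export
setClass("HaplotypeAlignment",
         representation(sequences = "DNAStringSet",
                        population = "character"))

.valid_HaplotypeAlignment <- function(object) {
  msg <- character()
  w <- Biostrings::width(object@sequences)
  if (length(w) == 0L || w[[1L]] < 1L)
    msg <- c(msg, "alignment must contain at least one non-empty sequence")
  if (length(unique(w)) > 1L)
    msg <- c(msg, "all sequences must have equal length")
  if (length(object@population) != length(object@sequences))
    msg <- c(msg, "one population label per sequence is required")
  if (length(msg)) msg else TRUE
}
setValidity("HaplotypeAlignment", .valid_HaplotypeAlignment)

#' Construct a HaplotypeAlignment
#'
#' @param sequences a `DNAStringSet` or named character vector of aligned,
#'   equal-length sequences. Lowercase input is uppercased.
#' @param populations named character vector mapping sequence name to
#'   population.
#' @return a [HaplotypeAlignment-class].
#' @export
HaplotypeAlignment <- function(sequences, populations) {
  if (is.character(sequences))
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
  w <- Biostrings::width(sequences)
  if (length(unique(w)) > 1L) {
    expected <- as.integer(names(which.max(table(w))))
    off <- names(sequences)[which(w != expected)[[1L]]]
    stop("ragged alignment: record ", off, " has length ",
         w[w != expected][[1L]], ", expected ", expected)
  }
  nm <- names(sequences)
  if (is.null(nm)) stop("sequences must be named")
  missing_pop <- setdiff(nm, names(populations))
  if (length(missing_pop))
    stop("sequence ", missing_pop[[1L]], " not in popmap")
  new("HaplotypeAlignment", sequences = sequences,
      population = unname(populations[nm]))
}

#' Joint null distribution of heterozygosity and F_ST
#'
#' Holds (heterozygosity, F_ST) pairs from independent coalescent
#' simulations of the hierarchical island model, used as the FDIST-style
#' envelope against which observed loci are classified.
#'
#' @slot het total expected heterozygosity of each simulated locus.
#' @slot fst multi-deme Weir-Cockerham theta of each simulated locus.
#' @slot config the [fdistConfig()] list used for the simulations.
#' @export
setClass("NullTable",
         representation(het = "numeric", fst = "numeric", config = "list"))

setValidity("NullTable", function(object) {
  if (length(object@het) != length(object@fst))
    return("het and fst must have equal length")
  if (length(object@het) && (min(object@het) < 0 || max(object@het) > 1))
    return("heterozygosity must lie in [0, 1]")
  TRUE
})

#' Binned LD decay curve with logarithmic fit
#'
#' @slot bin_width bin width in basepairs.
#' @slot bin_mid_mb bin midpoints, megabases.
#' @slot mean_r2 mean r-squared per bin.
#' @slot n_pairs number of SNP pairs per bin.
#' @slot a,b coefficients of the least-squares fit
#'   `mean r2 = a * ln(distance in Mb) + b`.
#' @export
setClass("DecayFit",
         representation(bin_width = "numeric", bin_mid_mb = "numeric",
                        mean_r2 = "numeric", n_pairs = "integer",
                        a = "numeric", b = "numeric"))
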