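#' Accessors for GenotypeDataset and HaplotypeAlignment
#'
#' `genotypes()` returns the loci x samples integer matrix of
#' alternate-allele counts; `populations()` the sample-to-population map;
#' `populationGroups()` the population-to-group map (`NA`-free only when a
#' groupmap was supplied); `lociTable()` a `data.frame` of locus id,
#' chromosome, position and alleles; `alnSequences()` and
#' `alnPopulations()` the sequences and labels of an alignment.
#'
#' @param x a [GenotypeDataset-class] or [HaplotypeAlignment-class].
#' @return see description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname accessors
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @rdname accessors
#' @export
setGeneric("populationGroups",
           function(x) standardGeneric("populationGroups"))

#' @rdname accessors
#' @export
setGeneric("lociTable", function(x) standardGeneric("lociTable"))

#' @rdname accessors
#' @export
setGeneric("alnSequences", function(x) standardGeneric("alnSequences"))

#' @rdname accessors
#' @export
setGeneric("alnPopulations", function(x) standardGeneric("alnPopulations"))

#' @rdname accessors
setMethod("genotypes", "GenotypeDataset", function(x)
  SummarizedExperiment::assay(x, "GT"))

#' @rdname accessors
setMethod("populations", "GenotypeDataset", function(x)
  setNames(SummarizedExperiment::colData(x)$population, colnames(x)))

#' @rdname accessors
setMethod("populationGroups", "GenotypeDataset", function(x) {
  cd <- SummarizedExperiment::colData(x)
  dup <- !duplicated(cd$population)
  setNames(cd$group[dup], cd$population[dup])
})

#' @rdname accessors
setMethod("lociTable", "GenotypeDataset", function(x) {
  rr <- SummarizedExperiment::rowRanges(x)
  data.frame(locus_id = names(rr),
             chrom = as.character(GenomicRanges::seqnames(rr)),
             pos = GenomicRanges::start(rr),
             ref = S4Vectors::mcols(rr)$ref,
             alt = S4Vectors::mcols(rr)$alt,
             row.names = NULL, stringsAsFactors = FALSE)
})

#' @rdname accessors
setMethod("alnSequences", "HaplotypeAlignment", function(x) x@sequences)

#' @rdname accessors
setMethod("alnPopulations", "HaplotypeAlignment", function(x)
  setNames(x@population, names(x@sequences)))

setMethod("show", "GenotypeDataset", function(object) {
  cat("GenotypeDataset:", nrow(object), "loci x", ncol(object), "samples\n")
  pops <- table(populations(object))
  cat(" populations (", length(pops), "): ",
      paste0(names(pops), "(", pops, ")", collapse = " "), "\n", sep = "")
  grp <- populationGroups(object)
  if (!all(is.na(grp)))
    cat(" groups:", length(unique(grp[!is.na(grp)])), "\n")
  gt <- genotypes(object)
  cat(sprintf(" missing genotypes: %.2f%%\n", 100 * mean(is.na(gt))))
})

setMethod("show", "HaplotypeAlignment", function(object) {
  cat("HaplotypeAlignment:", length(object@sequences), "sequences x",
      Biostrings::width(object@sequences)[[1L]], "bp\n")
  pops <- table(object@population)
  cat(" populations (", length(pops), "): ",
      paste0(names(pops), "(", pops, ")", collapse = " "), "\n", sep = "")
})

setMethod("show", "NullTable", function(object) {
  cat("NullTable:", length(object@het), "simulated loci\n")
  if (length(object@fst))
    cat(sprintf(" mean F_ST %.3f; het range [%.3f, %.3f]\n",
                mean(object@fst), min(object@het), max(object@het)))
})

setMethod("show", "DecayFit", function(object) {
  cat("DecayFit:", length(object@bin_mid_mb), "bins of",
      object@bin_width / 1e6, "Mb\n")
  cat(sprintf(" mean r2 = %.4g * ln(Mb) + %.4g\n", object@a, object@b))
})

#' Number of simulated loci in a NullTable
#' @param x a [NullTable-class]
#' @export
setMethod("length", "NullTable", function(x) length(x@het))
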