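# Reading, writing and filtering of SNP genotype data.

.read_popmap <- function(path) {
  pm <- read.table(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(pm) < 2L) stop("popmap must have at least 2 tab-separated columns")
  out <- list(populations = setNames(as.character(pm[[2L]]),
                                     as.character(pm[[1L]])))
  if (ncol(pm) >= 3L)
    out$groups <- setNames(as.character(pm[[3L]]), as.character(pm[[2L]]))
  out
}

#' Read biallelic SNP genotypes from a VCF with a population map
#'
#' Parses a VCF (4.x, GT field) of biallelic SNPs together with a
#' two-column tab-separated popmap (`sample<TAB>population`) and an
#' optional two-column groupmap (`population<TAB>group`). Genotypes are
#' recoded as alternate-allele counts; loci are ordered by
#' (chromosome, position).
#'
#' @param vcf_path path to a VCF file (plain text or gzipped).
#' @param popmap_path path to the popmap TSV.
#' @param groupmap_path optional path to a population-to-group TSV.
#' @return a [GenotypeDataset-class].
#' @export
readGenotypes <- function(vcf_path, popmap_path, groupmap_path = NULL) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) # single-record VCFs drop to a named vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  bad <- grepl(",", alt) | nchar(ref) != 1L | nchar(alt) != 1L
  if (any(bad)) {
    id <- fix[bad, "ID"][[1L]]
    if (is.na(id) || id == ".")
      id <- paste0(fix[bad, "CHROM"][[1L]], ":", fix[bad, "POS"][[1L]])
    stop("multiallelic or non-SNP record: ", id)
  }
  gt_chr <- vcfR::extract.gt(vcf, element = "GT")
  code <- matrix(NA_integer_, nrow(gt_chr), ncol(gt_chr),
                 dimnames = dimnames(gt_chr))
  norm <- gsub("\\|", "/", gt_chr)
  code[norm %in% c("0/0")] <- 0L
  code[norm %in% c("0/1", "1/0")] <- 1L
  code[norm %in% c("1/1")] <- 2L
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":",
                                         fix[, "POS"])[is.na(ids) | ids == "."]
  if (anyDuplicated(ids)) stop("duplicate locus ids in VCF")
  loci <- data.frame(locus_id = ids, chrom = fix[, "CHROM"],
                     pos = as.integer(fix[, "POS"]), ref = ref, alt = alt,
                     stringsAsFactors = FALSE)
  pm <- .read_popmap(popmap_path)
  pops <- pm$populations
  missing <- setdiff(colnames(code), names(pops))
  if (length(missing)) stop("sample ", missing[[1L]], " not in popmap")
  groups <- if (!is.null(groupmap_path)) {
    gm <- read.table(groupmap_path, header = FALSE, sep = "\t",
                     stringsAsFactors = FALSE)
    setNames(as.character(gm[[2L]]), as.character(gm[[1L]]))
  } else pm$groups
  rownames(code) <- ids
  GenotypeDataset(code, loci, pops, groups)
}

#' Write a GenotypeDataset as a minimal VCF 4.2 plus popmap
#'
#' Emits a plain-text VCF with CHROM, POS, ID, REF, ALT and per-sample GT
#' fields (`./.` for missing), and a tab-separated popmap (with a third
#' group column when the dataset carries groups). The pair round-trips
#' through [readGenotypes()].
#'
#' @param ds a [GenotypeDataset-class].
#' @param vcf_path,popmap_path output paths.
#' @return invisibly, `ds`.
#' @export
writeGenotypes <- function(ds, vcf_path, popmap_path) {
  loci <- lociTable(ds)
  gt <- genotypes(ds)
  samples <- colnames(ds)
  header <- c("##fileformat=VCFv4.2",
              "##source=zfpopgen",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[gt + 1L], nrow(gt), ncol(gt))
  gt_str[is.na(gt_str)] <- "./."
  body <- if (nrow(loci)) {
    paste(loci$chrom, loci$pos, loci$locus_id, loci$ref, loci$alt,
          ".", "PASS", ".", "GT",
          apply(gt_str, 1L, paste, collapse = "\t"), sep = "\t")
  } else character()
  writeLines(c(header, body), vcf_path)
  popv <- populations(ds)
  grp <- populationGroups(ds)
  pm <- data.frame(sample = names(popv), population = unname(popv))
  if (!all(is.na(grp))) pm$group <- unname(grp[pm$population])
  write.table(pm, popmap_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(ds)
}

#' Read an aligned FASTA of mitochondrial haplotypes with a popmap
#'
#' @param fasta_path path to an aligned FASTA (equal-length records).
#' @param popmap_path path to a `name<TAB>population` TSV.
#' @return a [HaplotypeAlignment-class]; sequences stored uppercase.
#' @export
readAlignment <- function(fasta_path, popmap_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  pm <- .read_popmap(popmap_path)
  HaplotypeAlignment(Biostrings::DNAStringSet(toupper(as.character(seqs))),
                     pm$populations)
}

#' Write a HaplotypeAlignment as FASTA plus popmap
#'
#' @param aln a [HaplotypeAlignment-class].
#' @param fasta_path,popmap_path output paths.
#' @return invisibly, `aln`.
#' @export
writeAlignment <- function(aln, fasta_path, popmap_path) {
  Biostrings::writeXStringSet(alnSequences(aln), fasta_path)
  pm <- data.frame(name = names(alnSequences(aln)),
                   population = alnPopulations(aln))
  write.table(pm, popmap_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(aln)
}

#' Remove fixed and low-frequency loci
#'
#' Computes the minor-allele frequency of every locus on the pooled sample
#' (all populations together, missing genotypes excluded) and drops loci
#' below `maf_min` and, when `remove_fixed`, monomorphic loci. Original
#' locus order is preserved; the removal counts are attached as the
#' `"filter_log"` attribute. Applying the filter twice is a no-op.
#'
#' @param ds a [GenotypeDataset-class].
#' @param maf_min minimum pooled minor-allele frequency (default 0.01).
#' @param remove_fixed drop monomorphic loci (default TRUE).
#' @return the filtered [GenotypeDataset-class].
#' @export
filterLoci <- function(ds, maf_min = 0.01, remove_fixed = TRUE) {
  if (maf_min < 0 || maf_min > 0.5) stop("maf_min must lie in [0, 0.5]")
  p <- .pooled_alt_freq(genotypes(ds))
  maf <- pmin(p, 1 - p)
  fixed <- is.na(maf) | maf == 0
  low <- !fixed & maf < maf_min
  keep <- !(low | (remove_fixed & fixed))
  out <- ds[keep, ]
  attr(out, "filter_log") <- c(n_in = length(keep),
                               n_fixed_removed = sum(fixed & remove_fixed),
                               n_maf_removed = sum(low),
                               n_out = sum(keep))
  out
}

#' Prune loci in high linkage disequilibrium
#'
#' Scans same-chromosome locus pairs in (chrom, pos_i, pos_j) order; when
#' a pair of still-retained loci has pooled-sample r-squared above
#' `r2_max`, one member is removed by a fair coin from the seeded stream.
#' After pruning no retained syntenic pair exceeds `r2_max`.
#'
#' @param ds a [GenotypeDataset-class].
#' @param r2_max maximum tolerated r-squared (default 0.5).
#' @param seed integer seed; fixed seed gives a deterministic result.
#' @return the pruned [GenotypeDataset-class].
#' @export
ldPrune <- function(ds, r2_max = 0.5, seed = 1L) {
  lt <- lociTable(ds)
  gt <- genotypes(ds)
  keep <- rep(TRUE, nrow(lt))
  .with_seed(seed, {
    for (chr in unique(lt$chrom)) {
      idx <- which(lt$chrom == chr)
      if (length(idx) < 2L) next
      for (ii in seq_len(length(idx) - 1L)) {
        i <- idx[[ii]]
        if (!keep[[i]]) next
        for (jj in seq.int(ii + 1L, length(idx))) {
          j <- idx[[jj]]
          if (!keep[[i]]) break
          if (!keep[[j]]) next
          r2 <- r2Pair(gt[i, ], gt[j, ])["r2"]
          if (!is.na(r2) && r2 > r2_max) {
            drop <- if (runif(1L) < 0.5) i else j
            keep[[drop]] <- FALSE
            if (drop == i) break
          }
        }
      }
    }
  })
  out <- ds[keep, ]
  attr(out, "prune_log") <- c(n_in = length(keep), n_removed = sum(!keep))
  out
}

#' Merge populations into one pooled label
#'
#' Popmap-level utility: relabels the given populations with one pooled
#' name (e.g. to form a representative wild population from several
#' weakly differentiated ones before LD or sweep scans).
#'
#' @param ds a [GenotypeDataset-class].
#' @param pops character vector of population names to merge.
#' @param name new pooled population name.
#' @return a [GenotypeDataset-class] with the merged popmap.
#' @export
mergePopulations <- function(ds, pops, name) {
  cd <- SummarizedExperiment::colData(ds)
  hit <- cd$population %in% pops
  if (!any(hit)) stop("no samples in the populations to merge")
  cd$population[hit] <- name
  SummarizedExperiment::colData(ds) <- cd
  ds
}
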