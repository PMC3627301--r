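# Post-hoc genome scans around outlier loci: Poisson bin clustering,
# heterozygosity-valley windows and LD-elevation windows.

#' Chromosome-length table yielding the canonical 76-bin tiling
#'
#' A synthetic Zv9-style table of 25 zebrafish chromosome lengths,
#' constructed so that 20 Mb tiling with partial final bins kept
#' produces 76 bins genome-wide (the published assembly's exact lengths
#' and tiling rule are not recoverable; this table reproduces the bin
#' count). Shipped as
#' `inst/extdata/zv9_synthetic_chrom_lengths.tsv`.
#'
#' @return named numeric vector of lengths in basepairs.
#' @export
defaultChromLengths <- function() {
  path <- system.file("extdata", "zv9_synthetic_chrom_lengths.tsv",
                      package = "zfpopgen")
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  setNames(tab$length_bp, tab$chrom)
}

#' Tile the genome into bins and count outliers per bin
#'
#' Bins are tiled per chromosome from position 1 as half-open intervals
#' `[start, start + bin_size)`; the final partial bin is kept.
#'
#' @param loci `data.frame` with `locus_id`, `chrom`, `pos` (e.g. from
#'   [lociTable()]).
#' @param outlier_mask logical vector flagging outlier loci (same
#'   order).
#' @param chrom_lengths named vector of chromosome lengths covering all
#'   loci.
#' @param bin_size bin size in basepairs (default 20 Mb).
#' @return `data.frame` with `chrom`, `start`, `end`, `n_outliers`,
#'   `n_snps`.
#' @export
binOutliers <- function(loci, outlier_mask, chrom_lengths,
                        bin_size = 20e6) {
  stopifnot(length(outlier_mask) == nrow(loci))
  res <- list()
  for (chr in names(chrom_lengths)) {
    len <- chrom_lengths[[chr]]
    on_chr <- loci$chrom == chr
    if (any(loci$pos[on_chr] > len))
      stop("locus beyond declared length of ", chr)
    n_bins <- ceiling(len / bin_size)
    starts <- 1 + (seq_len(n_bins) - 1) * bin_size
    ends <- pmin(starts + bin_size, len + 1)
    bin_of <- floor((loci$pos[on_chr] - 1) / bin_size) + 1L
    cnt_out <- tabulate(bin_of[outlier_mask[on_chr]], n_bins)
    cnt_all <- tabulate(bin_of, n_bins)
    res[[chr]] <- data.frame(chrom = chr, start = starts, end = ends,
                             n_outliers = cnt_out, n_snps = cnt_all,
                             stringsAsFactors = FALSE)
  }
  unexpected <- setdiff(unique(loci$chrom), names(chrom_lengths))
  if (length(unexpected))
    stop("chromosome ", unexpected[[1L]], " not in chrom_lengths")
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Poisson probability of an outlier count in one bin
#'
#' Point probability P(X = k) under a Poisson law whose mean is the
#' genome-wide outlier rate per bin, lambda = n_outliers / n_bins.
#'
#' @param k observed outlier count in the bin.
#' @param n_outliers total significant outliers genome-wide.
#' @param n_bins total bins.
#' @return P(X = k).
#' @examples
#' poissonClusterP(4, 62, 76) # 0.008
#' @export
poissonClusterP <- function(k, n_outliers, n_bins) {
  stopifnot(n_bins >= 1, k >= 0)
  dpois(k, n_outliers / n_bins)
}

#' Nonoverlapping null windows clear of exclusion zones
#'
#' Tiles nonoverlapping windows per chromosome from position 1 and
#' retains those lying fully outside every exclusion zone and containing
#' at least `min_snps` polymorphic SNPs.
#'
#' @param ds a [GenotypeDataset-class].
#' @param exclusion_zones `data.frame` with `chrom`, `start`, `end`
#'   (half-open) or NULL.
#' @param window window size, basepairs (default 10 Mb).
#' @param min_snps minimum polymorphic SNP count (default 6).
#' @param population population(s) defining polymorphism (default: all
#'   samples pooled).
#' @return `data.frame` with `chrom`, `start`, `end`, `n_snps`.
#' @export
tileNullWindows <- function(ds, exclusion_zones = NULL, window = 10e6,
                            min_snps = 6L, population = NULL) {
  lt <- lociTable(ds)
  gt <- genotypes(ds)
  if (!is.null(population)) gt <- gt[, populations(ds) %in% population,
                                     drop = FALSE]
  p <- .pooled_alt_freq(gt)
  poly <- !is.na(p) & p > 0 & p < 1
  res <- list()
  for (chr in unique(lt$chrom)) {
    on_chr <- lt$chrom == chr
    max_pos <- max(lt$pos[on_chr])
    n_win <- ceiling(max_pos / window)
    for (w in seq_len(n_win)) {
      start <- 1 + (w - 1) * window
      end <- start + window
      if (!is.null(exclusion_zones) && nrow(exclusion_zones)) {
        ez <- exclusion_zones[exclusion_zones$chrom == chr, , drop = FALSE]
        if (nrow(ez) && any(start < ez$end & ez$start < end)) next
      }
      inside <- on_chr & lt$pos >= start & lt$pos < end
      n_snps <- sum(inside & poly)
      if (n_snps < min_snps) next
      res[[length(res) + 1L]] <- data.frame(chrom = chr, start = start,
                                            end = end, n_snps = n_snps,
                                            stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_snps = integer()))
  do.call(rbind, res)
}

# Mean unbiased expected heterozygosity over a set of loci for the
# chosen sample. With a single population (or NULL = all samples pooled)
# the pooled allele frequency is used; with several populations the
# statistic is within-population He averaged across them, the natural
# "diversity within populations" a sweep depresses.
.window_het <- function(ds, loci_idx, population = NULL) {
  gt <- genotypes(ds)
  if (is.null(population) || length(population) == 1L) {
    if (!is.null(population)) gt <- gt[, populations(ds) %in% population,
                                       drop = FALSE]
    g <- gt[loci_idx, , drop = FALSE]
    nn <- rowSums(!is.na(g))
    p <- ifelse(nn > 0, rowSums(g, na.rm = TRUE) / (2 * nn), NA_real_)
    mean(.unbiased_het(nn, p), na.rm = TRUE)
  } else {
    popv <- populations(ds)
    he <- vapply(population, function(pp) {
      gp <- gt[loci_idx, popv == pp, drop = FALSE]
      nn <- rowSums(!is.na(gp))
      p <- ifelse(nn > 0, rowSums(gp, na.rm = TRUE) / (2 * nn), NA_real_)
      mean(.unbiased_het(nn, p), na.rm = TRUE)
    }, 0)
    mean(he, na.rm = TRUE)
  }
}

.outlier_windows <- function(ds, outliers, window) {
  lt <- lociTable(ds)
  sig <- outliers[outliers$class %in% c("high", "low"), , drop = FALSE]
  idx <- match(sig$locus_id, lt$locus_id)
  data.frame(locus_id = sig$locus_id, class = sig$class,
             chrom = lt$chrom[idx],
             pos = lt$pos[idx],
             start = pmax(1, lt$pos[idx] - window / 2),
             end = lt$pos[idx] + window / 2,
             stringsAsFactors = FALSE)
}

#' Heterozygosity-valley scan around outlier loci
#'
#' For each significant outlier, computes the mean expected
#' heterozygosity of the SNPs in a window centred on it (focal locus
#' excluded) and compares it against the genome-wide distribution of
#' means over nonoutlier windows ([tileNullWindows()] with all outlier
#' windows excluded). The empirical lower-tail percentile is the
#' P-value; windows with P below `alpha` are flagged as heterozygosity
#' valleys consistent with selective sweeps.
#'
#' @param ds a [GenotypeDataset-class].
#' @param outliers `data.frame` from [classifyOutliers()] (or any frame
#'   with `locus_id` and `class`).
#' @param population population(s) in which heterozygosity is measured,
#'   pooled; NULL = all samples.
#' @param window window size, basepairs (default 10 Mb).
#' @param min_snps minimum SNPs per window (default 6).
#' @param alpha significance cutoff (default 0.05).
#' @return `data.frame` of per-outlier window statistics with
#'   `empirical_p` and `significant`; null-window means are attached as
#'   the `"null_means"` attribute.
#' @export
hetWindowScan <- function(ds, outliers, population = NULL,
                          window = 10e6, min_snps = 6L, alpha = 0.05) {
  lt <- lociTable(ds)
  ow <- .outlier_windows(ds, outliers, window)
  nw <- tileNullWindows(ds, exclusion_zones = ow, window = window,
                        min_snps = min_snps, population = population)
  if (nrow(nw) < 10L) stop("fewer than 10 null windows available")
  null_means <- vapply(seq_len(nrow(nw)), function(i) {
    idx <- which(lt$chrom == nw$chrom[[i]] & lt$pos >= nw$start[[i]] &
                   lt$pos < nw$end[[i]])
    .window_het(ds, idx, population)
  }, 0)
  out <- ow
  out$n_snps <- NA_integer_
  out$statistic <- NA_real_
  out$empirical_p <- NA_real_
  for (i in seq_len(nrow(ow))) {
    idx <- which(lt$chrom == ow$chrom[[i]] & lt$pos >= ow$start[[i]] &
                   lt$pos < ow$end[[i]] & lt$locus_id != ow$locus_id[[i]])
    out$n_snps[[i]] <- length(idx)
    if (length(idx) < min_snps) next
    stat <- .window_het(ds, idx, population)
    out$statistic[[i]] <- stat
    out$empirical_p[[i]] <- (1 + sum(null_means <= stat + 1e-12)) /
      (1 + length(null_means))
  }
  out$significant <- !is.na(out$empirical_p) & out$empirical_p < alpha
  attr(out, "null_means") <- null_means
  out
}

#' LD-elevation scan around outlier loci
#'
#' For each significant outlier, computes the mean r-squared between the
#' focal locus and every other polymorphic SNP in its window, and
#' compares it (upper tail) against null windows whose focal locus is
#' the SNP nearest the window midpoint.
#'
#' @inheritParams hetWindowScan
#' @return `data.frame` of per-outlier window statistics with
#'   `empirical_p` (upper tail) and `significant`; null-window means
#'   attached as `"null_means"`.
#' @export
ldWindowScan <- function(ds, outliers, population = NULL,
                         window = 10e6, min_snps = 6L, alpha = 0.05) {
  lt <- lociTable(ds)
  gt <- genotypes(ds)
  if (!is.null(population)) gt <- gt[, populations(ds) %in% population,
                                     drop = FALSE]
  mean_r2_focal <- function(focal_idx, idx) {
    r2 <- vapply(idx, function(j)
      r2Pair(gt[focal_idx, ], gt[j, ])[["r2"]], 0)
    if (all(is.na(r2))) NA_real_ else mean(r2, na.rm = TRUE)
  }
  ow <- .outlier_windows(ds, outliers, window)
  nw <- tileNullWindows(ds, exclusion_zones = ow, window = window,
                        min_snps = min_snps, population = population)
  if (nrow(nw) < 10L) stop("fewer than 10 null windows available")
  null_means <- vapply(seq_len(nrow(nw)), function(i) {
    idx <- which(lt$chrom == nw$chrom[[i]] & lt$pos >= nw$start[[i]] &
                   lt$pos < nw$end[[i]])
    mid <- (nw$start[[i]] + nw$end[[i]]) / 2
    focal <- idx[which.min(abs(lt$pos[idx] - mid))]
    mean_r2_focal(focal, setdiff(idx, focal))
  }, 0)
  null_means <- null_means[!is.na(null_means)]
  out <- ow
  out$n_snps <- NA_integer_
  out$statistic <- NA_real_
  out$empirical_p <- NA_real_
  for (i in seq_len(nrow(ow))) {
    focal <- match(ow$locus_id[[i]], lt$locus_id)
    idx <- which(lt$chrom == ow$chrom[[i]] & lt$pos >= ow$start[[i]] &
                   lt$pos < ow$end[[i]])
    idx <- setdiff(idx, focal)
    out$n_snps[[i]] <- length(idx)
    if (!length(idx)) next
    stat <- mean_r2_focal(focal, idx)
    out$statistic[[i]] <- stat
    if (!is.na(stat))
      out$empirical_p[[i]] <- (1 + sum(null_means >= stat - 1e-12)) /
        (1 + length(null_means))
  }
  out$significant <- !is.na(out$empirical_p) & out$empirical_p < alpha
  attr(out, "null_means") <- null_means
  out
}
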