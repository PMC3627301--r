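# Pairwise linkage disequilibrium for unphased diploid genotypes,
# genome-wide decay curves, logarithmic fits and characteristic
# distances.

#' r-squared between two unphased genotype columns
#'
#' Two-locus haplotype frequencies are estimated by EM over the
#' double-heterozygote phase ambiguity (initialized at linkage
#' equilibrium, convergence when the largest frequency change is below
#' `tol`). D = p_AB - p_A p_B and r2 = D^2 / (p_A q_A p_B q_B).
#'
#' @param gA,gB integer genotype vectors (0/1/2, NA missing) over the
#'   same individuals.
#' @param tol EM convergence tolerance (default 1e-8).
#' @param max_iter maximum EM iterations (default 1000).
#' @return named vector `c(r2, D, n)`; `r2` is `NA` (flagged) when a
#'   locus is monomorphic or fewer than 2 complete individuals remain.
#' @export
r2Pair <- function(gA, gB, tol = 1e-8, max_iter = 1000L) {
  stopifnot(length(gA) == length(gB))
  out <- .r2_em(as.integer(gA), as.integer(gB), tol, as.integer(max_iter))
  setNames(out, c("r2", "D", "n"))
}

#' All same-chromosome locus pairs with distances and r-squared
#'
#' @param ds a [GenotypeDataset-class].
#' @param population population name, a character vector of populations
#'   (treated as one pooled sample), or `NULL` for all samples pooled.
#' @param max_distance optional distance cap in basepairs.
#' @return `data.frame` with `locus1`, `locus2`, `chrom`, `distance`,
#'   `r2`, `D` (monomorphic pairs are dropped).
#' @export
syntenicPairs <- function(ds, population = NULL, max_distance = NULL) {
  lt <- lociTable(ds)
  gt <- genotypes(ds)
  if (!is.null(population)) {
    sel <- populations(ds) %in% population
    if (!any(sel)) stop("no samples in population ", population[[1L]])
    gt <- gt[, sel, drop = FALSE]
  }
  res <- list()
  for (chr in unique(lt$chrom)) {
    idx <- which(lt$chrom == chr)
    if (length(idx) < 2L) next
    for (a in seq_len(length(idx) - 1L)) for (b in seq.int(a + 1L,
                                                           length(idx))) {
      i <- idx[[a]]; j <- idx[[b]]
      dist <- abs(lt$pos[[i]] - lt$pos[[j]])
      if (!is.null(max_distance) && dist > max_distance) next
      r <- r2Pair(gt[i, ], gt[j, ])
      if (is.na(r[["r2"]])) next
      res[[length(res) + 1L]] <-
        data.frame(locus1 = lt$locus_id[[i]], locus2 = lt$locus_id[[j]],
                   chrom = chr, distance = dist,
                   r2 = r[["r2"]], D = r[["D"]],
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(locus1 = character(), locus2 = character(),
                      chrom = character(), distance = numeric(),
                      r2 = numeric(), D = numeric()))
  do.call(rbind, res)
}

#' Fit a logarithmic decay curve to binned r-squared
#'
#' Bins pairs by distance into `[k*w, (k+1)*w)` intervals, takes the
#' mean r-squared per bin, and fits ordinary least squares of the bin
#' means on the natural log of the bin midpoint in megabases:
#' `mean r2 = a * ln(Mb) + b`.
#'
#' @param pairs `data.frame` from [syntenicPairs()].
#' @param bin_width bin width, basepairs (default 5 Mb).
#' @param truncate_at ignore pairs beyond this distance (optional).
#' @return a [DecayFit-class].
#' @export
fitDecay <- function(pairs, bin_width = 5e6, truncate_at = NULL) {
  if (!is.null(truncate_at)) pairs <- pairs[pairs$distance <= truncate_at, ]
  if (!nrow(pairs)) stop("no pairs to fit")
  bin <- floor(pairs$distance / bin_width)
  mid <- (sort(unique(bin)) + 0.5) * bin_width / 1e6
  mean_r2 <- tapply(pairs$r2, bin, mean)
  n_pairs <- as.integer(table(bin))
  if (length(mid) < 2L) stop("need at least 2 nonempty bins")
  fit <- lm(y ~ x, data = data.frame(x = log(mid), y = as.numeric(mean_r2)))
  new("DecayFit", bin_width = bin_width, bin_mid_mb = mid,
      mean_r2 = as.numeric(mean_r2), n_pairs = n_pairs,
      a = unname(coef(fit)[[2L]]), b = unname(coef(fit)[[1L]]))
}

#' Distance at which the fitted decay curve reaches a threshold
#'
#' Solves `a * ln(x) + b = threshold` for x in megabases; returned in
#' basepairs. Requires a decaying fit (a < 0). A warning is raised when
#' the solution lies outside the fitted distance range (extrapolation).
#'
#' @param fit a [DecayFit-class] (or a list with `a` and `b`).
#' @param threshold target r-squared (default 0.2).
#' @return distance in basepairs.
#' @export
decayDistance <- function(fit, threshold = 0.2) {
  a <- if (is(fit, "DecayFit")) fit@a else fit$a
  b <- if (is(fit, "DecayFit")) fit@b else fit$b
  if (a >= 0) stop("fit is not decaying (a >= 0)")
  x_mb <- exp((threshold - b) / a)
  if (is(fit, "DecayFit") && length(fit@bin_mid_mb) &&
      (x_mb < min(fit@bin_mid_mb) || x_mb > max(fit@bin_mid_mb)))
    warning(sprintf("solution %.3g Mb extrapolates beyond the fitted range",
                    x_mb))
  x_mb * 1e6
}

#' Half-length of the empirical LD decay curve
#'
#' The maximal value is the mean r-squared of the shortest-distance bin;
#' the half-length is the distance at which linear interpolation of the
#' bin-mean curve first crosses half that value. The empirical curve is
#' used rather than the logarithmic fit, which can be unreliable for
#' this quantity. If the curve never crosses, the upper data bound is
#' returned with a warning.
#'
#' @param fit a [DecayFit-class].
#' @return distance in basepairs.
#' @export
halfLength <- function(fit) {
  if (!length(fit@bin_mid_mb)) stop("empty fit")
  y <- fit@mean_r2
  x <- fit@bin_mid_mb
  target <- y[[1L]] / 2
  for (i in seq_len(length(y) - 1L)) {
    if ((y[[i]] - target) * (y[[i + 1L]] - target) <= 0) {
      frac <- if (y[[i + 1L]] == y[[i]]) 0 else
        (y[[i]] - target) / (y[[i]] - y[[i + 1L]])
      return((x[[i]] + frac * (x[[i + 1L]] - x[[i]])) * 1e6)
    }
  }
  warning("decay curve never crosses half its maximum; returning upper bound")
  x[[length(x)]] * 1e6
}
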