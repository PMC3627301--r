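# Among-population differentiation: Weir-Cockerham theta, Jost's D_est,
# permutation/bootstrap uncertainty, and FDR control.

# Vectorized Weir-Cockerham (1984) variance components for many loci at
# once. n, p, h: loci x populations matrices of diploid sample sizes,
# alternate-allele frequencies and observed heterozygote fractions.
# Populations with zero usable genotypes at a locus are dropped locus-wise.
.wc_components <- function(n, p, h) {
  use <- !is.na(p) & n > 0
  r <- rowSums(use)
  n_ <- n; n_[!use] <- 0
  p_ <- p; p_[!use] <- 0
  h_ <- h; h_[!use] <- 0
  nsum <- rowSums(n_)
  nbar <- nsum / r
  nc <- (nsum - rowSums(n_^2) / nsum) / (r - 1)
  pbar <- rowSums(n_ * p_) / nsum
  s2 <- rowSums(n_ * (p_ - pbar)^2 * use) / ((r - 1) * nbar)
  hbar <- rowSums(n_ * h_) / nsum
  pq <- pbar * (1 - pbar)
  a <- (nbar / nc) *
    (s2 - (pq - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pq - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  c <- hbar / 2
  bad <- r < 2 | nbar <= 1
  a[bad] <- b[bad] <- c[bad] <- NA_real_
  list(a = a, b = b, c = c,
       theta = ifelse(a + b + c != 0, a / (a + b + c), NA_real_),
       nbar = nbar, nc = nc, r = r, pbar = pbar, s2 = s2, hbar = hbar)
}

#' Weir-Cockerham variance components and theta for one locus
#'
#' Computes the among-population (a), among-individual-within-population
#' (b) and within-individual (c) components of allele-frequency variance
#' and theta = a/(a+b+c), the sample-size-corrected F_ST estimator.
#'
#' @param n integer vector of diploid sample sizes per population.
#' @param p alternate-allele frequency per population.
#' @param h observed heterozygote fraction per population.
#' @return list with `a`, `b`, `c`, `theta` and the intermediate
#'   quantities (`nbar`, `nc`, `r`, `pbar`, `s2`, `hbar`). `theta` is
#'   `NA` (flagged) when a + b + c = 0.
#' @examples
#' # two populations of 5 diploids fixed for alternative alleles:
#' wcThetaLocus(c(5, 5), c(0, 1), c(0, 0))$theta # 1
#' @export
wcThetaLocus <- function(n, p, h) {
  if (length(n) < 2L) stop("need at least 2 populations")
  comp <- .wc_components(matrix(n, 1L), matrix(p, 1L), matrix(h, 1L))
  lapply(comp, as.numeric)
}

# Per-locus components for a dataset restricted to pops.
.wc_dataset <- function(ds, pops = NULL) {
  pc <- .pop_counts(ds, pops)
  .wc_components(pc$n, pc$p, pc$h)
}

#' Multilocus Weir-Cockerham theta with bootstrap CI and pairwise tests
#'
#' The overall estimate is the ratio-of-sums combination
#' `sum(a) / sum(a+b+c)` over loci. The 95% confidence interval is a
#' percentile bootstrap over loci (`n_perm` draws). Pairwise
#' population-by-population theta is tested by permuting individuals
#' between the two populations.
#'
#' @param ds a [GenotypeDataset-class] (filter loci beforehand as
#'   desired).
#' @param pops populations to include (default: all).
#' @param n_perm bootstrap/permutation replicates (default 1000).
#' @param seed integer seed.
#' @param pairwise also compute the pairwise matrix and permutation
#'   P-values (default TRUE).
#' @return list with `theta`, `ci_low`, `ci_high`, `per_locus`, and when
#'   `pairwise`, matrices `pair_theta` and `pair_p`.
#' @export
wcThetaOverall <- function(ds, pops = NULL, n_perm = 1000L, seed = 1L,
                           pairwise = TRUE) {
  popv <- populations(ds)
  if (is.null(pops)) pops <- unique(unname(popv))
  comp <- .wc_dataset(ds, pops)
  ok <- !is.na(comp$a)
  theta <- sum(comp$a[ok]) / sum((comp$a + comp$b + comp$c)[ok])
  nl <- sum(ok)
  ci <- c(NA_real_, NA_real_)
  out <- list(theta = theta, per_locus = comp$theta)
  .with_seed(seed, {
    if (nl >= 2L) {
      idx_ok <- which(ok)
      boot <- vapply(seq_len(n_perm), function(i) {
        bi <- sample(idx_ok, nl, replace = TRUE)
        sum(comp$a[bi]) / sum((comp$a + comp$b + comp$c)[bi])
      }, 0)
      ci <- unname(quantile(boot, c(0.025, 0.975), na.rm = TRUE))
    } else warning("fewer than 2 usable loci: CI undefined")
    if (pairwise && length(pops) >= 2L) {
      np <- length(pops)
      pair_theta <- pair_p <- matrix(NA_real_, np, np,
                                     dimnames = list(pops, pops))
      gt <- genotypes(ds)
      for (i in seq_len(np - 1L)) for (j in seq.int(i + 1L, np)) {
        sel <- popv %in% pops[c(i, j)]
        sub <- gt[, sel, drop = FALSE]
        lab <- popv[sel]
        obs <- .theta_from_matrix(sub, lab, pops[c(i, j)])
        perm <- vapply(seq_len(n_perm), function(b)
          .theta_from_matrix(sub, sample(lab), pops[c(i, j)]), 0)
        pair_theta[i, j] <- pair_theta[j, i] <- obs
        pair_p[i, j] <- pair_p[j, i] <-
          (1 + sum(perm >= obs - 1e-12, na.rm = TRUE)) / (1 + n_perm)
      }
      out$pair_theta <- pair_theta
      out$pair_p <- pair_p
    }
  })
  out$ci_low <- ci[[1L]]; out$ci_high <- ci[[2L]]
  out
}

.theta_from_matrix <- function(gt, labels, pops) {
  n <- p <- h <- matrix(NA_real_, nrow(gt), length(pops))
  for (j in seq_along(pops)) {
    g <- gt[, labels == pops[[j]], drop = FALSE]
    nn <- rowSums(!is.na(g))
    n[, j] <- nn
    p[, j] <- ifelse(nn > 0, rowSums(g, na.rm = TRUE) / (2 * nn), NA_real_)
    h[, j] <- ifelse(nn > 0, rowSums(g == 1L, na.rm = TRUE) / nn, NA_real_)
  }
  comp <- .wc_components(n, p, h)
  ok <- !is.na(comp$a)
  sum(comp$a[ok]) / sum((comp$a + comp$b + comp$c)[ok])
}

# Nei-Chesser estimators and Jost's D per locus.
# n, p: vectors over populations (diploid counts, alt freqs); ho:
# observed heterozygote fractions.
.dest_locus <- function(n, p, ho) {
  use <- !is.na(p) & n > 0
  n <- n[use]; p <- p[use]; ho <- ho[use]
  r <- length(n)
  if (r < 2L) return(NA_real_)
  ntilde <- r / sum(1 / n)
  ho_bar <- mean(ho)
  hs <- (ntilde / (ntilde - 1)) *
    (1 - mean(p^2 + (1 - p)^2) - ho_bar / (2 * ntilde))
  pbar <- mean(p)
  ht <- 1 - (pbar^2 + (1 - pbar)^2) + hs / (ntilde * r) -
    ho_bar / (2 * ntilde * r)
  if (hs >= 1) return(NA_real_)
  ((ht - hs) / (1 - hs)) * r / (r - 1)
}

#' Jost's D_est with permutation P and bootstrap CI
#'
#' Per-locus D_est uses the Nei-Chesser sample-size-corrected H_S and
#' H_T (harmonic mean sample size); the overall estimate is the mean of
#' per-locus values. The P-value permutes individuals among populations;
#' the confidence interval bootstraps individuals within populations.
#' Negative per-locus values are retained.
#'
#' @param ds a [GenotypeDataset-class].
#' @param pops populations to include (default: all).
#' @param n_perm permutation/bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @return list with `dest`, `per_locus`, `p`, `ci_low`, `ci_high`.
#' @export
jostDest <- function(ds, pops = NULL, n_perm = 1000L, seed = 1L) {
  popv <- populations(ds)
  if (is.null(pops)) pops <- unique(unname(popv))
  if (length(pops) < 2L) stop("need at least 2 populations")
  gt <- genotypes(ds)[, popv %in% pops, drop = FALSE]
  lab <- popv[popv %in% pops]
  dest_all <- function(g, labels) {
    per <- vapply(seq_len(nrow(g)), function(l) {
      row <- g[l, ]
      nn <- vapply(pops, function(pp) sum(!is.na(row[labels == pp])), 0)
      p <- vapply(pops, function(pp) {
        x <- row[labels == pp]; x <- x[!is.na(x)]
        if (length(x)) sum(x) / (2 * length(x)) else NA_real_
      }, 0)
      ho <- vapply(pops, function(pp) {
        x <- row[labels == pp]; x <- x[!is.na(x)]
        if (length(x)) mean(x == 1L) else NA_real_
      }, 0)
      .dest_locus(nn, p, ho)
    }, 0)
    mean(per, na.rm = TRUE)
  }
  per_locus <- vapply(seq_len(nrow(gt)), function(l) {
    row <- gt[l, ]
    nn <- vapply(pops, function(pp) sum(!is.na(row[lab == pp])), 0)
    p <- vapply(pops, function(pp) {
      x <- row[lab == pp]; x <- x[!is.na(x)]
      if (length(x)) sum(x) / (2 * length(x)) else NA_real_
    }, 0)
    ho <- vapply(pops, function(pp) {
      x <- row[lab == pp]; x <- x[!is.na(x)]
      if (length(x)) mean(x == 1L) else NA_real_
    }, 0)
    .dest_locus(nn, p, ho)
  }, 0)
  obs <- mean(per_locus, na.rm = TRUE)
  res <- list(dest = obs, per_locus = per_locus)
  .with_seed(seed, {
    perm <- vapply(seq_len(n_perm), function(b)
      dest_all(gt, sample(lab)), 0)
    res$p <- (1 + sum(perm >= obs - 1e-12, na.rm = TRUE)) / (1 + n_perm)
    boot <- vapply(seq_len(n_perm), function(b) {
      idx <- unlist(lapply(pops, function(pp) {
        w <- which(lab == pp)
        sample(w, length(w), replace = TRUE)
      }))
      dest_all(gt[, idx, drop = FALSE], lab[idx])
    }, 0)
    ci <- unname(quantile(boot, c(0.025, 0.975), na.rm = TRUE))
    res$ci_low <- ci[[1L]]; res$ci_high <- ci[[2L]]
  })
  res
}

#' Benjamini-Hochberg step-up FDR mask
#'
#' @param pvalues numeric vector of P-values in [0, 1].
#' @param alpha FDR level (default 0.05).
#' @return logical vector: TRUE where the hypothesis is rejected with
#'   false discovery rate controlled at `alpha`.
#' @export
bhFdr <- function(pvalues, alpha = 0.05) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("P-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH") <= alpha & !is.na(pvalues)
}
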