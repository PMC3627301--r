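# Within-population diversity statistics for SNPs and mtDNA, exact
# Hardy-Weinberg tests, TN93 distances, hierarchical AMOVA and the pooled
# two-sample t comparison.

#' Unbiased expected heterozygosity at one locus in one population
#'
#' He = 2n/(2n-1) * (1 - p^2 - q^2) with n the number of non-missing
#' diploid genotypes and p the alternate-allele frequency, i.e. Nei's
#' gene diversity with the small-sample correction.
#'
#' @param ds a [GenotypeDataset-class].
#' @param population population name.
#' @param locus locus id.
#' @return He in [0, 1]; `NA` (with a warning) when fewer than two usable
#'   genotypes exist.
#' @export
expectedHet <- function(ds, population, locus) {
  g <- genotypes(ds)[locus, populations(ds) == population]
  g <- g[!is.na(g)]
  n <- length(g)
  if (n < 2L) {
    warning("locus ", locus, " has fewer than 2 usable genotypes in ",
            population)
    return(NA_real_)
  }
  p <- sum(g) / (2 * n)
  (2 * n / (2 * n - 1)) * (1 - p^2 - (1 - p)^2)
}

# Vectorized unbiased He from diploid count and alt frequency matrices.
.unbiased_het <- function(n, p) {
  ifelse(n >= 2, (2 * n / (2 * n - 1)) * (1 - p^2 - (1 - p)^2), NA_real_)
}

#' Mean unbiased expected heterozygosity per population (H_S)
#'
#' Averages [expectedHet()] over all retained loci (zeros from
#' monomorphic loci included; loci with fewer than two usable genotypes
#' excluded).
#'
#' @param ds a [GenotypeDataset-class].
#' @param pops populations to summarize (default: all).
#' @return named numeric vector of per-population means.
#' @export
meanExpectedHet <- function(ds, pops = NULL) {
  pc <- .pop_counts(ds, pops)
  he <- .unbiased_het(pc$n, pc$p)
  setNames(colMeans(he, na.rm = TRUE), pc$pops)
}

# Levene (1949) conditional distribution of the heterozygote count given
# the allele counts: log P(h | nA, n) for all feasible h.
.levene_logprob <- function(nA, n) {
  n2 <- 2L * n
  nB <- n2 - nA
  hmax <- min(nA, nB)
  h <- seq.int(nA %% 2L, hmax, by = 2L)
  lp <- lgamma(n + 1) - lgamma((nA - h) / 2 + 1) - lgamma(h + 1) -
    lgamma((nB - h) / 2 + 1) + h * log(2) +
    lgamma(nA + 1) + lgamma(nB + 1) - lgamma(n2 + 1)
  list(h = h, logp = lp)
}

#' Exact Hardy-Weinberg test for one locus in one population
#'
#' Conditional exact test: the heterozygote count given the allele counts
#' follows the Levene distribution; the two-sided P-value sums the
#' probabilities of all heterozygote counts no more probable than the
#' observed one.
#'
#' @param ds a [GenotypeDataset-class].
#' @param population population name.
#' @param locus locus id.
#' @return P-value in (0, 1]; 1 for monomorphic loci.
#' @export
hweExactTest <- function(ds, population, locus) {
  g <- genotypes(ds)[locus, populations(ds) == population]
  g <- g[!is.na(g)]
  if (length(g) < 2L) stop("fewer than 2 usable genotypes")
  .hwe_p(sum(g == 0L), sum(g == 1L), sum(g == 2L))
}

.hwe_p <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  nA <- n1 + 2L * n2
  if (nA == 0L || nA == 2L * n) return(1)
  lev <- .levene_logprob(min(nA, 2L * n - nA), n)
  p_obs <- lev$logp[match(n1, lev$h)]
  min(1, sum(exp(lev$logp[lev$logp <= p_obs + 1e-12])))
}

#' Hardy-Weinberg test summary over all population x locus combinations
#'
#' Runs [hweExactTest()] for every (population, locus) pair that is
#' polymorphic with at least two usable genotypes, and reports the number
#' of tests, the number significant at `alpha`, and the count expected by
#' chance (`round(alpha * n_tests)`).
#'
#' @param ds a [GenotypeDataset-class].
#' @param alpha significance level (default 0.05).
#' @return list with `n_tests`, `n_significant`, `n_expected` and the
#'   vector of P-values.
#' @export
hweSummary <- function(ds, alpha = 0.05) {
  .assert_fraction(alpha, "alpha")
  pc <- .pop_counts(ds)
  gt <- genotypes(ds)
  popv <- populations(ds)
  pvals <- numeric(0)
  for (j in seq_along(pc$pops)) {
    g <- gt[, popv == pc$pops[[j]], drop = FALSE]
    n0 <- rowSums(g == 0L, na.rm = TRUE)
    n1 <- rowSums(g == 1L, na.rm = TRUE)
    n2 <- rowSums(g == 2L, na.rm = TRUE)
    ok <- (n0 + n1 + n2) >= 2L & (n1 + 2L * n2) > 0L &
      (n1 + 2L * n0) > 0L
    if (any(ok))
      pvals <- c(pvals, mapply(.hwe_p, n0[ok], n1[ok], n2[ok]))
  }
  list(n_tests = length(pvals),
       n_significant = sum(pvals < alpha),
       n_expected = round(alpha * length(pvals)),
       pvalues = pvals)
}

# Alignment as a character matrix restricted to complete (gap- and
# N-free) columns.
.aln_matrix <- function(aln, complete_deletion = TRUE) {
  m <- do.call(rbind, strsplit(as.character(alnSequences(aln)), ""))
  rownames(m) <- names(alnSequences(aln))
  if (complete_deletion && ncol(m)) {
    ok <- colSums(m == "N" | m == "-") == 0L
    m <- m[, ok, drop = FALSE]
  }
  m
}

#' Haplotype summary statistics for one population
#'
#' S = number of segregating sites, h = unbiased haplotype diversity
#' (n/(n-1))(1 - sum f_i^2), pi = mean pairwise p-distance per site.
#' Columns containing N or a gap in any included sequence are excluded
#' (complete deletion).
#'
#' @param aln a [HaplotypeAlignment-class].
#' @param population population name.
#' @return list with `S`, `h`, `pi`, `n`.
#' @export
haplotypeStats <- function(aln, population) {
  sel <- alnPopulations(aln) == population
  if (sum(sel) < 2L) stop("need at least 2 sequences in ", population)
  m <- .aln_matrix(aln)[sel, , drop = FALSE]
  n <- nrow(m)
  S <- sum(apply(m, 2L, function(col) length(unique(col)) > 1L))
  hap <- apply(m, 1L, paste, collapse = "")
  f <- table(hap) / n
  h <- (n / (n - 1)) * (1 - sum(f^2))
  dif <- 0
  for (i in seq_len(n - 1L))
    for (j in seq.int(i + 1L, n))
      dif <- dif + sum(m[i, ] != m[j, ])
  pi <- if (ncol(m)) dif / choose(n, 2) / ncol(m) else 0
  list(S = S, h = h, pi = pi, n = n)
}

#' Tamura-Nei (TN93) distance between two aligned sequences
#'
#' Distance correction with distinct rates for purine transitions,
#' pyrimidine transitions and transversions, using externally supplied
#' base frequencies. Sites where either sequence has N or a gap are
#' skipped.
#'
#' @param seqA,seqB character strings or `DNAString`s of equal length.
#' @param freqs named numeric vector `c(A=,C=,G=,T=)` summing to 1.
#' @return the TN93 distance (substitutions per site).
#' @export
tn93Distance <- function(seqA, seqB, freqs) {
  a <- strsplit(toupper(as.character(seqA)), "")[[1L]]
  b <- strsplit(toupper(as.character(seqB)), "")[[1L]]
  if (length(a) != length(b)) stop("sequences must have equal length")
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[ok]; b <- b[ok]
  L <- length(a)
  if (L < 1L) stop("no overlapping unambiguous sites")
  P1 <- sum((a == "A" & b == "G") | (a == "G" & b == "A")) / L
  P2 <- sum((a == "C" & b == "T") | (a == "T" & b == "C")) / L
  Q <- sum(a != b) / L - P1 - P2
  gA <- freqs[["A"]]; gC <- freqs[["C"]]; gG <- freqs[["G"]]; gT <- freqs[["T"]]
  gR <- gA + gG; gY <- gC + gT
  k1 <- 2 * gA * gG / gR
  k2 <- 2 * gC * gT / gY
  k3 <- 2 * (gR * gY - gA * gG * gY / gR - gC * gT * gR / gY)
  w1 <- if (k1 > 0) 1 - P1 / k1 - Q / (2 * gR) else 1
  w2 <- if (k2 > 0) 1 - P2 / k2 - Q / (2 * gY) else 1
  w3 <- 1 - Q / (2 * gR * gY)
  if (w1 <= 0 || w2 <= 0 || w3 <= 0)
    stop("TN93 distance undefined (saturation): log argument <= 0")
  t1 <- if (k1 > 0) -k1 * log(w1) else 0
  t2 <- if (k2 > 0) -k2 * log(w2) else 0
  unname(t1 + t2 - k3 * log(w3))
}

#' Distance model for alignment-based statistics
#'
#' @param kind `"p"` (proportion of differing sites) or `"TN93"`.
#' @param aln optional [HaplotypeAlignment-class] from which TN93 base
#'   frequencies are estimated (complete-deletion sites).
#' @return list with `kind` and `freqs`.
#' @export
distanceModel <- function(kind = c("p", "TN93"), aln = NULL) {
  kind <- match.arg(kind)
  freqs <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  if (!is.null(aln)) {
    m <- .aln_matrix(aln)
    tab <- table(factor(m, levels = c("A", "C", "G", "T")))
    freqs <- as.numeric(tab) / sum(tab)
    names(freqs) <- c("A", "C", "G", "T")
  }
  list(kind = kind, freqs = freqs)
}

# Pairwise distance matrix over all sequences under a model.
.pairwise_dist <- function(aln, model) {
  m <- .aln_matrix(aln)
  n <- nrow(m)
  L <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(max(0L, n - 1L)))
    for (j in seq.int(i + 1L, n)) {
      d[i, j] <- d[j, i] <- if (model$kind == "p")
        sum(m[i, ] != m[j, ]) / L
      else tn93Distance(paste(m[i, ], collapse = ""),
                        paste(m[j, ], collapse = ""), model$freqs)
    }
  d
}

#' Net nucleotide divergence (Da) between two populations
#'
#' Da = dXY - (dX + dY)/2 with d the mean pairwise distance under the
#' chosen model (within-population means taken over distinct pairs).
#'
#' @param aln a [HaplotypeAlignment-class].
#' @param popX,popY population names.
#' @param model a [distanceModel()] (default p-distance).
#' @return Da, substitutions per site.
#' @export
netDivergence <- function(aln, popX, popY, model = distanceModel("p")) {
  pops <- alnPopulations(aln)
  ix <- which(pops == popX); iy <- which(pops == popY)
  if (!length(ix) || !length(iy)) stop("both populations need sequences")
  d <- .pairwise_dist(aln, model)
  mean_within <- function(idx) {
    if (length(idx) < 2L) return(0)
    sub <- d[idx, idx, drop = FALSE]
    sum(sub[upper.tri(sub)]) / choose(length(idx), 2)
  }
  dxy <- mean(d[ix, iy, drop = FALSE])
  dxy - (mean_within(ix) + mean_within(iy)) / 2
}

#' Hierarchical AMOVA from a squared-distance matrix
#'
#' Excoffier-style analysis of molecular variance with three levels
#' (among groups, among populations within groups, within populations).
#' Phi-statistics follow the standard definitions: Phi_CT = sigma_a /
#' total, Phi_SC = sigma_b / (sigma_b + sigma_c), Phi_ST =
#' (sigma_a + sigma_b) / total. Permutation P-values use level-specific
#' schemes: sequences among populations within groups (Phi_SC), whole
#' populations among groups (Phi_CT), sequences among populations across
#' groups (Phi_ST).
#'
#' @param dist square matrix of squared distances between sequences
#'   (e.g. squared TN93 or p-distances; for Euclidean-embedded distances
#'   pass `d^2`).
#' @param popmap character vector, population of each row of `dist`.
#' @param groups named character vector mapping population to group; by
#'   default every population forms its own group is not allowed - a
#'   grouping must be supplied.
#' @param n_perm permutations for P-values (default 10000).
#' @param seed integer seed.
#' @return list with variance components `sigma_a`, `sigma_b`, `sigma_c`,
#'   `phi_ct`, `phi_sc`, `phi_st`, permutation P-values and a
#'   `degenerate` flag set when the total variance is zero.
#' @export
amova <- function(dist, popmap, groups, n_perm = 10000L, seed = 1L) {
  dist <- as.matrix(dist)
  popmap <- as.character(popmap)
  stopifnot(nrow(dist) == length(popmap))
  if (length(unique(popmap)) < 2L) stop("need at least 2 populations")
  grp_of_pop <- groups[unique(popmap)]
  if (anyNA(grp_of_pop)) stop("groups must partition the populations")
  comp <- .amova_components(dist, popmap, groups)
  obs <- comp
  total <- comp$sigma_a + comp$sigma_b + comp$sigma_c
  if (abs(total) < 1e-15) {
    return(list(sigma_a = 0, sigma_b = 0, sigma_c = 0,
                phi_ct = 0, phi_sc = 0, phi_st = 0,
                p_ct = NA_real_, p_sc = NA_real_, p_st = NA_real_,
                degenerate = TRUE))
  }
  cnt <- c(ct = 0L, sc = 0L, st = 0L)
  .with_seed(seed, {
    pops <- unique(popmap)
    grp_vec <- as.character(groups[popmap])
    for (b in seq_len(n_perm)) {
      # Phi_ST: permute sequences among populations across groups
      perm <- sample(length(popmap))
      st <- .amova_components(dist, popmap[perm], groups)
      if (st$phi_st >= obs$phi_st - 1e-12) cnt[["st"]] <- cnt[["st"]] + 1L
      # Phi_SC: permute sequences among populations within groups
      pm_sc <- popmap
      for (g in unique(grp_vec)) {
        idx <- which(grp_vec == g)
        pm_sc[idx] <- popmap[idx][sample(length(idx))]
      }
      sc <- .amova_components(dist, pm_sc, groups)
      if (sc$phi_sc >= obs$phi_sc - 1e-12) cnt[["sc"]] <- cnt[["sc"]] + 1L
      # Phi_CT: permute whole populations among groups
      g_perm <- setNames(sample(as.character(groups[pops])), pops)
      ct <- .amova_components(dist, popmap, g_perm)
      if (ct$phi_ct >= obs$phi_ct - 1e-12) cnt[["ct"]] <- cnt[["ct"]] + 1L
    }
  })
  p <- (1 + cnt) / (1 + n_perm)
  list(sigma_a = comp$sigma_a, sigma_b = comp$sigma_b,
       sigma_c = comp$sigma_c,
       phi_ct = comp$phi_ct, phi_sc = comp$phi_sc, phi_st = comp$phi_st,
       p_ct = unname(p[["ct"]]), p_sc = unname(p[["sc"]]),
       p_st = unname(p[["st"]]), degenerate = FALSE)
}

.amova_components <- function(dist, popmap, groups) {
  pops <- unique(popmap)
  grp_vec <- as.character(groups[popmap])
  grps <- unique(grp_vec)
  N <- length(popmap); P <- length(pops); G <- length(grps)
  ssd <- function(idx) {
    if (length(idx) < 2L) return(0)
    sub <- dist[idx, idx, drop = FALSE]
    sum(sub[upper.tri(sub)]) / length(idx)
  }
  ssd_t <- ssd(seq_len(N))
  ssd_wp <- sum(vapply(pops, function(p) ssd(which(popmap == p)), 0))
  ssd_wg <- sum(vapply(grps, function(g) ssd(which(grp_vec == g)), 0))
  ssd_ap <- ssd_wg - ssd_wp
  ssd_ag <- ssd_t - ssd_wg
  n_p <- vapply(pops, function(p) sum(popmap == p), 0L)
  n_g <- vapply(grps, function(g) sum(grp_vec == g), 0L)
  grp_of_pop <- as.character(groups[pops])
  df_wp <- N - P
  df_ap <- P - G
  df_ag <- G - 1L
  sigma_c <- if (df_wp > 0) ssd_wp / df_wp else 0
  sum_np2_over_ng <- sum(vapply(grps, function(g) {
    idx <- grp_of_pop == g
    sum(n_p[idx]^2) / sum(n_p[idx])
  }, 0))
  n1 <- if (df_ap > 0) (N - sum_np2_over_ng) / df_ap else 0
  sigma_b <- if (df_ap > 0 && n1 > 0)
    (ssd_ap / df_ap - sigma_c) / n1 else 0
  n2 <- if (df_ag > 0) (sum_np2_over_ng - sum(n_p^2) / N) / df_ag else 0
  n3 <- if (df_ag > 0) (N - sum(n_g^2) / N) / df_ag else 0
  sigma_a <- if (df_ag > 0 && n3 > 0)
    (ssd_ag / df_ag - sigma_c - n2 * sigma_b) / n3 else 0
  tot <- sigma_a + sigma_b + sigma_c
  list(sigma_a = sigma_a, sigma_b = sigma_b, sigma_c = sigma_c,
       phi_ct = if (tot != 0) sigma_a / tot else 0,
       phi_sc = if ((sigma_b + sigma_c) != 0)
         sigma_b / (sigma_b + sigma_c) else 0,
       phi_st = if (tot != 0) (sigma_a + sigma_b) / tot else 0)
}

#' Equal-variance pooled two-sample t comparison
#'
#' @param groupA,groupB numeric vectors (each length >= 2).
#' @return list with `t`, `df` (= nA + nB - 2) and one-sided P
#'   (upper tail for mean(A) > mean(B)).
#' @export
pooledT <- function(groupA, groupB) {
  nA <- length(groupA); nB <- length(groupB)
  if (nA < 2L || nB < 2L) stop("each group needs at least 2 values")
  sp2 <- ((nA - 1) * var(groupA) + (nB - 1) * var(groupB)) / (nA + nB - 2)
  if (sp2 <= 0) stop("zero pooled variance")
  t <- (mean(groupA) - mean(groupB)) / sqrt(sp2 * (1 / nA + 1 / nB))
  df <- nA + nB - 2L
  list(t = t, df = df, p_one_sided = stats::pt(t, df, lower.tail = FALSE))
}
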