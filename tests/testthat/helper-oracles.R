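# Shared fixtures and independent oracles used across the test files.
# Every fixture is built in code; oracles deliberately take a different
# computational route than the implementation they check.

# Small GenotypeDataset from a loci x samples matrix.
make_ds <- function(gt, populations, chrom = NULL, pos = NULL,
                    groups = NULL) {
  nl <- nrow(gt)
  if (is.null(chrom)) chrom <- rep("chr1", nl)
  if (is.null(pos)) pos <- seq_len(nl) * 1000L
  if (is.null(rownames(gt))) rownames(gt) <- sprintf("L%03d", seq_len(nl))
  if (is.null(colnames(gt))) colnames(gt) <- sprintf("S%03d", seq_len(ncol(gt)))
  if (is.null(names(populations))) names(populations) <- colnames(gt)
  loci <- data.frame(locus_id = rownames(gt), chrom = chrom, pos = pos,
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
  GenotypeDataset(gt, loci, populations, groups)
}

# Random HWE genotype table: r populations, n diploids each, independent
# allele frequencies.
random_pop_table <- function(r = 3, n = 10, seed = 1) {
  set.seed(seed)
  p <- runif(r, 0.05, 0.95)
  lapply(seq_len(r), function(i) rbinom(n, 2, p[[i]]))
}

# Weir-Cockerham components via the nested-ANOVA mean-squares route
# (per-individual sums of squares), an independent transcription of the
# estimator.
oracle_wc_anova <- function(geno_list) {
  r <- length(geno_list)
  n_i <- vapply(geno_list, length, 0L)
  N <- sum(n_i)
  p_i <- vapply(geno_list, function(g) mean(g) / 2, 0)
  pbar <- sum(n_i * p_i) / N
  SSG <- sum(vapply(geno_list, function(g) sum(g == 1L), 0)) / 2
  SSI <- 0
  for (i in seq_len(r))
    SSI <- SSI + sum(2 * (geno_list[[i]] / 2 - p_i[[i]])^2)
  SSP <- sum(2 * n_i * (p_i - pbar)^2)
  MSG <- SSG / N
  MSI <- SSI / (N - r)
  MSP <- SSP / (r - 1)
  nc <- (N - sum(n_i^2) / N) / (r - 1)
  a <- (MSP - MSI) / (2 * nc)
  b <- (MSI - MSG) / 2
  c <- MSG
  list(a = a, b = b, c = c, theta = a / (a + b + c))
}

# Maximum-likelihood two-locus haplotype frequency by grid search over
# the admissible p_AB range, refined once; likelihood evaluated from the
# 3x3 genotype count table.
oracle_r2_grid <- function(gA, gB) {
  ok <- !is.na(gA) & !is.na(gB)
  gA <- gA[ok]; gB <- gB[ok]
  cnt <- table(factor(gA, 0:2), factor(gB, 0:2))
  pA <- mean(gA) / 2; pB <- mean(gB) / 2
  loglik <- function(p11) {
    p10 <- pA - p11; p01 <- pB - p11; p00 <- 1 - pA - pB + p11
    if (min(p10, p01, p00) < -1e-12) return(-Inf)
    p10 <- max(p10, 0); p01 <- max(p01, 0); p00 <- max(p00, 0)
    probs <- rbind(c(p00^2, 2 * p00 * p01, p01^2),
                   c(2 * p00 * p10,
                     2 * p11 * p00 + 2 * p10 * p01,
                     2 * p01 * p11),
                   c(p10^2, 2 * p10 * p11, p11^2))
    if (any(probs[cnt > 0] <= 0)) return(-Inf)
    sum(cnt[cnt > 0] * log(probs[cnt > 0]))
  }
  lo <- max(0, pA + pB - 1); hi <- min(pA, pB)
  grid <- seq(lo, hi, length.out = 2001)
  best <- grid[[which.max(vapply(grid, loglik, 0))]]
  step <- (hi - lo) / 2000
  grid2 <- seq(max(lo, best - step), min(hi, best + step),
               length.out = 2001)
  best <- grid2[[which.max(vapply(grid2, loglik, 0))]]
  step <- step / 1000
  grid3 <- seq(max(lo, best - step), min(hi, best + step),
               length.out = 2001)
  best <- grid3[[which.max(vapply(grid3, loglik, 0))]]
  D <- best - pA * pB
  c(r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)), D = D)
}

# Full AMOVA variance components from the brute-force sums of squares,
# with the design coefficients computed independently.
oracle_amova_components <- function(dist2, popmap, grp_of_pop) {
  ss <- oracle_amova_ss(dist2, popmap, grp_of_pop)
  pops <- unique(popmap)
  grp <- as.character(grp_of_pop[popmap])
  grps <- unique(grp)
  N <- length(popmap); P <- length(pops); G <- length(grps)
  n_p <- vapply(pops, function(p) sum(popmap == p), 0)
  n_g <- vapply(grps, function(g) sum(grp == g), 0)
  sigma_c <- ss$within_pop / (N - P)
  grp_of <- as.character(grp_of_pop[pops])
  s_npg <- 0
  for (g in grps) s_npg <- s_npg + sum(n_p[grp_of == g]^2) / sum(n_p[grp_of == g])
  sigma_b <- if (P > G) {
    nn1 <- (N - s_npg) / (P - G)
    ((ss$within_grp - ss$within_pop) / (P - G) - sigma_c) / nn1
  } else 0
  nn2 <- (s_npg - sum(n_p^2) / N) / (G - 1)
  nn3 <- (N - sum(n_g^2) / N) / (G - 1)
  sigma_a <- ((ss$total - ss$within_grp) / (G - 1) - sigma_c -
                nn2 * sigma_b) / nn3
  list(sigma_a = sigma_a, sigma_b = sigma_b, sigma_c = sigma_c)
}

# AMOVA sums of squares by explicit loops over the distance matrix.
oracle_amova_ss <- function(dist2, popmap, grp_of_pop) {
  N <- nrow(dist2)
  ssd_of <- function(idx) {
    if (length(idx) < 2) return(0)
    s <- 0
    for (a in idx) for (b in idx) s <- s + dist2[a, b]
    s / (2 * length(idx))
  }
  pops <- unique(popmap)
  grp <- as.character(grp_of_pop[popmap])
  list(total = ssd_of(seq_len(N)),
       within_pop = sum(vapply(pops, function(p)
         ssd_of(which(popmap == p)), 0)),
       within_grp = sum(vapply(unique(grp), function(g)
         ssd_of(which(grp == g)), 0)))
}

# Exact heterozygote-count distribution under random pairing of the
# allele pool: every placement of the nA minor copies among the 2n slots
# is equally likely, and consecutive slots form individuals. Independent
# of the closed-form conditional distribution used by the implementation.
oracle_levene_exact <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  nA <- n1 + 2L * n2
  placements <- combn(2L * n, nA)
  hets <- apply(placements, 2, function(idx) {
    x <- integer(2L * n); x[idx] <- 1L
    sum(x[seq(1, 2 * n, 2)] != x[seq(2, 2 * n, 2)])
  })
  table(factor(hets, levels = 0:n)) / ncol(placements)
}

# Two-sided exact P from the enumerated distribution.
oracle_hwe_p <- function(n0, n1, n2) {
  dist <- oracle_levene_exact(n0, n1, n2)
  p_obs <- dist[[as.character(n1)]]
  sum(dist[dist <= p_obs + 1e-12])
}

# p-distance between two character strings.
pdist <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  mean(av != bv)
}
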