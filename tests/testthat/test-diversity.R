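# Heterozygosity, Hardy-Weinberg exact tests, mtDNA summaries, TN93,
# AMOVA and the pooled t comparison.

test_that("unbiased expected heterozygosity matches the closed form", {
  # n = 10 diploids, allele counts 12/8 -> (20/19)(1 - .6^2 - .4^2)
  gt <- rbind(c(2L, 2L, 2L, 2L, 2L, 1L, 1L, 0L, 0L, 0L),
              rep(0L, 10))
  ds <- make_ds(gt, setNames(rep("A", 10), sprintf("S%03d", 1:10)))
  expect_equal(expectedHet(ds, "A", "L001"), (20 / 19) * (1 - 0.36 - 0.16),
               tolerance = 1e-12)
  expect_equal(expectedHet(ds, "A", "L002"), 0)
  # p = 0.5 -> (20/19) * 0.5
  gt2 <- rbind(rep(1L, 10))
  ds2 <- make_ds(gt2, setNames(rep("A", 10), sprintf("S%03d", 1:10)))
  expect_equal(expectedHet(ds2, "A", "L001"), 0.5263158, tolerance = 1e-6)
})

test_that("HWE exact P-values agree with the Levene pairing distribution", {
  dsf <- function(n0, n1, n2) {
    g <- c(rep(0L, n0), rep(1L, n1), rep(2L, n2))
    make_ds(matrix(g, nrow = 1), setNames(rep("A", length(g)),
                                          sprintf("S%03d", seq_along(g))))
  }
  # monomorphic -> 1
  expect_equal(hweExactTest(dsf(6, 0, 0), "A", "L001"), 1)
  # mode of the distribution -> 1
  expect_equal(hweExactTest(dsf(1, 2, 1), "A", "L001"), 1)
  # exact enumeration oracle over all allele placements
  for (cnt in list(c(3, 0, 3), c(2, 4, 2), c(5, 1, 4), c(4, 2, 0))) {
    got <- hweExactTest(dsf(cnt[1], cnt[2], cnt[3]), "A", "L001")
    expect_equal(got, oracle_hwe_p(cnt[1], cnt[2], cnt[3]),
                 tolerance = 1e-10)
  }
})

test_that("HWE summary counts polymorphic tests and the chance expectation", {
  set.seed(5)
  gt <- t(replicate(40, rbinom(30, 2, runif(1, 0.1, 0.9))))
  pops <- setNames(rep(c("A", "B"), each = 15), sprintf("S%03d", 1:30))
  ds <- make_ds(gt, pops)
  hw <- hweSummary(ds, alpha = 0.05)
  expect_equal(hw$n_expected, round(0.05 * hw$n_tests))
  expect_equal(hweSummary(ds, alpha = 0)$n_expected, 0)
  # exact conditional tests are valid (super-uniform): rejections do not
  # exceed the upper 99% binomial bound at alpha = 0.05
  expect_lte(hw$n_significant, qbinom(0.995, hw$n_tests, 0.05))
  expect_true(all(hw$pvalues > 0 & hw$pvalues <= 1))
})

test_that("haplotype statistics match direct pairwise counting", {
  aln <- HaplotypeAlignment(
    c(h1 = "AAAAAAAAAA", h2 = "AAAAAAAAAA"),
    c(h1 = "P", h2 = "P"))
  s <- haplotypeStats(aln, "P")
  expect_equal(unlist(s[c("S", "h", "pi")]), c(S = 0, h = 0, pi = 0))

  a2 <- HaplotypeAlignment(
    c(h1 = paste(rep("A", 100), collapse = ""),
      h2 = paste(c(rep("A", 99), "G"), collapse = "")),
    c(h1 = "P", h2 = "P"))
  s2 <- haplotypeStats(a2, "P")
  expect_equal(unlist(s2[c("S", "h", "pi")]), c(S = 1, h = 1, pi = 0.01))

  # seeded simulated clade vs direct pairwise-count oracle
  aln3 <- simulateMtdna(n_clades = 1, seqs_per_clade = 5, seq_length = 300,
                        within_clade_theta = 0.02, seed = 9)
  s3 <- haplotypeStats(aln3, "clade1")
  seqs <- as.character(alnSequences(aln3))
  difs <- combn(5, 2, function(ij) pdist(seqs[[ij[1]]], seqs[[ij[2]]]))
  expect_equal(s3$pi, mean(difs), tolerance = 1e-12)
  m <- do.call(rbind, strsplit(seqs, ""))
  expect_equal(s3$S, sum(apply(m, 2, function(x) length(unique(x)) > 1)))
  expect_error(haplotypeStats(aln3, "nope"), "at least 2")
})

test_that("gap and N columns are excluded by complete deletion", {
  aln <- HaplotypeAlignment(
    c(h1 = "AAN-AAAAAA", h2 = "AGNAAAAAAA", h3 = "AGN-AAAAAT"),
    setNames(rep("P", 3), c("h1", "h2", "h3")))
  s <- haplotypeStats(aln, "P")
  # columns 3 and 4 dropped; S counts columns 2 and 10
  expect_equal(s$S, 2)
  expect_equal(s$pi, mean(c(1, 2, 1) / 8))
})

test_that("TN93 distance agrees with the reference implementation", {
  skip_if_not_installed("ape")
  expect_equal(tn93Distance("ACGT", "ACGT",
                            c(A = .25, C = .25, G = .25, T = .25)), 0)
  set.seed(13)
  for (rep in 1:20) {
    L <- 600
    a <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                prob = c(.3, .2, .2, .3))
    b <- a
    mut <- sample(L, 45)
    b[mut] <- vapply(a[mut], function(x) {
      ts <- c(A = "G", G = "A", C = "T", T = "C")[[x]]
      if (runif(1) < 0.8) ts else sample(setdiff(c("A","C","G","T"),
                                                 c(x, ts)), 1)
    }, "")
    bin <- ape::as.DNAbin(rbind(a = a, b = b))
    ref <- as.numeric(ape::dist.dna(bin, model = "TN93"))
    tab <- table(factor(c(a, b), levels = c("A", "C", "G", "T")))
    freqs <- as.numeric(tab) / sum(tab)
    names(freqs) <- c("A", "C", "G", "T")
    got <- tn93Distance(paste(a, collapse = ""), paste(b, collapse = ""),
                        freqs)
    expect_equal(got, ref, tolerance = 1e-8)
  }
})

test_that("TN93 exceeds p-distance and errors at saturation", {
  set.seed(4)
  L <- 400
  a <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  b <- a
  mut <- sample(L, 60)
  b[mut] <- vapply(a[mut], function(x)
    sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
  freqs <- setNames(rep(0.25, 4), c("A", "C", "G", "T"))
  sa <- paste(a, collapse = ""); sb <- paste(b, collapse = "")
  expect_gte(tn93Distance(sa, sb, freqs), pdist(sa, sb))
  # saturated pair
  c2 <- vapply(a, function(x) c(A = "G", G = "A", C = "T", T = "C")[[x]], "")
  expect_error(tn93Distance(sa, paste(c2, collapse = ""), freqs),
               "saturation")
})

test_that("net divergence subtracts within-population diversity", {
  aln <- HaplotypeAlignment(
    c(x1 = paste(rep("A", 100), collapse = ""),
      x2 = paste(rep("A", 100), collapse = ""),
      y1 = paste(c(rep("A", 95), rep("G", 5)), collapse = ""),
      y2 = paste(c(rep("A", 95), rep("G", 5)), collapse = "")),
    c(x1 = "X", x2 = "X", y1 = "Y", y2 = "Y"))
  expect_equal(netDivergence(aln, "X", "Y"), 0.05)
  expect_equal(netDivergence(aln, "X", "X"), 0)
})

test_that("AMOVA components equal the brute-force decomposition", {
  # 3 populations (2 groups), 6 sequences, arbitrary squared distances
  set.seed(2)
  d <- matrix(0, 6, 6)
  d[upper.tri(d)] <- runif(15, 0, 4)
  d <- d + t(d)
  popmap <- c("P1", "P1", "P2", "P2", "P3", "P3")
  groups <- c(P1 = "G1", P2 = "G1", P3 = "G2")
  res <- amova(d, popmap, groups, n_perm = 99, seed = 1)
  ss <- oracle_amova_ss(d, popmap, groups)
  N <- 6; P <- 3; G <- 2
  sigma_c <- ss$within_pop / (N - P)
  expect_equal(res$sigma_c, sigma_c, tolerance = 1e-12)
  # components reconstruct the SSDs through their defining identities
  ssd_ap <- ss$within_grp - ss$within_pop
  ssd_ag <- ss$total - ss$within_grp
  n_p <- c(2, 2, 2); n_g <- c(4, 2)
  sum_np2_over_ng <- (2^2 + 2^2) / 4 + (2^2) / 2
  nn1 <- (N - sum_np2_over_ng) / (P - G)
  sigma_b <- (ssd_ap / (P - G) - sigma_c) / nn1
  expect_equal(res$sigma_b, sigma_b, tolerance = 1e-12)
  nn2 <- (sum_np2_over_ng - sum(n_p^2) / N) / (G - 1)
  nn3 <- (N - sum(n_g^2) / N) / (G - 1)
  sigma_a <- (ssd_ag / (G - 1) - sigma_c - nn2 * sigma_b) / nn3
  expect_equal(res$sigma_a, sigma_a, tolerance = 1e-12)
  expect_equal(res$phi_st, (sigma_a + sigma_b) /
                 (sigma_a + sigma_b + sigma_c), tolerance = 1e-12)
})

test_that("AMOVA degenerate and fixed-haplotype limits behave", {
  d0 <- matrix(0, 4, 4)
  res <- amova(d0, c("P1", "P1", "P2", "P2"), c(P1 = "G", P2 = "G"),
               n_perm = 19, seed = 1)
  expect_true(res$degenerate)
  expect_equal(res$phi_st, 0)
  # two populations fixed for haplotypes at distance d -> Phi_ST = 1
  d1 <- matrix(0, 4, 4)
  d1[1:2, 3:4] <- 1; d1[3:4, 1:2] <- 1
  res1 <- amova(d1, c("P1", "P1", "P2", "P2"), c(P1 = "G", P2 = "G"),
                n_perm = 99, seed = 1)
  expect_equal(res1$phi_st, 1, tolerance = 1e-12)
})

test_that("pooled t reproduces the published lab vs wild comparison", {
  lab <- c(0.142, 0.027, 0.235)
  wild <- c(0.154, 0.060, 0.223, 0.226, 0.224, 0.253, 0.272, 0.219,
            0.215, 0.068)
  res <- pooledT(wild, lab)
  expect_equal(res$df, 11)
  expect_equal(round(abs(res$t), 2), 1.08)
  expect_equal(pooledT(c(1, 2, 3), c(1, 2, 3))$t, 0)
  # closed-form check on a tiny case
  r <- pooledT(c(0, 2), c(1, 3))
  sp2 <- (2 + 2) / 2
  expect_equal(r$t, (1 - 2) / sqrt(sp2 * (1 / 2 + 1 / 2)), tolerance = 1e-12)
  expect_error(pooledT(c(1, 1), c(1, 1)), "variance")
})
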