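# Structured-coalescent engine, calibration, null tables and outlier
# classification.

two_deme_cfg <- function(n_sims = 100, M2 = 1, copies = c(20L, 20L),
                         seed = 1) {
  fdistConfig(n_groups = 2, demes_per_group = 1, n_sims = n_sims,
              sample_layout = data.frame(group = c(1, 2), deme = c(1, 1),
                                         copies = copies),
              M1 = 0, M2 = M2, seed = seed)
}

test_that("two gene copies yield one derived and one ancestral allele", {
  cfg <- fdistConfig(n_groups = 1, demes_per_group = 1, n_sims = 1,
                     sample_layout = data.frame(group = 1, deme = 1,
                                                copies = 2L),
                     M1 = 0, M2 = 0, seed = 3)
  for (s in 1:10) expect_equal(sum(coalesceLocus(cfg, seed = s)), 1)
})

test_that("panmictic site-frequency spectrum matches an independent oracle", {
  # Single deme, 20 gene copies, one mutation per genealogy. The derived
  # count i is close to the 1/i law, but exactly follows E[L_i / L_tot]
  # (the single mutation conditions on each tree's own branch lengths,
  # overweighting short trees' external branches). The oracle is a pure-R
  # Kingman coalescent with the same one-mutation rule.
  n <- 20L; reps <- 8000L
  cfg <- fdistConfig(n_groups = 1, demes_per_group = 1, n_sims = reps,
                     sample_layout = data.frame(group = 1, deme = 1,
                                                copies = n),
                     M1 = 0, M2 = 0, seed = 5)
  sim <- zfpopgen:::.with_seed(5, zfpopgen:::.run_engine(cfg, reps))
  counts <- rowSums(sim$derived)
  expect_true(all(counts >= 1 & counts <= n - 1))
  obs <- tabulate(counts, n - 1L)

  set.seed(99)
  oracle <- vapply(seq_len(reps), function(i) {
    sizes <- rep(1L, n); birth <- rep(0, n)
    lens <- numeric(0); lsizes <- integer(0)
    k <- n; tt <- 0
    while (k > 1) {
      tt <- tt + rexp(1, k * (k - 1) / 2)
      pair <- sample.int(k, 2)
      lens <- c(lens, tt - birth[pair])
      lsizes <- c(lsizes, sizes[pair])
      sizes <- c(sizes[-pair], sum(sizes[pair]))
      birth <- c(birth[-pair], tt)
      k <- k - 1L
    }
    lsizes[[sample.int(length(lens), 1, prob = lens)]]
  }, 0L)
  exp_tab <- tabulate(oracle, n - 1L)
  # two-sample chi-square homogeneity between engine and oracle spectra
  pooled <- (obs + exp_tab) / 2
  chi2 <- sum((obs - pooled)^2 / pooled) + sum((exp_tab - pooled)^2 / pooled)
  expect_lt(chi2, qchisq(0.999, df = n - 2L))
  # and the classical 1/i shape holds to first order
  frac <- obs / reps
  law <- (1 / seq_len(n - 1L)) / sum(1 / seq_len(n - 1L))
  expect_lt(sum(abs(frac - law)) / 2, 0.05)
})

test_that("isolation between groups drives theta towards one", {
  cfg <- two_deme_cfg(n_sims = 300, M2 = 0.01, seed = 9)
  nt <- simulateNull(cfg)
  expect_gt(mean(nt@fst, na.rm = TRUE), 0.8)
})

test_that("strong migration drives theta to zero", {
  cfg <- two_deme_cfg(n_sims = 500, M2 = 100, seed = 11)
  nt <- simulateNull(cfg)
  expect_lt(abs(mean(nt@fst, na.rm = TRUE)), 0.02)
  # 99% per-locus theta quantile near zero when many demes are sampled
  # deeply under near-panmixia
  lay <- data.frame(group = 1:20, deme = 1, copies = 150L)
  cfg2 <- fdistConfig(n_groups = 20, demes_per_group = 1, n_sims = 600,
                      sample_layout = lay, M1 = 0, M2 = 100, seed = 12)
  nt2 <- simulateNull(cfg2)
  expect_lt(quantile(nt2@fst, 0.99, na.rm = TRUE), 0.05)
})

test_that("calibration reaches the target and is deterministic", {
  lay <- data.frame(group = 1:3, deme = c(1, 1, 1),
                    copies = c(20L, 20L, 20L))
  cfg <- fdistConfig(n_groups = 3, demes_per_group = 2, n_sims = 100,
                     sample_layout = lay, target_fst = 0.17, seed = 13)
  cal <- calibrateMigration(cfg, probe_loci = 300)
  expect_lte(abs(cal$achieved_fst - 0.17), 0.01)
  cal2 <- calibrateMigration(cfg, probe_loci = 300)
  expect_identical(cal[c("M1", "M2")], cal2[c("M1", "M2")])
  expect_equal(cal$M1 / cal$M2, 10, tolerance = 1e-9)
  # verification by independent re-simulation at the returned rates
  ver <- fdistConfig(n_groups = 3, demes_per_group = 2, n_sims = 2000,
                     sample_layout = lay, M1 = cal$M1, M2 = cal$M2,
                     seed = 99)
  sim <- zfpopgen:::.with_seed(99, zfpopgen:::.run_engine(ver, 2000))
  th <- zfpopgen:::.engine_theta_het(sim, lay$copies)
  nh <- sim$n_het; n0 <- sim$n_hom_ref; n2 <- sim$n_hom_alt
  n <- n0 + nh + n2
  comp <- zfpopgen:::.wc_components(n, (nh + 2 * n2) / (2 * n), nh / n)
  ok <- !is.na(comp$a)
  multi <- sum(comp$a[ok]) / sum((comp$a + comp$b + comp$c)[ok])
  expect_lt(abs(multi - 0.17), 0.035)
})

test_that("null table length, envelope shape and chain determinism", {
  cfg <- two_deme_cfg(n_sims = 10, M2 = 1, seed = 21)
  expect_equal(length(simulateNull(cfg)), 10)

  lay <- data.frame(group = c(1, 2, 3, 4, 4, 4, 4, 4, 5, 5),
                    deme = c(1, 1, 1, 1, 2, 3, 4, 5, 1, 2),
                    copies = rep(30L, 10))
  cfg2 <- fdistConfig(n_groups = 20, demes_per_group = 100, n_sims = 4000,
                      sample_layout = lay, M1 = 4.76, M2 = 0.476,
                      seed = 23)
  nt <- simulateNull(cfg2)
  # envelope is wider at low heterozygosity than near het ~ 0.5
  env <- nullEnvelope(nt, at = c(0.15, 0.48), probs = c(0.01, 0.99))
  expect_gt(diff(env[1, ]), diff(env[2, ]))
  expect_gt(env[1, 2], env[2, 2])
  # determinism of the whole chain
  obs <- data.frame(locus_id = "x", theta = 0.4, het = 0.3)
  c1 <- classifyOutliers(obs, simulateNull(cfg2, seed = 23))
  c2 <- classifyOutliers(obs, simulateNull(cfg2, seed = 23))
  expect_identical(c1, c2)
})

test_that("classification hits the forced tails and the het filter", {
  nt <- new("NullTable", het = runif(2000, 0.2, 0.5),
            fst = rnorm(2000, 0.2, 0.05),
            config = list(het_conditioning_k = 500L))
  obs <- data.frame(locus_id = c("hi", "mid", "filt"),
                    theta = c(0.5, 0.2, 0.99),
                    het = c(0.45, 0.35, 0.1))
  calls <- classifyOutliers(obs, nt)
  expect_identical(calls$class, c("high", "neutral", "filtered"))
  expect_equal(calls$p_high[[1]], 0)
  expect_identical(calls$class[calls$het_scaled <= 0.2], "filtered")
  # observed theta at the null median is neutral with p ~ 0.5
  expect_gt(calls$p_high[[2]], 0.2)
  expect_gt(calls$p_low[[2]], 0.2)
})

test_that("planted differentiation boost exceeds the neutral 99th percentile", {
  cfg <- simConfig(n_loci = 300, seed = 55, missing_rate = 0,
                   M1 = 5, M2 = 0.5, target_fst = NULL)
  sim <- simulateSnpDataset(cfg)
  lt <- lociTable(sim$dataset)
  sw <- sweepSpec(lt$chrom[[10]], lt$pos[[10]], favored_group = "G4",
                  radius = 1e5, intensity = 0.5,
                  differentiation_boost = TRUE)
  ps <- plantSweeps(sim$dataset, sim$truth, list(sw), seed = 6)
  obs <- fstHetObserved(ps$dataset)
  focal <- names(ps$truth$labels)[ps$truth$labels == "sweep_focal"]
  neutral <- obs$theta[obs$locus_id %in%
                         names(ps$truth$labels)[ps$truth$labels == "neutral"]]
  expect_gt(obs$theta[obs$locus_id == focal],
            quantile(neutral, 0.99, na.rm = TRUE))
})
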