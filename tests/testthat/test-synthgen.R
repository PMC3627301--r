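# Synthetic SNP dataset and mtDNA alignment generators.

test_that("the SNP simulator is deterministic and structured as configured", {
  cfg <- simConfig(n_loci = 80, M1 = 5, M2 = 0.5, target_fst = NULL,
                   seed = 2)
  s1 <- simulateSnpDataset(cfg)
  s2 <- simulateSnpDataset(cfg)
  expect_identical(genotypes(s1$dataset), genotypes(s2$dataset))
  expect_identical(lociTable(s1$dataset), lociTable(s2$dataset))
  expect_identical(s1$truth$realized_fst, s2$truth$realized_fst)
  expect_equal(nrow(s1$dataset), 80)
  expect_equal(length(unique(populations(s1$dataset))), 10)
  expect_setequal(unique(unname(populationGroups(s1$dataset))),
                  paste0("G", 1:5))
  expect_true(all(lociTable(s1$dataset)$pos >= 1))
  expect_lte(mean(is.na(genotypes(s1$dataset))), 0.05)
})

test_that("strong among-group migration approaches panmixia", {
  cfg <- simConfig(n_groups = 2, demes_per_group = 1,
                   sampled_pops = data.frame(
                     population = c("X", "Y"), group = c(1L, 2L),
                     deme = c(1L, 1L), n_individuals = c(20L, 20L)),
                   n_loci = 1000, M1 = 0, M2 = 100, target_fst = NULL,
                   missing_rate = 0, seed = 4)
  sim <- simulateSnpDataset(cfg)
  expect_lt(abs(sim$truth$realized_fst), 0.02)
})

test_that("isolated single-deme groups approach complete differentiation", {
  cfg <- simConfig(n_groups = 2, demes_per_group = 1,
                   sampled_pops = data.frame(
                     population = c("X", "Y"), group = c(1L, 2L),
                     deme = c(1L, 1L), n_individuals = c(15L, 15L)),
                   n_loci = 500, M1 = 0, M2 = 0.01, target_fst = NULL,
                   missing_rate = 0, seed = 6)
  sim <- simulateSnpDataset(cfg)
  expect_gt(sim$truth$realized_fst, 0.5)
})

test_that("calibrated datasets recover the target F_ST across seeds", {
  for (s in 1:5) {
    cfg <- simConfig(n_loci = 400, target_fst = 0.17, seed = 100 + s)
    sim <- simulateSnpDataset(cfg)
    expect_gte(sim$truth$realized_fst, 0.12)
    expect_lte(sim$truth$realized_fst, 0.22)
  }
})

test_that("sweep planting honours intensity limits and labels loci", {
  cfg <- simConfig(n_loci = 150, M1 = 5, M2 = 0.5, target_fst = NULL,
                   missing_rate = 0, seed = 8)
  sim <- simulateSnpDataset(cfg)
  lt <- lociTable(sim$dataset)
  chr <- lt$chrom[[1]]
  # an (effectively) zero-intensity sweep leaves the data unchanged
  sw0 <- sweepSpec(chr, 2e7, "G4", radius = 4e9, intensity = 1e-9)
  p0 <- plantSweeps(sim$dataset, sim$truth, list(sw0), seed = 2)
  expect_identical(genotypes(p0$dataset), genotypes(sim$dataset))

  # intensity 1 with a radius dwarfing the chromosome removes almost all
  # favored-group heterozygosity on it
  sw1 <- sweepSpec(chr, 2e7, "G4", radius = 4e9, intensity = 1)
  p1 <- plantSweeps(sim$dataset, sim$truth, list(sw1), seed = 2)
  fav <- names(populationGroups(sim$dataset))[
    populationGroups(sim$dataset) == "G4"]
  sel <- populations(sim$dataset) %in% fav
  on_chr <- lt$chrom == chr
  before <- sum(genotypes(sim$dataset)[on_chr, sel] == 1L, na.rm = TRUE)
  after <- sum(genotypes(p1$dataset)[on_chr, sel] == 1L, na.rm = TRUE)
  expect_lt(after, before * 0.2)
  expect_true(all(p1$truth$labels[lt$locus_id[on_chr]] == "sweep"))
  expect_true(all(p1$truth$labels[lt$locus_id[!on_chr]] == "neutral"))

  # sweep with no SNP in radius warns and is skipped
  expect_warning(plantSweeps(sim$dataset, sim$truth,
                             list(sweepSpec("chrZZ", 100, "G4")),
                             seed = 1),
                 "skipped")
})

test_that("mtDNA clades diverge by the Poisson-expected amount", {
  L <- 1122
  aln <- simulateMtdna(n_clades = 2, seqs_per_clade = 3, seq_length = L,
                       clade_net_divergence = 0.055,
                       within_clade_theta = 0, seed = 12)
  seqs <- as.character(alnSequences(aln))
  pops <- alnPopulations(aln)
  w1 <- combn(which(pops == "clade1"), 2, function(ij)
    pdist(seqs[[ij[1]]], seqs[[ij[2]]]))
  expect_true(all(w1 == 0))
  between <- mean(outer(which(pops == "clade1"), which(pops == "clade2"),
                        Vectorize(function(i, j)
                          pdist(seqs[[i]], seqs[[j]]))))
  lambda <- 0.055 * L # two stems of lambda/2 each
  expect_lt(abs(between * L - lambda), 3 * sqrt(lambda))
  expect_error(simulateMtdna(clade_net_divergence = 0.8), "saturated")
})

test_that("transition bias and base composition are realized", {
  aln <- simulateMtdna(n_clades = 3, seqs_per_clade = 8, seq_length = 2000,
                       clade_net_divergence = 0.06,
                       within_clade_theta = 0.01, ts_tv_ratio = 22,
                       at_content = 0.61, seed = 14)
  m <- do.call(rbind, strsplit(as.character(alnSequences(aln)), ""))
  at <- mean(m %in% c("A", "T"))
  expect_lt(abs(at - 0.61), 0.05)
  # classify segregating columns as transition or transversion
  ts <- tv <- 0
  for (j in seq_len(ncol(m))) {
    st <- unique(m[, j])
    if (length(st) == 2) {
      if (paste(sort(st), collapse = "") %in% c("AG", "CT")) ts <- ts + 1
      else tv <- tv + 1
    }
  }
  expect_gte(ts + tv, 200)
  ratio <- ts / max(tv, 1)
  expect_gt(ratio, 11)  # within +/-50% of 22
  expect_lt(ratio, 33)
  # infinite bias produces no transversions
  aln2 <- simulateMtdna(n_clades = 2, seqs_per_clade = 4,
                        seq_length = 1000, ts_tv_ratio = 1e9, seed = 15)
  m2 <- do.call(rbind, strsplit(as.character(alnSequences(aln2)), ""))
  for (j in seq_len(ncol(m2))) {
    st <- sort(unique(m2[, j]))
    if (length(st) > 1)
      expect_true(paste(st, collapse = "") %in% c("AG", "CT"))
  }
})

test_that("within-clade diversity is recovered by the haplotype statistics", {
  theta <- 0.01
  aln <- simulateMtdna(n_clades = 3, seqs_per_clade = 10,
                       seq_length = 1122, within_clade_theta = theta,
                       seed = 16)
  pis <- vapply(paste0("clade", 1:3), function(p)
    haplotypeStats(aln, p)$pi, 0)
  expect_lt(abs(mean(pis) - theta) / theta, 0.3)
})

test_that("mean among-clade net divergence emulates the deep mtDNA split", {
  aln <- simulateMtdna(seed = 17)
  model <- distanceModel("p")
  das <- c(netDivergence(aln, "clade1", "clade2", model),
           netDivergence(aln, "clade1", "clade3", model),
           netDivergence(aln, "clade2", "clade3", model))
  expect_lt(abs(mean(das) - 0.055), 0.012)
})
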