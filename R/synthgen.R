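# Synthetic SNP datasets and mtDNA alignments with the statistical
# structure the analyses assume, plus ground truth for recovery tests.

# Default sampled populations: 10 wild zebrafish-style populations in 5
# groups (three singleton groups, one group of five, one group of two)
# with realistic per-population diploid sample sizes.
.default_sampled_pops <- function() {
  data.frame(
    population = c("PAR", "KHA", "CHT", "BER", "DHO", "JOR", "PGM",
                   "RCH", "PNS", "UTR"),
    group = c(1L, 2L, 3L, 4L, 4L, 4L, 4L, 4L, 5L, 5L),
    deme = c(1L, 1L, 1L, 1L, 2L, 3L, 4L, 5L, 1L, 2L),
    n_individuals = c(19L, 19L, 18L, 19L, 15L, 17L, 19L, 14L, 20L, 19L),
    stringsAsFactors = FALSE)
}

#' Configuration for the synthetic SNP dataset generator
#'
#' The defaults emulate a hierarchically structured wild metapopulation:
#' 20 groups of 100 demes, ten sampled populations in five groups,
#' 1832 biallelic SNPs on 25 chromosomes of 40 Mb, and migration rates
#' calibrated so the multilocus Weir-Cockerham theta is near 0.17.
#'
#' @param n_groups,demes_per_group metapopulation dimensions.
#' @param sampled_pops `data.frame` with columns `population`, `group`,
#'   `deme`, `n_individuals`.
#' @param n_loci number of simulated SNPs (default 1832).
#' @param chrom_lengths named integer vector of chromosome lengths in
#'   basepairs (default 25 chromosomes of 40 Mb).
#' @param M1,M2 scaled within-/among-group migration rates (used as-is
#'   when `target_fst` is NULL).
#' @param target_fst when set, [calibrateMigration()] adjusts M1/M2 so
#'   the realized multilocus theta matches (default 0.17).
#' @param missing_rate independent genotype missingness (default 0.02).
#' @param seed integer seed.
#' @return a list of class `sim_config`.
#' @export
simConfig <- function(n_groups = 20L, demes_per_group = 100L,
                      sampled_pops = .default_sampled_pops(),
                      n_loci = 1832L,
                      chrom_lengths = setNames(rep(40e6, 25),
                                               paste0("chr", 1:25)),
                      M1 = NULL, M2 = NULL, target_fst = 0.17,
                      missing_rate = 0.02, seed = 1L) {
  stopifnot(n_loci >= 1L, missing_rate >= 0, missing_rate < 1)
  if (is.null(M2) && is.null(target_fst))
    stop("either migration rates or target_fst must be given")
  structure(list(n_groups = as.integer(n_groups),
                 demes_per_group = as.integer(demes_per_group),
                 sampled_pops = sampled_pops, n_loci = as.integer(n_loci),
                 chrom_lengths = chrom_lengths,
                 M1 = M1, M2 = M2, target_fst = target_fst,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_config")
}

.fdist_cfg_from_sim <- function(cfg, n_sims = 1L) {
  fdistConfig(n_groups = cfg$n_groups,
              demes_per_group = cfg$demes_per_group,
              n_sims = n_sims,
              sample_layout = data.frame(
                population = cfg$sampled_pops$population,
                group = cfg$sampled_pops$group,
                deme = cfg$sampled_pops$deme,
                copies = 2L * cfg$sampled_pops$n_individuals),
              M1 = if (is.null(cfg$M1)) 1 else cfg$M1,
              M2 = if (is.null(cfg$M2)) 0.1 else cfg$M2,
              target_fst = cfg$target_fst, seed = cfg$seed)
}

#' Simulate a structured SNP dataset with ground truth
#'
#' Every locus is generated independently by one structured-coalescent
#' genealogy carrying a single mutation (the same engine as the outlier
#' null, see [coalesceLocus()]); gene copies are paired into diploids
#' within demes, positions are drawn uniformly over the chromosomes, and
#' genotypes are masked independently at the missing rate. With
#' `target_fst` set, migration rates are first calibrated.
#'
#' @param cfg a [simConfig()].
#' @return list with `dataset` (a [GenotypeDataset-class]) and `truth`
#'   (migration rates used, per-locus neutral/sweep labels, sweep specs,
#'   realized overall theta).
#' @export
simulateSnpDataset <- function(cfg) {
  fc <- .fdist_cfg_from_sim(cfg)
  if (!is.null(cfg$target_fst)) fc <- calibrateMigration(fc)
  seeds <- .child_seeds(cfg$seed, 3L)
  sim <- .with_seed(seeds[[1L]], .run_engine(fc, cfg$n_loci, TRUE))
  sp <- cfg$sampled_pops
  sample_ids <- unlist(lapply(seq_len(nrow(sp)), function(i)
    paste0(sp$population[[i]], "_", seq_len(sp$n_individuals[[i]]))))
  # engine emits individuals grouped by population in layout order
  pops <- setNames(rep(sp$population, sp$n_individuals), sample_ids)
  gt <- sim$genotypes # loci x individuals
  colnames(gt) <- sample_ids
  loci <- .with_seed(seeds[[2L]], {
    chrom <- sample(names(cfg$chrom_lengths), cfg$n_loci, replace = TRUE)
    pos <- floor(runif(cfg$n_loci, 1,
                       unname(cfg$chrom_lengths[chrom]) + 1))
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, cfg$n_loci, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
    data.frame(locus_id = sprintf("L%05d", seq_len(cfg$n_loci)),
               chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
               stringsAsFactors = FALSE)
  })
  if (cfg$missing_rate > 0)
    gt <- .with_seed(seeds[[3L]], {
      gt[runif(length(gt)) < cfg$missing_rate] <- NA_integer_
      gt
    })
  rownames(gt) <- loci$locus_id
  groups <- setNames(paste0("G", sp$group), sp$population)
  ds <- GenotypeDataset(gt, loci, pops, groups)
  comp <- .wc_dataset(ds)
  ok <- !is.na(comp$a)
  truth <- list(M1 = fc$M1, M2 = fc$M2,
                labels = setNames(rep("neutral", cfg$n_loci),
                                  loci$locus_id),
                sweeps = list(),
                realized_fst = sum(comp$a[ok]) /
                  sum((comp$a + comp$b + comp$c)[ok]))
  list(dataset = ds, truth = truth)
}

#' Specify a planted selective sweep
#'
#' @param chrom chromosome name.
#' @param pos sweep centre, basepairs.
#' @param favored_group group label (as in the dataset's groupmap) whose
#'   populations experienced the sweep.
#' @param radius reach of the sweep in basepairs (default 3 Mb); the
#'   diversity reduction decays linearly to zero at the radius.
#' @param intensity fraction in (0, 1]: proportion of heterozygous
#'   genotypes converted at distance zero.
#' @param differentiation_boost also force near-fixation of alternate
#'   alleles between the favored group and the rest at the SNP nearest
#'   the sweep centre.
#' @return a list of class `sweep_spec`.
#' @export
sweepSpec <- function(chrom, pos, favored_group, radius = 3e6,
                      intensity = 1, differentiation_boost = FALSE) {
  stopifnot(radius > 0, intensity > 0, intensity <= 1)
  structure(list(chrom = chrom, pos = pos, favored_group = favored_group,
                 radius = radius, intensity = intensity,
                 differentiation_boost = differentiation_boost),
            class = "sweep_spec")
}

#' Plant selective sweeps into a simulated dataset
#'
#' For each locus within a sweep's radius, a fraction
#' `intensity * (1 - distance/radius)` of the heterozygous genotypes in
#' each population of the favored group is set to the locally-majority
#' homozygote, depressing within-population heterozygosity around the
#' sweep centre while acting on genotypes (Hardy-Weinberg structure
#' stays testable). With `differentiation_boost`, the SNP nearest the
#' centre is recoded so favored-group populations are near-fixed for the
#' alternate allele and all others for the reference.
#'
#' @param ds a [GenotypeDataset-class].
#' @param truth the truth list from [simulateSnpDataset()].
#' @param sweeps list of [sweepSpec()]s.
#' @param seed integer seed.
#' @return list with the modified `dataset` and updated `truth`.
#' @export
plantSweeps <- function(ds, truth, sweeps, seed = 1L) {
  lt <- lociTable(ds)
  gt <- genotypes(ds)
  popv <- populations(ds)
  grp <- populationGroups(ds)
  .with_seed(seed, {
    for (sw in sweeps) {
      if (!sw$chrom %in% lt$chrom) {
        warning("sweep at ", sw$chrom, ":", sw$pos,
                " has no SNP within radius; skipped")
        next
      }
      d <- ifelse(lt$chrom == sw$chrom, abs(lt$pos - sw$pos), Inf)
      hit <- which(d < sw$radius)
      if (!length(hit)) {
        warning("sweep at ", sw$chrom, ":", sw$pos,
                " has no SNP within radius; skipped")
        next
      }
      fav_pops <- names(grp)[!is.na(grp) & grp == sw$favored_group]
      if (!length(fav_pops))
        stop("favored group ", sw$favored_group, " not in groupmap")
      for (l in hit) {
        R <- sw$intensity * (1 - d[[l]] / sw$radius)
        for (pp in fav_pops) {
          cols <- which(popv == pp)
          g <- gt[l, cols]
          het <- which(!is.na(g) & g == 1L)
          if (!length(het)) next
          n <- sum(!is.na(g))
          p_alt <- sum(g, na.rm = TRUE) / (2 * n)
          q <- min(p_alt, 1 - p_alt)
          if (q == 0) next
          # heterozygote-conversion fraction realizing a He reduction of
          # R at this locus: solve 2q'(1-q') = (1-R) * 2q(1-q) for the
          # post-sweep minor frequency, cap at exhausting the hets
          qp <- (1 - sqrt(max(0, 1 - 4 * (1 - R) * q * (1 - q)))) / 2
          m <- min(length(het), round(2 * n * (q - qp)))
          if (m < 1L) next
          conv <- sample(het, m)
          gt[l, cols[conv]] <- if (p_alt > 0.5) 2L else 0L
        }
        truth$labels[[lt$locus_id[[l]]]] <- "sweep"
      }
      if (sw$differentiation_boost) {
        focal <- hit[which.min(d[hit])]
        fav_cols <- popv %in% fav_pops
        n_fav <- sum(fav_cols); n_oth <- sum(!fav_cols)
        g <- gt[focal, ]
        keep_na <- is.na(g)
        alt_cnt <- rbinom(n_fav, 2L, 0.975)
        ref_cnt <- rbinom(n_oth, 2L, 0.025)
        g[fav_cols] <- alt_cnt
        g[!fav_cols] <- ref_cnt
        g[keep_na] <- NA_integer_
        gt[focal, ] <- g
        truth$labels[[lt$locus_id[[focal]]]] <- "sweep_focal"
      }
      truth$sweeps <- c(truth$sweeps, list(sw))
    }
  })
  out <- ds
  SummarizedExperiment::assay(out, "GT") <- gt
  list(dataset = out, truth = truth)
}

#' Copy a genotype column into its neighbours with noise
#'
#' Creates controllable linkage disequilibrium by replacing the genotype
#' columns of loci near a focal SNP with noisy copies of the focal
#' column: each copied genotype is independently replaced by a random
#' Hardy-Weinberg draw with probability `flip_prob` (a number, or a
#' function of distance in basepairs for distance-dependent decay).
#'
#' @param ds a [GenotypeDataset-class].
#' @param locus focal locus id.
#' @param max_dist neighbours within this distance are overwritten.
#' @param flip_prob noise level in [0, 1], or `function(dist_bp)`.
#' @param seed integer seed.
#' @return the modified [GenotypeDataset-class].
#' @export
blockCopyLoci <- function(ds, locus, max_dist = 5e6, flip_prob = 0.1,
                          seed = 1L) {
  lt <- lociTable(ds)
  gt <- genotypes(ds)
  li <- match(locus, lt$locus_id)
  if (is.na(li)) stop("locus ", locus, " not in dataset")
  d <- ifelse(lt$chrom == lt$chrom[[li]], abs(lt$pos - lt$pos[[li]]), Inf)
  nb <- setdiff(which(d <= max_dist), li)
  fp <- if (is.function(flip_prob)) flip_prob else function(x) flip_prob
  focal <- gt[li, ]
  p <- mean(focal, na.rm = TRUE) / 2
  .with_seed(seed, {
    for (j in nb) {
      g <- focal
      noise <- runif(length(g)) < fp(d[[j]])
      g[noise] <- rbinom(sum(noise), 2L, p)
      gt[j, ] <- g
    }
  })
  out <- ds
  SummarizedExperiment::assay(out, "GT") <- gt
  out
}

.transition <- c(A = "G", G = "A", C = "T", T = "C")
.transversions <- list(A = c("C", "T"), G = c("C", "T"),
                       C = c("A", "G"), T = c("A", "G"))

# Apply n substitutions to a base vector: site uniform, transition with
# odds ts_tv_ratio : 1, transversion target uniform among the two.
.mutate_seq <- function(x, n_sub, ts_tv_ratio) {
  if (n_sub == 0L) return(x)
  sites <- sample(length(x), n_sub, replace = TRUE)
  p_ts <- ts_tv_ratio / (ts_tv_ratio + 1)
  for (s in sites) {
    if (runif(1L) < p_ts) x[[s]] <- .transition[[x[[s]]]]
    else x[[s]] <- sample(.transversions[[x[[s]]]], 1L)
  }
  x
}

#' Simulate a clade-structured mitochondrial haplotype alignment
#'
#' Generates a root sequence at the given AT-rich base composition,
#' diverges each clade along its own stem by a Poisson number of
#' substitutions matching the net divergence, and adds within-clade
#' variation per sequence (star genealogy within clades). Substitutions
#' are transitions vs transversions at odds `ts_tv_ratio` : 1.
#'
#' @param n_clades number of clades (default 3).
#' @param seqs_per_clade sequences per clade (recycled; default 10).
#' @param seq_length alignment length in basepairs (default 1122).
#' @param clade_net_divergence expected net divergence between clades,
#'   substitutions per site (default 0.055).
#' @param within_clade_theta expected pairwise difference per site
#'   within clades (default 0.005).
#' @param ts_tv_ratio transition:transversion odds (default 22).
#' @param at_content total A+T fraction of the root (default 0.61).
#' @param seed integer seed.
#' @return a [HaplotypeAlignment-class] with populations
#'   `clade1..cladeN`.
#' @export
simulateMtdna <- function(n_clades = 3L, seqs_per_clade = 10L,
                          seq_length = 1122L,
                          clade_net_divergence = 0.055,
                          within_clade_theta = 0.005,
                          ts_tv_ratio = 22, at_content = 0.61,
                          seed = 1L) {
  if (clade_net_divergence >= 0.75)
    stop("divergence >= 0.75 is saturated")
  .assert_fraction(at_content, "at_content")
  seqs_per_clade <- rep_len(seqs_per_clade, n_clades)
  .with_seed(seed, {
    root <- sample(c("A", "T", "C", "G"), seq_length, replace = TRUE,
                   prob = c(at_content / 2, at_content / 2,
                            (1 - at_content) / 2, (1 - at_content) / 2))
    seqs <- character(0); pops <- character(0)
    for (k in seq_len(n_clades)) {
      stem <- .mutate_seq(root,
                          rpois(1L, clade_net_divergence * seq_length / 2),
                          ts_tv_ratio)
      for (s in seq_len(seqs_per_clade[[k]])) {
        tip <- .mutate_seq(stem,
                           rpois(1L, within_clade_theta * seq_length / 2),
                           ts_tv_ratio)
        seqs <- c(seqs, paste(tip, collapse = ""))
        pops <- c(pops, paste0("clade", k))
      }
    }
    names(seqs) <- paste0(pops, "_s", unlist(lapply(seqs_per_clade,
                                                    seq_len)))
    HaplotypeAlignment(seqs, setNames(pops, names(seqs)))
  })
}
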