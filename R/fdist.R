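# Hierarchical island-model coalescent null distribution and FDIST-style
# outlier classification.

#' Configuration for the hierarchical island-model null
#'
#' Describes the simulated metapopulation (groups of demes), the scaled
#' migration rates, and the sample layout: one sampled population per
#' deme, each with a number of gene copies (2 x diploids).
#'
#' @param n_groups number of simulated groups (default 20).
#' @param demes_per_group demes per group (default 100).
#' @param n_sims number of simulated loci for the null table
#'   (default 30000).
#' @param sample_layout `data.frame` with columns `group` (1-based group
#'   index), `deme` (1-based deme index within the group; at most one
#'   sampled population per deme) and `copies` (even gene-copy count).
#' @param M1 scaled within-group migration rate (2Nm).
#' @param M2 scaled among-group migration rate.
#' @param target_fst optional F_ST the rates should be calibrated to.
#' @param het_conditioning_k simulated loci nearest in heterozygosity
#'   used for the conditional P-value; default `NULL` = `n_sims / 30`
#'   capped at 1000 (1000 at the default 30000 simulations), keeping the
#'   conditioning neighbourhood a fixed fraction of the table so
#'   heterozygosity strata are not smeared on smaller tables.
#' @param seed integer seed.
#' @return a validated list of class `fdist_config`.
#' @export
fdistConfig <- function(n_groups = 20L, demes_per_group = 100L,
                        n_sims = 30000L, sample_layout,
                        M1 = 10, M2 = 1, target_fst = NULL,
                        het_conditioning_k = NULL, seed = 1L) {
  stopifnot(n_groups >= 1L, demes_per_group >= 1L, n_sims >= 1L,
            M1 >= 0, M2 >= 0)
  stopifnot(all(c("group", "deme", "copies") %in% names(sample_layout)))
  if (any(sample_layout$copies %% 2L != 0L))
    stop("gene-copy counts must be even")
  if (sum(sample_layout$copies) < 2L)
    stop("need at least 2 sampled gene copies")
  if (anyDuplicated(sample_layout[, c("group", "deme")]))
    stop("at most one sampled population per deme")
  if (any(sample_layout$group > n_groups |
          sample_layout$deme > demes_per_group))
    stop("sample layout exceeds the metapopulation dimensions")
  if (is.null(het_conditioning_k))
    het_conditioning_k <- min(1000L, ceiling(n_sims / 30))
  structure(list(n_groups = as.integer(n_groups),
                 demes_per_group = as.integer(demes_per_group),
                 n_sims = as.integer(n_sims),
                 sample_layout = sample_layout,
                 M1 = M1, M2 = M2, target_fst = target_fst,
                 het_conditioning_k = as.integer(het_conditioning_k),
                 seed = as.integer(seed)),
            class = "fdist_config")
}

#' Sample layout matching an observed dataset
#'
#' Places each observed population in its own simulated deme,
#' populations of the same empirical group in the same simulated group,
#' and sets gene-copy counts to the per-locus average number of usable
#' copies (rounded to an even count).
#'
#' @param ds a [GenotypeDataset-class] with a groupmap (populations
#'   without a group each form their own group).
#' @param pops populations to include (default: all).
#' @return a `sample_layout` data.frame for [fdistConfig()].
#' @export
layoutFromDataset <- function(ds, pops = NULL) {
  pc <- .pop_counts(ds, pops)
  grp <- populationGroups(ds)[pc$pops]
  grp[is.na(grp)] <- paste0(".solo.", which(is.na(grp)))
  gidx <- as.integer(factor(grp, levels = unique(grp)))
  deme <- integer(length(gidx))
  for (g in unique(gidx)) deme[gidx == g] <- seq_len(sum(gidx == g))
  copies <- 2L * pmax(1L, round(colMeans(pc$n)))
  data.frame(population = pc$pops, group = gidx, deme = deme,
             copies = as.integer(copies))
}

.run_engine <- function(cfg, n_loci, return_genotypes = FALSE) {
  lay <- cfg$sample_layout
  .sim_fdist_batch(as.integer(n_loci),
                   as.integer(lay$group - 1L),
                   as.integer((lay$group - 1L) * cfg$demes_per_group +
                                (lay$deme - 1L)),
                   as.integer(lay$copies),
                   cfg$n_groups, cfg$demes_per_group,
                   cfg$M1, cfg$M2, return_genotypes, 5e7)
}

#' Simulate one locus genealogy under the hierarchical island model
#'
#' Runs the structured coalescent (within-deme pairwise coalescence at
#' rate 1, within-group migration at rate M1/2, among-group migration at
#' rate M2/2 per lineage) to the most recent common ancestor and places
#' a single mutation uniformly on the genealogy, so the locus is always
#' polymorphic among the sampled gene copies.
#'
#' @param cfg an [fdistConfig()].
#' @param seed integer seed (default: `cfg$seed`).
#' @return integer vector of derived-allele copy counts per sampled
#'   deme/population.
#' @export
coalesceLocus <- function(cfg, seed = cfg$seed) {
  .with_seed(seed, drop(.run_engine(cfg, 1L)$derived))
}

# theta and total heterozygosity for engine output (count matrices).
.engine_theta_het <- function(sim, copies) {
  nh <- sim$n_het; n0 <- sim$n_hom_ref; n2 <- sim$n_hom_alt
  n <- n0 + nh + n2
  p <- (nh + 2 * n2) / (2 * n)
  h <- nh / n
  comp <- .wc_components(n, p, h)
  pooled <- rowSums(sim$derived) / sum(copies)
  list(theta = comp$theta, het = 2 * pooled * (1 - pooled))
}

#' Simulate the joint null distribution of heterozygosity and F_ST
#'
#' Draws `n_sims` independent loci with [coalesceLocus()]'s engine, pairs
#' gene copies into diploids within demes, and records for each locus the
#' total expected heterozygosity (from the pooled derived-allele
#' frequency) and the multi-deme Weir-Cockerham theta treating sampled
#' demes as populations.
#'
#' @param cfg an [fdistConfig()]; rates must be set (directly or via
#'   [calibrateMigration()]).
#' @param seed integer seed (default: `cfg$seed`).
#' @return a [NullTable-class].
#' @export
simulateNull <- function(cfg, seed = cfg$seed) {
  sim <- .with_seed(seed, .run_engine(cfg, cfg$n_sims))
  th <- .engine_theta_het(sim, cfg$sample_layout$copies)
  new("NullTable", het = th$het, fst = as.numeric(th$theta),
      config = unclass(cfg))
}

#' Calibrate migration rates to a target multilocus F_ST
#'
#' Holds the M1/M2 ratio fixed and bisects on M2 (log scale) until the
#' mean multilocus theta of `probe_loci` simulated loci is within `tol`
#' of `target_fst`. Probe batches reuse one derived seed (common random
#' numbers), so the bisection objective is monotone and the result
#' deterministic.
#'
#' @param cfg an [fdistConfig()].
#' @param target_fst desired multilocus theta, in (0, 0.9).
#' @param tol convergence tolerance (default 0.01).
#' @param probe_loci loci per probe batch (default 500).
#' @param max_iter bisection iterations (default 25).
#' @param ratio fixed M1/M2 ratio (default 10).
#' @return the input config with calibrated `M1`, `M2` and an
#'   `achieved_fst` entry.
#' @export
calibrateMigration <- function(cfg, target_fst = cfg$target_fst,
                               tol = 0.01, probe_loci = 500L,
                               max_iter = 25L, ratio = 10) {
  if (is.null(target_fst) || target_fst <= 0 || target_fst >= 0.9)
    stop("target_fst must lie in (0, 0.9)")
  probe_seed <- .child_seeds(cfg$seed, 1L)
  probe <- function(m2) {
    c2 <- cfg; c2$M2 <- m2; c2$M1 <- ratio * m2
    sim <- .with_seed(probe_seed, .run_engine(c2, probe_loci))
    nh <- sim$n_het; n0 <- sim$n_hom_ref; n2 <- sim$n_hom_alt
    n <- n0 + nh + n2
    comp <- .wc_components(n, (nh + 2 * n2) / (2 * n), nh / n)
    ok <- !is.na(comp$a)
    sum(comp$a[ok]) / sum((comp$a + comp$b + comp$c)[ok])
  }
  # theta is decreasing in M2; expand the bracket upward from small M2
  # (large M2 probes are the expensive ones: event count grows with M)
  lo <- 1e-4
  f_lo <- probe(lo)
  if (f_lo < target_fst)
    stop(sprintf("target F_ST %.3f above achievable maximum %.3f",
                 target_fst, f_lo))
  hi <- 0.05
  f_hi <- probe(hi)
  while (f_hi > target_fst) {
    lo <- hi; f_lo <- f_hi
    hi <- hi * 4
    if (hi > 400)
      stop(sprintf("target F_ST %.3f below achievable minimum %.3f",
                   target_fst, f_hi))
    f_hi <- probe(hi)
  }
  achieved <- NA_real_; m2 <- NA_real_
  for (it in seq_len(max_iter)) {
    m2 <- sqrt(lo * hi)
    achieved <- probe(m2)
    if (abs(achieved - target_fst) <= tol) break
    if (achieved > target_fst) lo <- m2 else hi <- m2
    if (it == max_iter)
      stop(sprintf(paste0("calibration did not converge in %d iterations; ",
                          "bracket M2 in [%.4g, %.4g], theta [%.3f, %.3f]"),
                   max_iter, lo, hi, probe(hi), probe(lo)))
  }
  cfg$M2 <- m2; cfg$M1 <- ratio * m2
  cfg$achieved_fst <- achieved
  cfg
}

#' Observed per-locus F_ST and heterozygosity for outlier classification
#'
#' @param ds a [GenotypeDataset-class].
#' @param pops populations treated as demes (default: all).
#' @return `data.frame` with `locus_id`, `theta`, `het` (total expected
#'   heterozygosity from the pooled allele frequency).
#' @export
fstHetObserved <- function(ds, pops = NULL) {
  pc <- .pop_counts(ds, pops)
  comp <- .wc_components(pc$n, pc$p, pc$h)
  pooled <- rowSums(pc$n * pc$p, na.rm = TRUE) /
    rowSums(pc$n * !is.na(pc$p))
  data.frame(locus_id = rownames(genotypes(ds)),
             theta = as.numeric(comp$theta),
             het = as.numeric(2 * pooled * (1 - pooled)),
             stringsAsFactors = FALSE)
}

#' Classify loci against the simulated null envelope
#'
#' For each observed locus, the conditional P-values are computed against
#' the `het_conditioning_k` simulated loci nearest in heterozygosity:
#' `p_high` is the fraction of those with simulated theta at or above the
#' observed value, `p_low` at or below. A locus is `"filtered"` when its
#' scaled heterozygosity (heterozygosity x (1 - theta), or / (1 - theta)
#' with `scaling = "divide"`) is at or below `het_min`; otherwise
#' `"high"`/`"low"` when the corresponding tail P is below `p_cut`, else
#' `"neutral"`.
#'
#' @param observed `data.frame` from [fstHetObserved()] (columns
#'   `locus_id`, `theta`, `het`).
#' @param null a [NullTable-class].
#' @param p_cut tail significance cutoff (default 0.01).
#' @param het_min scaled-heterozygosity floor (default 0.2).
#' @param k conditioning neighbourhood size (default: from the null's
#'   config).
#' @param scaling how heterozygosity is scaled by (1 - theta).
#' @return `data.frame` with `locus_id`, `theta`, `het`, `het_scaled`,
#'   `p_high`, `p_low`, `class`.
#' @export
classifyOutliers <- function(observed, null, p_cut = 0.01, het_min = 0.2,
                             k = NULL,
                             scaling = c("multiply", "divide")) {
  scaling <- match.arg(scaling)
  if (!length(null@het)) stop("null table is empty")
  if (is.null(k)) k <- null@config$het_conditioning_k
  k <- min(k, length(null@het))
  ord <- order(null@het)
  het_s <- null@het[ord]; fst_s <- null@fst[ord]
  n_sim <- length(het_s)
  p_high <- p_low <- rep(NA_real_, nrow(observed))
  for (i in seq_len(nrow(observed))) {
    ho <- observed$het[[i]]; to <- observed$theta[[i]]
    if (is.na(to) || is.na(ho)) next
    # window of the k nearest simulated loci in heterozygosity
    j <- findInterval(ho, het_s)
    lo <- max(1L, j - k); hi <- min(n_sim, j + k)
    idx <- seq.int(lo, hi)
    d <- abs(het_s[idx] - ho)
    sel <- idx[order(d)[seq_len(k)]]
    p_high[[i]] <- mean(fst_s[sel] >= to - 1e-12)
    p_low[[i]] <- mean(fst_s[sel] <= to + 1e-12)
  }
  het_scaled <- if (scaling == "multiply")
    observed$het * (1 - observed$theta)
  else observed$het / pmax(1e-12, 1 - observed$theta)
  class <- rep("neutral", nrow(observed))
  class[which(p_low < p_cut)] <- "low"
  class[which(p_high < p_cut)] <- "high"
  class[which(is.na(observed$theta))] <- NA_character_
  class[which(het_scaled <= het_min)] <- "filtered"
  data.frame(locus_id = observed$locus_id,
             theta = observed$theta, het = observed$het,
             het_scaled = het_scaled,
             p_high = p_high, p_low = p_low, class = class,
             stringsAsFactors = FALSE)
}

#' Quantile envelope of a null table as a function of heterozygosity
#'
#' Sliding-neighbourhood quantiles of simulated F_ST at the given
#' heterozygosity values (the dotted envelope of an FDIST plot).
#'
#' @param null a [NullTable-class].
#' @param at heterozygosity values at which to evaluate.
#' @param probs quantiles (default 1% and 99%).
#' @param k neighbourhood size (default: from the config).
#' @return matrix `length(at)` x `length(probs)`.
#' @export
nullEnvelope <- function(null, at, probs = c(0.01, 0.99), k = NULL) {
  if (is.null(k)) k <- null@config$het_conditioning_k
  k <- min(k, length(null@het))
  ord <- order(null@het)
  het_s <- null@het[ord]; fst_s <- null@fst[ord]
  out <- matrix(NA_real_, length(at), length(probs),
                dimnames = list(NULL, paste0("q", probs)))
  for (i in seq_along(at)) {
    j <- findInterval(at[[i]], het_s)
    lo <- max(1L, j - k); hi <- min(length(het_s), j + k)
    idx <- seq.int(lo, hi)
    sel <- idx[order(abs(het_s[idx] - at[[i]]))[seq_len(k)]]
    out[i, ] <- quantile(fst_s[sel], probs, na.rm = TRUE)
  }
  out
}
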