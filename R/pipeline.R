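# End-to-end orchestration: filter -> diversity -> differentiation ->
# hierarchical outlier analysis -> genome scans -> LD decay.

#' Run the full population-genomic analysis
#'
#' Executes the canonical analysis order on real or simulated inputs:
#' locus filtering (MAF/fixed), LD pruning for the differentiation
#' subset only (the outlier analysis runs on the unpruned filtered set
#' so linked candidate regions stay detectable), per-population
#' diversity and Hardy-Weinberg summaries, the hierarchical island-model
#' outlier analysis, removal of significant outliers before the final
#' differentiation estimates, outlier-cluster/heterozygosity/LD genome
#' scans and the genome-wide LD decay fit. All stage seeds derive from
#' the single top-level seed.
#'
#' @param config list with either `sim` (a [simConfig()]) or `vcf` /
#'   `popmap` (/ `groupmap`) paths; optionally `fasta` + `fasta_popmap`
#'   for mtDNA stages; and tuning entries `maf_min`, `r2_max`,
#'   `target_fst` (`"auto"` = calibrate to the observed theta),
#'   `n_sims`, `p_cut`, `het_min`, `scan_window`, `min_snps`,
#'   `bin_size`, `ld_bin_width`, `n_perm`, `seed`, `out_dir`.
#' @return list of stage results (`dataset`, `filtered`, `pruned`,
#'   `diversity`, `hwe`, `outliers`, `null`, `differentiation`, `bins`,
#'   `het_scan`, `ld_scan`, `decay`, `log`); TSVs are written when
#'   `out_dir` is set.
#' @export
runPipeline <- function(config) {
  defaults <- list(maf_min = 0.01, r2_max = 0.5, target_fst = "auto",
                   n_sims = 5000L, p_cut = 0.01, het_min = 0.2,
                   scan_window = 10e6, min_snps = 6L, bin_size = 20e6,
                   ld_bin_width = 5e6, n_perm = 200L, seed = 1L,
                   out_dir = NULL)
  cfg <- utils::modifyList(defaults, config)
  seeds <- .child_seeds(cfg$seed, 8L)
  run_log <- list(seed = cfg$seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  truth <- NULL
  ds <- stage("input", {
    if (!is.null(cfg$sim)) {
      sim <- simulateSnpDataset(cfg$sim)
      truth <- sim$truth
      sim$dataset
    } else if (!is.null(cfg$vcf)) {
      readGenotypes(cfg$vcf, cfg$popmap, cfg$groupmap)
    } else stop("config needs either 'sim' or 'vcf'/'popmap'")
  })
  aln <- if (!is.null(cfg$fasta))
    stage("mtdna-input", readAlignment(cfg$fasta, cfg$fasta_popmap))
  else NULL
  run_log$n_loci_in <- nrow(ds)

  filtered <- stage("filter", filterLoci(ds, cfg$maf_min))
  run_log$filter <- attr(filtered, "filter_log")
  pruned <- stage("ld-prune", ldPrune(filtered, cfg$r2_max,
                                      seed = seeds[[1L]]))
  run_log$prune <- attr(pruned, "prune_log")

  diversity <- stage("diversity", meanExpectedHet(filtered))
  hwe <- stage("hwe", hweSummary(filtered))
  mtdna <- if (!is.null(aln)) stage("mtdna-stats", {
    pops <- unique(alnPopulations(aln))
    do.call(rbind, lapply(pops, function(p) {
      s <- haplotypeStats(aln, p)
      data.frame(population = p, S = s$S, h = s$h, pi = s$pi, n = s$n)
    }))
  }) else NULL

  outlier_stage <- stage("fdist", {
    layout <- layoutFromDataset(filtered)
    obs <- fstHetObserved(filtered)
    fc <- fdistConfig(sample_layout = layout, n_sims = cfg$n_sims,
                      seed = seeds[[2L]])
    tf <- cfg$target_fst
    if (identical(tf, "auto")) {
      comp <- .wc_dataset(filtered)
      ok <- !is.na(comp$a)
      tf <- sum(comp$a[ok]) / sum((comp$a + comp$b + comp$c)[ok])
    }
    fc$target_fst <- tf
    fc <- calibrateMigration(fc)
    null <- simulateNull(fc, seed = seeds[[3L]])
    list(null = null,
         calls = classifyOutliers(obs, null, cfg$p_cut, cfg$het_min))
  })
  outliers <- outlier_stage$calls
  run_log$n_high <- sum(outliers$class == "high", na.rm = TRUE)
  run_log$n_low <- sum(outliers$class == "low", na.rm = TRUE)

  differentiation <- stage("differentiation", {
    sig <- outliers$locus_id[outliers$class %in% c("high", "low")]
    keep <- !rownames(genotypes(pruned)) %in% sig
    final <- pruned[keep, ]
    run_log$n_final_diff_loci <- sum(keep)
    theta <- wcThetaOverall(final, n_perm = cfg$n_perm,
                            seed = seeds[[4L]])
    dest <- jostDest(final, n_perm = cfg$n_perm, seed = seeds[[5L]])
    pair_p <- theta$pair_p[upper.tri(theta$pair_p)]
    list(theta = theta, dest = dest,
         pair_fdr_significant = bhFdr(pair_p))
  })

  chrom_lengths <- if (!is.null(cfg$sim)) cfg$sim$chrom_lengths
  else setNames(rep(max(lociTable(filtered)$pos) + 1,
                    length(unique(lociTable(filtered)$chrom))),
                unique(lociTable(filtered)$chrom))
  bins <- stage("binscan", {
    mask_high <- outliers$class == "high" & !is.na(outliers$class)
    b <- binOutliers(lociTable(filtered), mask_high, chrom_lengths,
                     cfg$bin_size)
    b$poisson_p <- poissonClusterP(b$n_outliers, sum(mask_high), nrow(b))
    b
  })
  het_scan <- stage("sweepscan", tryCatch(
    hetWindowScan(filtered, outliers, window = cfg$scan_window,
                  min_snps = cfg$min_snps),
    error = function(e) NULL))
  ld_scan <- stage("ldscan", tryCatch(
    ldWindowScan(filtered, outliers, window = cfg$scan_window,
                 min_snps = cfg$min_snps),
    error = function(e) NULL))
  decay <- stage("lddecay", tryCatch({
    pairs <- syntenicPairs(filtered)
    fit <- fitDecay(pairs, bin_width = cfg$ld_bin_width)
    list(fit = fit,
         half_length_bp = halfLength(fit),
         d_at_0.2_bp = tryCatch(suppressWarnings(decayDistance(fit, 0.2)),
                                error = function(e) NA_real_))
  }, error = function(e) NULL))

  report <- list(dataset = ds, truth = truth, filtered = filtered,
                 pruned = pruned, diversity = diversity, hwe = hwe,
                 mtdna = mtdna, null = outlier_stage$null,
                 outliers = outliers, differentiation = differentiation,
                 bins = bins, het_scan = het_scan, ld_scan = ld_scan,
                 decay = decay, log = run_log)
  if (!is.null(cfg$out_dir)) .write_report(report, cfg)
  report
}

.write_tsv <- function(df, path, meta) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", names(meta), " = ", unlist(meta)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

.write_report <- function(report, cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(package = paste0("zfpopgen ",
                                as.character(utils::packageVersion("zfpopgen"))),
               seed = cfg$seed)
  p <- function(f) file.path(cfg$out_dir, f)
  .write_tsv(data.frame(population = names(report$diversity),
                        H_S = unname(report$diversity)),
             p("diversity.tsv"), meta)
  .write_tsv(report$outliers, p("outliers.tsv"), meta)
  .write_tsv(report$bins, p("bins.tsv"), meta)
  if (!is.null(report$mtdna)) .write_tsv(report$mtdna,
                                         p("mtdna_stats.tsv"), meta)
  if (!is.null(report$het_scan))
    .write_tsv(report$het_scan, p("het_windows.tsv"), meta)
  if (!is.null(report$ld_scan))
    .write_tsv(report$ld_scan, p("ld_windows.tsv"), meta)
  if (!is.null(report$decay)) {
    fit <- report$decay$fit
    .write_tsv(data.frame(bin_mid_mb = fit@bin_mid_mb,
                          n_pairs = fit@n_pairs, mean_r2 = fit@mean_r2),
               p("decay.tsv"),
               c(meta, list(a = fit@a, b = fit@b,
                            half_length_bp = report$decay$half_length_bp,
                            d_at_0.2_bp = report$decay$d_at_0.2_bp)))
  }
  th <- report$differentiation$theta
  .write_tsv(data.frame(statistic = c("theta", "dest"),
                        estimate = c(th$theta,
                                     report$differentiation$dest$dest),
                        ci_low = c(th$ci_low,
                                   report$differentiation$dest$ci_low),
                        ci_high = c(th$ci_high,
                                    report$differentiation$dest$ci_high)),
             p("differentiation.tsv"), meta)
  writeLines(paste0(names(report$log), " = ",
                    vapply(report$log, function(x)
                      paste(format(x), collapse = ","), "")),
             p("run_log.txt"))
  invisible(NULL)
}
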