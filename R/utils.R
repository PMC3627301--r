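# Internal helpers.

# Evaluate expr under a temporary RNG state seeded with `seed`; the
# caller's RNG state is restored afterwards. All seeded API functions
# funnel through this so a single integer seed makes them reproducible
# without disturbing the session RNG.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seeds (< 2^31) derived from one parent seed, used
# to give pipeline stages independent, individually reproducible streams.
.child_seeds <- function(seed, n) {
  .with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Pooled alternate-allele frequency per locus (rows), missing excluded.
.pooled_alt_freq <- function(gt) {
  alt <- rowSums(gt, na.rm = TRUE)
  n2 <- 2L * rowSums(!is.na(gt))
  ifelse(n2 > 0, alt / n2, NA_real_)
}

# Per-population genotype count summaries for one dataset: list of
# matrices (loci x populations): n (diploids), p (alt freq), h (observed
# heterozygote fraction).
.pop_counts <- function(ds, pops = NULL) {
  gt <- genotypes(ds)
  popv <- populations(ds)
  if (is.null(pops)) pops <- unique(unname(popv))
  n <- p <- h <- matrix(NA_real_, nrow(gt), length(pops),
                        dimnames = list(rownames(gt), pops))
  for (j in seq_along(pops)) {
    g <- gt[, popv == pops[[j]], drop = FALSE]
    nn <- rowSums(!is.na(g))
    n[, j] <- nn
    p[, j] <- ifelse(nn > 0, rowSums(g, na.rm = TRUE) / (2 * nn), NA_real_)
    h[, j] <- ifelse(nn > 0, rowSums(g == 1L, na.rm = TRUE) / nn, NA_real_)
  }
  list(pops = pops, n = n, p = p, h = h)
}

.assert_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop(name, " must be a number in [", lo, ", ", hi, "]")
  invisible(x)
}
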