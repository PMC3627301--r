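# Reading/writing VCF + popmap, alignment input, locus filters.

test_that("VCF genotypes are read as alt-allele counts in popmap order", {
  vcf <- tempfile(fileext = ".vcf")
  pm <- tempfile(fileext = ".tsv")
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "S1", "S2", sep = "\t"),
               paste("chr1", "100", "L1", "A", "G", ".", "PASS", ".", "GT",
                     "0/0", "1/1", sep = "\t")), vcf)
  writeLines(c("S1\tpopA", "S2\tpopB"), pm)
  ds <- readGenotypes(vcf, pm)
  expect_identical(unname(genotypes(ds)[1, ]), c(0L, 2L))
  expect_identical(unname(populations(ds)), c("popA", "popB"))

  # popmap missing a sample names the sample
  writeLines("S1\tpopA", pm)
  expect_error(readGenotypes(vcf, pm), "S2 not in popmap")

  # multiallelic record names the locus
  writeLines(c("##fileformat=VCFv4.2",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "S1", "S2", sep = "\t"),
               paste("chr1", "100", "L9", "A", "G,T", ".", "PASS", ".", "GT",
                     "0/0", "1/1", sep = "\t")), vcf)
  writeLines(c("S1\tpopA", "S2\tpopB"), pm)
  expect_error(readGenotypes(vcf, pm), "L9")
})

test_that("write/read round-trip is the identity on a seeded dataset", {
  set.seed(7)
  gt <- matrix(sample(c(0:2, NA), 100 * 8, replace = TRUE), 100, 8)
  pops <- setNames(rep(c("A", "B"), each = 4), sprintf("S%03d", 1:8))
  ds <- make_ds(gt, pops, chrom = rep(c("chr1", "chr2"), 50),
                pos = rep(seq_len(50) * 1e4, each = 2),
                groups = c(A = "G1", B = "G2"))
  vcf <- tempfile(fileext = ".vcf"); pm <- tempfile(fileext = ".tsv")
  writeGenotypes(ds, vcf, pm)
  ds2 <- readGenotypes(vcf, pm)
  expect_identical(genotypes(ds2), genotypes(ds))
  expect_identical(lociTable(ds2), lociTable(ds))
  expect_identical(populations(ds2), populations(ds))
  expect_identical(populationGroups(ds2), populationGroups(ds))
  # missing genotypes are written as ./.
  expect_true(any(grepl("\\./\\.", readLines(vcf))))
})

test_that("writing an empty locus list yields a header-only VCF", {
  gt <- matrix(0L, 1, 2, dimnames = list("L1", c("S1", "S2")))
  ds <- make_ds(gt, c(S1 = "A", S2 = "A"))
  vcf <- tempfile(fileext = ".vcf"); pm <- tempfile(fileext = ".tsv")
  writeGenotypes(ds[integer(0), ], vcf, pm)
  lines <- readLines(vcf)
  expect_true(all(startsWith(lines, "#")))
  expect_silent(readGenotypes(vcf, pm))
})

test_that("alignment reader uppercases and rejects ragged records", {
  fa <- tempfile(fileext = ".fasta"); pm <- tempfile(fileext = ".tsv")
  writeLines(c(">h1", "acgtacgtaa", ">h2", "ACGTACGTAA"), fa)
  writeLines(c("h1\tP1", "h2\tP1"), pm)
  aln <- readAlignment(fa, pm)
  expect_equal(Biostrings::width(alnSequences(aln)), c(10L, 10L))
  expect_identical(as.character(alnSequences(aln)[[1]]),
                   "ACGTACGTAA")
  writeLines(c(">h1", "ACGTACGTA", ">h2", "ACGTACGTAA", ">h3",
               "ACGTACGTAA"), fa)
  writeLines(c("h1\tP1", "h2\tP1", "h3\tP1"), pm)
  expect_error(readAlignment(fa, pm), "h1")
})

test_that("MAF filter removes fixed and sub-threshold loci and is idempotent", {
  # locus 1: 1 alt / 199 ref (MAF 0.005); locus 2 monomorphic; locus 3 common
  gt <- rbind(c(1L, rep(0L, 99)),
              rep(0L, 100),
              rep(c(0L, 1L, 2L), length.out = 100))
  ds <- make_ds(gt, setNames(rep("A", 100), sprintf("S%03d", 1:100)))
  out <- filterLoci(ds)
  expect_identical(rownames(genotypes(out)), "L003")
  log <- attr(out, "filter_log")
  expect_equal(unname(log[c("n_fixed_removed", "n_maf_removed")]), c(1, 1))

  # planted sub-threshold loci are counted exactly
  set.seed(11)
  n <- 100
  freqs <- c(runif(470, 0.1, 0.5), rep(0.004, 30))
  gt2 <- t(vapply(freqs, function(p) {
    g <- rbinom(n, 2, p)
    if (p < 0.01) { g[] <- 0L; g[1] <- 1L }  # force exactly 1 alt copy
    g
  }, integer(n)))
  ds2 <- make_ds(gt2, setNames(rep("A", n), sprintf("S%03d", 1:n)),
                 chrom = rep("chr1", 500), pos = seq_len(500) * 1000L)
  out2 <- filterLoci(ds2)
  expect_equal(nrow(out2), 470)
  expect_equal(genotypes(filterLoci(out2)), genotypes(out2))
  expect_error(filterLoci(ds2, maf_min = 0.7), "maf_min")
})

test_that("LD pruning removes one of each high-r2 pair, deterministically", {
  set.seed(3)
  base <- rbinom(40, 2, 0.5)
  gt <- rbind(base, base, rbinom(40, 2, 0.5))
  rownames(gt) <- c("L001", "L002", "L003")
  ds <- make_ds(gt, setNames(rep("A", 40), sprintf("S%03d", 1:40)))
  pr <- ldPrune(ds, seed = 5)
  expect_equal(nrow(pr), 2)
  expect_true("L003" %in% rownames(genotypes(pr)))
  # determinism
  pr2 <- ldPrune(ds, seed = 5)
  expect_identical(rownames(genotypes(pr)), rownames(genotypes(pr2)))
  # nothing above threshold: unchanged
  set.seed(8)
  gt3 <- matrix(rbinom(6 * 60, 2, 0.5), 6, 60)
  ds3 <- make_ds(gt3, setNames(rep("A", 60), sprintf("S%03d", 1:60)))
  p3 <- suppressWarnings(ldPrune(ds3, r2_max = 0.9, seed = 1))
  expect_equal(nrow(p3), 6)
})

test_that("no retained syntenic pair exceeds the r2 ceiling after pruning", {
  set.seed(21)
  n <- 50
  cols <- replicate(12, rbinom(n, 2, runif(1, 0.2, 0.8)))
  # plant correlated duplicates
  cols[, 4] <- cols[, 1]; cols[, 9] <- cols[, 7]
  gt <- t(cols)
  ds <- make_ds(gt, setNames(rep("A", n), sprintf("S%03d", 1:n)))
  pr <- ldPrune(ds, r2_max = 0.5, seed = 2)
  g <- genotypes(pr)
  for (i in seq_len(nrow(g) - 1)) for (j in seq.int(i + 1, nrow(g))) {
    r2 <- r2Pair(g[i, ], g[j, ])[["r2"]]
    if (!is.na(r2)) expect_lte(r2, 0.5)
  }
})

test_that("population merging relabels samples", {
  gt <- matrix(0:1, 2, 4)
  ds <- make_ds(gt, setNames(c("A", "A", "B", "C"), sprintf("S%03d", 1:4)))
  m <- mergePopulations(ds, c("A", "B"), "AB")
  expect_identical(unname(populations(m)), c("AB", "AB", "AB", "C"))
})
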