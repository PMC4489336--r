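# Genotype container, VCF input, MAF partitioning, window tiling.

test_that("VCF parsing yields minor-allele dosages and excludes monomorphic sites", {
  path <- write_vcf_fixture(c(
    "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "chr1\t200\t.\tG\tC\t.\tPASS\t.\tGT\t0/0\t0/0\t0/0",
    "chr1\t300\t.\tG\tC\t.\tPASS\t.\tGT\t1/1\t1/1\t1/0"))
  g <- read_genotypes(path)
  # monomorphic site 200 dropped
  expect_equal(n_variants(g), 2L)
  expect_equal(g$positions, c(100, 300))
  expect_equal(unname(g$dosages[, 1]), c(0, 1, 2))
  expect_equal(g$maf[1], 0.5)
  # site 300 is flipped to count the minor (REF) allele
  expect_equal(unname(g$dosages[, 2]), c(0, 0, 1))
  expect_equal(g$maf[2], 1 / 6)
})

test_that("multi-allelic records split and missing genotypes mean-impute", {
  path <- write_vcf_fixture(c(
    "chr1\t100\t.\tA\tT,G\t.\tPASS\t.\tGT\t0/1\t1/2\t0/2",
    "chr1\t200\t.\tA\tT\t.\tPASS\t.\tGT\t0/1\t./.\t1/1"))
  g <- read_genotypes(path)
  expect_equal(n_variants(g), 3L)        # 2 alt columns + 1 biallelic
  expect_equal(g$positions, c(100, 100, 200))
  expect_equal(unname(g$dosages[, 1]), c(1, 1, 0))   # allele T
  expect_equal(unname(g$dosages[, 2]), c(0, 1, 1))   # allele G
  # missing imputed to the observed mean of (1, 2) = 1.5; the alt allele
  # is the major one (freq 0.75), so the column is flipped to minor counts
  expect_equal(unname(g$dosages[, 3]), 2 - c(1, 1.5, 2))
  expect_equal(g$maf[3], 0.25, tolerance = 1e-12)
})

test_that("region filtering works and empty regions signal explicitly", {
  path <- write_vcf_fixture(c(
    "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "chr1\t900\t.\tA\tT\t.\tPASS\t.\tGT\t0/1\t0/1\t0/0"))
  g <- read_genotypes(path, region = "chr1:500-1000")
  expect_equal(g$positions, 900)
  expect_error(read_genotypes(path, region = "chr1:5000-6000"),
               class = "winsig_empty_region")
  expect_error(read_genotypes(tempfile()), class = "winsig_io")
})

test_that("synthetic cohort round-trips through VCF identically", {
  spec <- cohort_spec(n_individuals = 40, n_sites = 300,
                      n_founder_haplotypes = 60, seed = 31)
  g <- sample_cohort(generate_founders(spec), spec)
  path <- tempfile(fileext = ".vcf")
  write_cohort_vcf(g, path)
  g2 <- read_genotypes(path)
  expect_equal(unname(g2$dosages), unname(g$dosages))
  expect_equal(g2$positions, g$positions)
  expect_equal(g2$maf, g$maf, tolerance = 1e-12)
})

test_that("MAF is invariant to allele-label flipping", {
  set.seed(5)
  d <- matrix(rbinom(200, 2, 0.3), nrow = 20)
  g1 <- genotype_matrix(d, seq_len(10) * 100)
  g2 <- genotype_matrix(2 - d, seq_len(10) * 100)
  expect_equal(g1$maf, g2$maf, tolerance = 1e-12)
})

test_that("split_by_maf uses a strict cutoff and partitions all variants", {
  # dosage columns engineered to known frequencies over 500 individuals
  n <- 500
  mk <- function(k) c(rep(1, k), rep(0, n - k))       # k minor alleles
  d <- cbind(mk(4), mk(10), mk(200))                  # maf .004, .01, .2
  g <- genotype_matrix(d, c(100, 200, 300))
  expect_equal(g$maf, c(0.004, 0.01, 0.2))
  part <- split_by_maf(g, 0.01)
  expect_equal(part$rare_idx, 1L)                     # boundary is common
  expect_equal(part$common_idx, c(2L, 3L))
  expect_equal(split_by_maf(g, 0.5)$rare_idx, 1:3)
  expect_error(split_by_maf(g, 0.7), class = "winsig_bad_argument")
  expect_error(split_by_maf(g, 0), class = "winsig_bad_argument")
})

test_that("window tiling reproduces the published chromosome-scale counts", {
  expect_equal(n_windows(build_windows(1779499)), 71179)
  expect_equal(n_windows(build_windows(1853923)), 74156)
  expect_equal(n_windows(build_windows(2046466)), 81858)
})

test_that("window tiling handles small and partial cases", {
  ws1 <- build_windows(50)
  expect_equal(n_windows(ws1), 1L)
  expect_equal(unlist(ws1$windows[1, c("start_rank", "end_rank")],
                      use.names = FALSE), c(0, 50))
  ws <- build_windows(76)
  expect_equal(ws$windows$start_rank, c(0, 25, 50))
  expect_equal(ws$windows$end_rank, c(50, 75, 76))
  expect_error(build_windows(0), class = "winsig_bad_argument")
  expect_error(build_windows(100, window_size = 10, step = 20),
               class = "winsig_bad_argument")
})

test_that("every rare rank is covered; interior ranks belong to exactly two windows", {
  for (n_rare in c(50, 76, 101, 999, 1000)) {
    ws <- build_windows(n_rare)
    cover <- integer(n_rare)
    for (w in seq_len(n_windows(ws))) {
      r <- ws$windows[w, ]
      idx <- (r$start_rank + 1):r$end_rank
      cover[idx] <- cover[idx] + 1L
    }
    expect_true(all(cover >= 1L), info = n_rare)
    # first step and a possible trailing remainder appear once
    interior <- setdiff(seq_len(n_rare),
                        c(seq_len(min(ws$step, n_rare)),
                          which(cover == 1L & seq_len(n_rare) > ws$step)))
    expect_true(all(cover[interior] == 2L), info = n_rare)
    expect_true(all(cover <= 2L), info = n_rare)
  }
})

test_that("window table reports BED-like spans in the parent coordinates", {
  spec <- cohort_spec(n_individuals = 50, n_sites = 400,
                      n_founder_haplotypes = 80, seed = 17)
  g <- sample_cohort(generate_founders(spec), spec)
  part <- split_by_maf(g, 0.05)
  ws <- build_windows(length(part$rare_idx))
  tab <- window_table(ws, g, part)
  expect_equal(nrow(tab), n_windows(ws))
  first <- part$rare_idx[ws$windows$start_rank[1] + 1]
  expect_equal(tab$start0[1], g$positions[first] - 1)
  expect_true(all(tab$end > tab$start0))
  path <- tempfile(fileext = ".tsv")
  write_window_table(tab, path)
  expect_equal(nrow(data.table::fread(path)), nrow(tab))
})
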