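test_that("genotype_panel enforces its invariants", {
  sites <- data.frame(chrom = "1", arm = "p", cm = c(1, 2))
  g <- matrix(c(0L, 1L, 2L, 1L), 2)
  expect_silent(genotype_panel(g, sites))
  expect_error(genotype_panel(g, sites, ploidy = "pseudo_haploid"),
               "heterozygous")
  expect_error(genotype_panel(matrix(3L, 1, 2), sites), "0, 1, 2")
  expect_error(genotype_panel(g, sites[1, , drop = FALSE]), "one row per")
})

test_that("PLINK BED/BIM/FAM round-trips including missing data", {
  panel <- simulate_ld_panel(huge_ne_model(), 17, tiny_genome(3, 3),
                             layout = "independent", sites_per_arm = 9,
                             seed = 12)
  ph <- pseudo_haploidize(panel, missingness = 0.2, seed = 2)
  for (p in list(panel, ph)) {
    prefix <- withr::local_tempfile()
    write_plink_panel(p, prefix)
    back <- read_plink_panel(prefix, ploidy = p$ploidy)
    expect_identical(unname(back$genotypes), unname(p$genotypes))
    expect_equal(back$sites$cm, p$sites$cm)
    expect_equal(back$sites$arm, p$sites$arm)
    expect_equal(back$sample_ids, p$sample_ids)
  }
})

test_that("VCF genotypes load through the genetic map", {
  skip_if_not_installed("vcfR")
  map <- reader_map()
  vcf <- c("##fileformat=VCFv4.2",
           "##contig=<ID=7>",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "s1", "s2", "s3", sep = "\t"),
           paste("7", "1000000", "v1", "A", "G", ".", "PASS", ".", "GT",
                 "0/0", "0/1", "1/1", sep = "\t"),
           paste("7", "9000000", "v2", "C", "T", ".", "PASS", ".", "GT",
                 "0|1", "./.", "0/0", sep = "\t"))
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  p <- read_vcf_panel(f, map)
  expect_equal(unname(p$genotypes[, 1]), c(0L, 1L, 2L))
  expect_equal(unname(p$genotypes[, 2]), c(1L, NA_integer_, 0L))
  expect_equal(p$sites$cm, c(0.5, 7.5))
  expect_equal(p$sites$arm, c("p", "q"))
})

test_that("pseudo-haploidisation follows the coverage-missingness relation", {
  expect_equal(exp(-30), 9.357623e-14, tolerance = 1e-6)
  panel <- simulate_ld_panel(huge_ne_model(), 50, tiny_genome(4, 4),
                             layout = "independent", sites_per_arm = 50,
                             seed = 3)
  ph <- pseudo_haploidize(panel, missingness = 0.5, seed = 6)
  n <- length(ph$genotypes)
  miss <- mean(is.na(ph$genotypes))
  expect_lt(abs(miss - 0.5), 3 * sqrt(0.25 / n))
  expect_false(any(ph$genotypes == 1L, na.rm = TRUE))
  # coverage interface: C = 1.4 implies m = exp(-1.4)
  ph2 <- pseudo_haploidize(panel, coverage = 1.4, seed = 6)
  expect_lt(abs(mean(is.na(ph2$genotypes)) - exp(-1.4)),
            3 * sqrt(exp(-1.4) * (1 - exp(-1.4)) / n))
  expect_error(pseudo_haploidize(panel), "exactly one")
  expect_error(pseudo_haploidize(panel, missingness = 1.2), "\\[0, 1\\)")
})

test_that("read counts invert the coverage-missingness relation", {
  # m = (1 - L/G)^N recovered exactly from the returned N
  N <- reads_for_missingness(0.25, n_samples = 1, read_length = 150,
                             genome_length = 3e9)
  expect_equal((1 - 150 / 3e9)^N, 0.25, tolerance = 1e-9)
  # per-sample effort scales linearly and approximates C = -log(m) x G/L
  expect_equal(reads_for_missingness(0.25, 10), 10 * N)
  expect_equal(N * 150 / 3e9, -log(0.25), tolerance = 1e-6)
  expect_error(reads_for_missingness(1.5, 1), "\\(0, 1\\)")
})

test_that("heterozygous sites are sampled to either homozygote equally", {
  sites <- data.frame(chrom = "1", arm = "p", cm = 1:2)
  g <- matrix(1L, nrow = 400, ncol = 2)
  panel <- genotype_panel(g, sites)
  draws <- sapply(1:20, function(s)
    mean(pseudo_haploidize(panel, missingness = 0, seed = s)$genotypes) / 2)
  expect_lt(abs(mean(draws) - 0.5), 3 * sqrt(0.25 / (20 * 800)))
})

test_that("sampling times are uniform on the requested range", {
  tab <- assign_sampling_times(500, 10, seed = 4)
  expect_true(all(tab$age_lo >= 0 & tab$age_hi <= 10))
  expect_equal(tab$age_lo, tab$age_hi)
  expect_gt(length(unique(tab$age_lo)), 8)
  z <- assign_sampling_times(10, 0, seed = 1)
  expect_true(all(z$age_lo == 0))
})

test_that("pseudo-haploidising leaves the demographic LD signal unchanged", {
  # paired comparison at matched sites: the baseline-adjusted curve of the
  # pseudo-haploid panel tracks the diploid one
  m <- scenario("collapse")
  n_dip <- 60; n_hap <- 120
  reps <- 60; u <- 0.01
  d_dip <- numeric(reps); d_ph <- numeric(reps)
  set.seed(99)
  for (r in seq_len(reps)) {
    p2 <- runif(2, 0.3, 0.5)
    tl <- sim_two_locus(m, n_hap, u, p2[1], p2[2], horizon = 600)
    gx <- tl$x[seq(1, n_hap, 2)] + tl$x[seq(2, n_hap, 2)]
    gy <- tl$y[seq(1, n_hap, 2)] + tl$y[seq(2, n_hap, 2)]
    sites <- data.frame(chrom = "1", arm = "p", cm = c(1, 2))
    pan <- genotype_panel(cbind(gx, gy), sites)
    G <- standardize_genotypes(pan)
    d_dip[r] <- pairwise_r2(G[, 1], G[, 2])
    ph <- pseudo_haploidize(pan, missingness = 0, seed = 1000 + r)
    Gp <- standardize_genotypes(ph)
    d_ph[r] <- pairwise_r2(Gp[, 1], Gp[, 2])
  }
  b_dip <- ld_baseline(n_dip, "diploid")$beta
  b_ph <- ld_baseline(n_dip, "pseudo_haploid")$beta
  sig_dip <- mean(d_dip, na.rm = TRUE) - b_dip
  sig_ph <- mean(d_ph, na.rm = TRUE) - b_ph
  se <- sd(d_ph - d_dip, na.rm = TRUE) / sqrt(reps)
  expect_lt(abs(sig_ph - sig_dip), 3 * se + 3e-4)
})
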