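test_that("standardisation matches hand-computed values and centres columns", {
  # column with phat = 0.5: the heterozygote maps to 0
  g <- matrix(c(2L, 1L, 0L, 1L), ncol = 1)
  sites <- data.frame(chrom = "1", arm = "p", cm = 1)
  p <- genotype_panel(g, sites)
  G <- standardize_genotypes(p)
  expect_equal(G[2, 1], 0)
  expect_equal(mean(G[, 1]), 0, tolerance = 1e-10)
  # phat = 0.25: homozygote standardises to (2 - 0.5)/sqrt(0.375)
  g2 <- matrix(c(2L, 0L, 0L, 0L), ncol = 1)
  G2 <- standardize_genotypes(genotype_panel(g2, sites))
  expect_equal(G2[1, 1], 1.5 / sqrt(0.375), tolerance = 1e-12)
  # pseudo-haploid panels use the Bernoulli normalisation
  g3 <- matrix(c(2L, 2L, 0L, 0L), ncol = 1)
  G3 <- standardize_genotypes(genotype_panel(g3, sites,
                                             ploidy = "pseudo_haploid"))
  expect_equal(G3[1, 1], 0.5 / sqrt(0.25), tolerance = 1e-12)
  expect_equal(mean(G3[, 1]^2), 1, tolerance = 1e-12)  # exact for Bernoulli
})

test_that("pairwise_r2 matches hand evaluation and masking rules", {
  g <- c(1, -1, 1, -1)
  expect_equal(pairwise_r2(g, g), (16 - 4) / 12)  # = 1
  # exactly orthogonal columns: negative value preserving unbiasedness
  gx <- c(1, 1, -1, -1); gy <- c(1, -1, 1, -1)
  expect_equal(pairwise_r2(gx, gy), -sum(gx^2 * gy^2) / 12)
  expect_lt(pairwise_r2(gx, gy), 0)
  expect_true(is.na(pairwise_r2(c(1, NA, NA, 1), c(NA, 1, 1, NA))))
})

test_that("the displayed formula agrees with a direct implementation", {
  direct <- function(gx, gy) {
    ok <- !is.na(gx) & !is.na(gy)
    s <- sum(ok); x <- gx[ok]; y <- gy[ok]
    acc <- 0
    for (i in seq_len(s)) for (j in seq_len(s))
      if (i != j) acc <- acc + x[i] * y[i] * x[j] * y[j]
    acc / (s * (s - 1))
  }
  set.seed(4)
  for (r in 1:20) {
    gx <- rnorm(7); gy <- rnorm(7)
    gx[sample(7, 1)] <- NA
    expect_equal(pairwise_r2(gx, gy), direct(gx, gy), tolerance = 1e-12)
  }
})

test_that("the finite-sample baseline matches Monte-Carlo independence", {
  s <- 40
  bl <- ld_baseline(s, "diploid")
  set.seed(11)
  reps <- 40000
  vals <- numeric(reps)
  p <- runif(reps, 0.25, 0.5); q <- runif(reps, 0.25, 0.5)
  for (r in seq_len(reps)) {
    gx <- rbinom(s, 2, p[r]); gy <- rbinom(s, 2, q[r])
    px <- mean(gx) / 2; py <- mean(gy) / 2
    if (px <= 0 || px >= 1 || py <= 0 || py >= 1) { vals[r] <- NA; next }
    sx <- (gx - 2 * px) / sqrt(2 * px * (1 - px))
    sy <- (gy - 2 * py) / sqrt(2 * py * (1 - py))
    vals[r] <- ((sum(sx * sy))^2 - sum(sx^2 * sy^2)) / (s * (s - 1))
  }
  vals <- vals[!is.na(vals)]
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - bl$beta), 3 * se)
  # tau approximates the estimator's spread
  expect_equal(sd(vals), bl$tau, tolerance = 0.15)
  # pseudo-haploid e2 is exactly 1
  expect_equal(ld_baseline(25, "pseudo_haploid")$e2, 1)
  expect_equal(ld_baseline(25, "pseudo_haploid")$beta, 1 / 24^2)
})

test_that("bin_ld_curve bins by half-open cM intervals and conserves pairs", {
  big <- huge_ne_model()
  panel <- simulate_ld_panel(big, 30, tiny_genome(4, 4),
                             layout = "independent", sites_per_arm = 12,
                             seed = 8)
  ld <- bin_ld_curve(panel, window_cm = c(0.5, 30), maf_min = 0.05)
  # conservation: per-region pair totals equal the in-window pair counts
  # among the sites that survive the frequency filter
  p <- colMeans(panel$genotypes, na.rm = TRUE) / 2
  keep <- pmin(p, 1 - p) > 0.05 & p > 0 & p < 1
  for (r in unique(ld$region)) {
    cm <- panel$sites$cm[panel$sites$region == r & keep]
    d <- as.vector(dist(cm))
    expect_equal(sum(ld$n_pairs[ld$region == r]),
                 sum(d >= 0.5 & d < 30))
  }
  # a 0.7 cM pair contributes to bin [0.5, 1.0)
  sites <- data.frame(chrom = "1", arm = "p", cm = c(10, 10.7))
  g <- matrix(rbinom(80, 2, 0.4), nrow = 40)
  ld2 <- bin_ld_curve(genotype_panel(g, sites), window_cm = c(0.5, 30))
  expect_equal(nrow(ld2), 1)
  expect_equal(ld2$bin_lo, 0.5)
  expect_equal(ld2$bin_hi, 1.0)
})

test_that("zero-history panels sit at the finite-sample baseline", {
  big <- huge_ne_model()
  acc <- c(); accn <- 0
  for (s in 1:6) {
    panel <- simulate_ld_panel(big, 50, tiny_genome(4, 6),
                               layout = "independent", sites_per_arm = 25,
                               seed = 20 + s)
    ld <- bin_ld_curve(panel, window_cm = c(0.5, 30))
    acc <- c(acc, ld$y)
  }
  bl <- ld_baseline(50, "diploid")
  se <- sd(acc) / sqrt(length(acc))      # bins share sites: conservative?
  # mean over many weakly dependent bins; allow 4 x naive SE
  expect_lt(abs(mean(acc) - bl$beta), 4 * se)
})

test_that("duplicating every individual changes R2 only through s", {
  big <- huge_ne_model()
  panel <- simulate_ld_panel(big, 25, tiny_genome(2, 2),
                             layout = "independent", sites_per_arm = 10,
                             seed = 5)
  dup <- genotype_panel(panel$genotypes[rep(1:25, 2), ], panel$sites,
                        sample_ids = sprintf("s%d", 1:50))
  G <- standardize_genotypes(dup)
  # recompute the statistic by hand for a site pair and compare
  ld_dup <- bin_ld_curve(dup, window_cm = c(0.5, 30))
  manual <- pairwise_r2(G[, 1], G[, 2])
  d12 <- abs(panel$sites$cm[1] - panel$sites$cm[2])
  if (d12 >= 0.5 && d12 < 30) {
    b <- ld_dup[ld_dup$region == panel$sites$region[1] &
                  ld_dup$bin_lo <= d12 & ld_dup$bin_hi > d12, ]
    expect_true(nrow(b) == 1)
  }
  expect_true(is.finite(manual))
})

test_that("cross-chromosome statistic matches brute-force enumeration", {
  # 3 individuals, two unlinked sites: enumerate ordered pairs directly
  gx <- matrix(c(0L, 1L, 2L), ncol = 1)
  gy <- matrix(c(2L, 1L, 0L), ncol = 1)
  sites <- data.frame(chrom = c("1", "2"), arm = "p", cm = c(1, 1))
  panel <- genotype_panel(cbind(gx, gy), sites)
  G <- standardize_genotypes(panel, scale = "dosage")
  s <- 3
  acc <- 0
  for (i in 1:s) for (j in 1:s) if (i != j)
    acc <- acc + G[i, 1] * G[i, 2] * G[j, 1] * G[j, 2]
  manual <- acc / (s * (s - 1)) - 4 / ((2 * s - 1) * (2 * s - 1))
  rep <- suppressWarnings(ccld_test(panel, maf_min = 0))
  expect_equal(rep$pair_means$mean_stat, manual, tolerance = 1e-12)
})

test_that("cross-chromosome test is calibrated under panmixia", {
  gen <- five_chrom_genome()
  big <- huge_ne_model()
  rej <- 0; pooled <- numeric(120)
  for (r in 1:120) {
    p <- simulate_ld_panel(big, 50, gen, layout = "independent",
                           sites_per_arm = 25, seed = 5000 + r)
    cc <- ccld_test(p, seed = r)
    rej <- rej + cc$significant
    pooled[r] <- cc$pooled_mean
  }
  rate <- rej / 120
  # binomial 99% bounds around 0.05 for 120 replicates
  bounds <- 0.05 + c(-1, 1) * 2.576 * sqrt(0.05 * 0.95 / 120)
  expect_gte(rate, max(0, bounds[1]))
  expect_lte(rate, bounds[2])
  expect_lt(abs(mean(pooled)), 3 * sd(pooled) / sqrt(120))
})

test_that("diverged-source panels are flagged by the structure test", {
  p <- simulate_structured_panel(50, fst = 0.2, five_chrom_genome(),
                                 sites_per_arm = 25, mode = "pooled",
                                 seed = 3)
  expect_true(ccld_test(p, seed = 1)$significant)
  # single chromosome: not-applicable result with a warning
  one <- simulate_ld_panel(huge_ne_model(), 20,
                           data.frame(region = "1_w", chrom = "1",
                                      arm = "w", length_morgans = 1),
                           layout = "independent", sites_per_arm = 10,
                           seed = 1)
  expect_warning(res <- ccld_test(one), "at least 2")
  expect_false(res$significant)
})

test_that("structure reports serialise with a pooled summary row", {
  p <- simulate_structured_panel(40, fst = 0.25, five_chrom_genome(),
                                 sites_per_arm = 20, mode = "pooled",
                                 seed = 7)
  cc <- ccld_test(p, seed = 1)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_ccld_report(cc, f)
  tab <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), cc$n_chrom_pairs + 1)
  expect_equal(tab$mean_stat[nrow(tab)], cc$pooled_mean, tolerance = 1e-12)
  expect_equal(tab$p_value[nrow(tab)], cc$p_value, tolerance = 1e-12)
})

test_that("binned LD TSV round-trips", {
  ld <- constant_ld_20(seed = 77)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_binned_ld(ld, f)
  back <- read_binned_ld(f)
  expect_equal(back$y, ld$y, tolerance = 1e-12)
  expect_equal(attr(back, "n_eff"), attr(ld, "n_eff"))
  expect_equal(attr(back, "ploidy"), attr(ld, "ploidy"))
})
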