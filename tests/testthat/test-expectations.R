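test_that("expected IBD density closed forms hold", {
  m <- scenario("constant")
  expect_equal(expected_ibd_density(m, c(0.02, 0.02)), 0)
  # all coalescence mass at generation 1: density over [u, Inf) is 2 e^{-2u}
  kernel <- recne:::mu_from_pmf(list(times = 1:5,
                                     pmf = c(1, 0, 0, 0, 0)),
                                c(0.02, 1e6))
  expect_equal(kernel, 2 * exp(-2 * 0.02), tolerance = 1e-6)
  expect_error(expected_ibd_density(m, 0.02), "length >= 2")
})

test_that("tiling-mode simulation is an independent oracle for the density", {
  m <- scenario("bottleneck")
  gen <- data.frame(region = "1_w", chrom = "1", arm = "w",
                    length_morgans = 0.5)
  n_pairs <- 400
  segs <- simulate_pairwise_ibd(m, n_pairs, gen, mode = "tiling", seed = 17)
  h <- build_ibd_histogram(segs, genome_map(gen), n_pairs = n_pairs)
  edges_m <- sort(unique(c(h$bin_lo, h$bin_hi))) / 100
  mu <- expected_ibd_density(m, edges_m)
  lam <- mu * 0.5 * n_pairs
  cnt <- h$count[order(h$bin_lo)]
  z <- (cnt - lam) / sqrt(pmax(lam, 1e-9))
  expect_true(all(abs(z[lam > 5]) < 3.5))
})

test_that("p_ibd decays with distance and with population size", {
  u <- c(0.005, 0.01, 0.02, 0.05, 0.1, 0.3)
  for (nm in c("constant", "expansion", "collapse", "bottleneck")) {
    p <- p_ibd(scenario(nm), u)
    expect_true(all(diff(p) < 0))
  }
  small <- demographic_model(c(0, 125), c(5000, 5000))
  large <- demographic_model(c(0, 125), c(50000, 50000))
  expect_true(all(p_ibd(large, u) < p_ibd(small, u)))
})

test_that("expected_ld approaches the baseline at long distances", {
  m <- scenario("constant")
  beta <- ld_baseline(100, "diploid")$beta
  far <- expected_ld(m, 500, 100)      # 5 Morgans
  expect_equal(far, beta, tolerance = 1e-4)
})

test_that("discrete p_ibd matches continuous-time integration for large N", {
  # the discrete and continuous conventions agree when the per-generation
  # recombination probability is small (2u << 1)
  u <- c(0.002, 0.005, 0.01)
  for (N in c(1000, 20000)) {
    m <- demographic_model(c(0, 125), c(N, N))
    disc <- p_ibd(m, u, horizon = 60 * N)
    cont <- vapply(u, function(uu)
      stats::integrate(function(t) (1 / N) * exp(-t / N) * exp(-2 * t * uu),
                       0, Inf, rel.tol = 1e-10)$value, numeric(1))
    expect_equal(disc, cont, tolerance = 0.01)
  }
})

test_that("two-locus ancestry simulation reproduces the expected LD curve", {
  m <- scenario("constant")
  n_dip <- 64; n_hap <- 128; horizon <- 800
  reps <- 120
  for (u_cm in c(1, 3)) {
    vals <- numeric(reps)
    set.seed(500 + u_cm)
    for (r in seq_len(reps)) {
      p2 <- runif(2, 0.25, 0.5)
      tl <- sim_two_locus(m, n_hap, u_cm / 100, p2[1], p2[2],
                          horizon = horizon)
      gx <- tl$x[seq(1, n_hap, 2)] + tl$x[seq(2, n_hap, 2)]
      gy <- tl$y[seq(1, n_hap, 2)] + tl$y[seq(2, n_hap, 2)]
      px <- mean(gx) / 2; py <- mean(gy) / 2
      if (min(px, py) <= 0 || max(px, py) >= 1) { vals[r] <- NA; next }
      sx <- (gx - 2 * px) / sqrt(2 * px * (1 - px))
      sy <- (gy - 2 * py) / sqrt(2 * py * (1 - py))
      vals[r] <- pairwise_r2(sx, sy)
    }
    vals <- vals[!is.na(vals)]
    mu <- expected_ld(m, u_cm, n_dip, horizon = horizon)
    se <- sd(vals) / sqrt(length(vals))
    expect_lt(abs(mean(vals) - mu), 3 * se)
  }
})

test_that("summary-level generator agrees with expected_ld on all scenarios", {
  gen <- synthetic_genome(10, 9)
  for (nm in c("constant", "collapse", "bottleneck", "expansion")) {
    m <- scenario(nm)
    acc <- NULL
    for (s in 1:4) {
      ld <- simulate_ld_summaries(m, 100, gen, seed = 6000 + 10 * s)
      fd <- recne:::build_fit_data(ld, NULL, fit_config())
      acc <- rbind(acc, fd$Y)
    }
    mu <- expected_ld(m, fd$u * 100, 100)
    ybar <- colMeans(acc)
    se <- apply(acc, 2, sd) / sqrt(nrow(acc))
    z <- (ybar - mu) / se
    expect_lt(max(abs(z)), 3.8)   # 59 bins per scenario
  }
})

test_that("pair age density matches its degenerate and brute-force cases", {
  z <- sample_age_table(c("a", "b", "c"), c(0, 0, 0))
  d <- pair_age_density(z)
  expect_equal(nrow(d), 1)
  expect_equal(d$a_old, 0L); expect_equal(d$gap, 0L)
  expect_equal(d$weight, 1)
  two <- sample_age_table(c("a", "b"), c(10, 30))
  d2 <- pair_age_density(two)
  expect_equal(d2$a_old, 30L); expect_equal(d2$gap, 20L)
  # all intervals [0, D]: exhaustive enumeration over discrete pairs
  D <- 4
  tab <- sample_age_table(letters[1:5], rep(0, 5), rep(D, 5))
  d3 <- pair_age_density(tab)
  brute <- new.env()
  for (x in 0:D) for (y in 0:D) {
    key <- paste(max(x, y), abs(x - y))
    old <- if (is.null(brute[[key]])) 0 else brute[[key]]
    brute[[key]] <- old + 1 / (D + 1)^2
  }
  for (k in seq_len(nrow(d3))) {
    key <- paste(d3$a_old[k], d3$gap[k])
    expect_equal(d3$weight[k], get(key, envir = brute), tolerance = 1e-9)
  }
  expect_equal(sum(d3$weight), 1, tolerance = 1e-9)
})

test_that("time-heterogeneous expectations reduce and bias as they should", {
  m <- scenario("constant")
  zero <- sample_age_table(letters[1:4], rep(0, 4))
  u <- c(0.75, 1.25, 3.25, 9.75, 25.25)
  a <- expected_ld_time_het(m, zero, u, 100)
  b <- expected_ld(m, u, 100)
  expect_lt(max(abs(a - b)), 1e-12)
  ages <- sample_age_table(letters[1:6], rep(0, 6), rep(10, 6))
  dens <- pair_age_density(ages)
  p_het <- recne:::p_ibd_time_het(m, u / 100, dens)
  p_mod <- p_ibd(m, u / 100)
  expect_true(all(p_mod > p_het))  # ignoring ages inflates sharing
})

test_that("age-aware generator matches the age-aware expectation", {
  m <- scenario("constant")
  ages <- sample_age_table(sprintf("s%d", 1:100), rep(0, 100), rep(10, 100))
  gen <- synthetic_genome(10, 9)
  acc <- NULL
  for (s in 1:4) {
    ld <- simulate_ld_summaries(m, 100, gen, ages = ages, seed = 7100 + s)
    fd <- recne:::build_fit_data(ld, NULL, fit_config())
    acc <- rbind(acc, fd$Y)
  }
  mu <- expected_ld_time_het(m, ages, fd$u * 100, 100)
  z <- (colMeans(acc) - mu) / (apply(acc, 2, sd) / sqrt(nrow(acc)))
  expect_lt(max(abs(z)), 3.8)
})

test_that("age tables read, write and convert years", {
  tab <- sample_age_table(c("x", "y"), c(0, 5), c(2, 9))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_age_table(tab, f)
  back <- read_age_table(f)
  expect_equal(back$age_lo, tab$age_lo)
  expect_equal(back$age_hi, tab$age_hi)
  expect_equal(years_to_generations(29), 1)
  expect_equal(years_to_generations(290, 29), 10)
  expect_error(sample_age_table("a", -1), "lo <= hi")
})
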