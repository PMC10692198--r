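test_that("analytic gradient of the pseudo-posterior matches finite differences", {
  ld <- fixture("grad_ld", function()
    simulate_ld_summaries(scenario("constant"), 50, tiny_genome(6, 5),
                          seed = 3))
  cfg <- fit_config(seed = 2, horizon = 600)
  fd <- recne:::build_fit_data(ld, NULL, cfg)
  gt <- c(0, 10, 30, 60, 90, 125)
  obj <- recne:::make_objective(fd, gt, cfg, power = 0.7, lambda = 2)
  th <- log(rep(c(15000, 25000), 3))
  gr_a <- obj$gr(th)
  gr_n <- vapply(seq_along(th), function(k) {
    e <- 1e-6; tp <- th; tm <- th
    tp[k] <- th[k] + e; tm[k] <- th[k] - e
    (obj$fn(tp) - obj$fn(tm)) / (2 * e)
  }, numeric(1))
  expect_lt(max(abs(gr_a - gr_n) / pmax(abs(gr_n), 1e-6)), 1e-5)
  # and for the quasi-Poisson IBD branch with age-free components
  segs <- simulate_pairwise_ibd(scenario("bottleneck"), 500,
                                tiny_genome(4, 4), seed = 4)
  h <- build_ibd_histogram(segs, genome_map(tiny_genome(4, 4)),
                           n_pairs = 500)
  fdi <- recne:::build_fit_data(h, NULL, cfg)
  obji <- recne:::make_objective(fdi, gt, cfg, power = 0.5, lambda = 1)
  gr_a2 <- obji$gr(th)
  gr_n2 <- vapply(seq_along(th), function(k) {
    e <- 1e-6; tp <- th; tm <- th
    tp[k] <- th[k] + e; tm[k] <- th[k] - e
    (obji$fn(tp) - obji$fn(tm)) / (2 * e)
  }, numeric(1))
  expect_lt(max(abs(gr_a2 - gr_n2) / pmax(abs(gr_n2), 1e-6)), 1e-5)
})

test_that("objective is linear in the power exponent", {
  ld <- fixture("grad_ld", function()
    simulate_ld_summaries(scenario("constant"), 50, tiny_genome(6, 5),
                          seed = 3))
  m <- demographic_model(c(0, 125), c(18000, 22000))
  v1 <- neg_log_pseudo_posterior(m, ld, power = 1, lambda = 0)
  v2 <- neg_log_pseudo_posterior(m, ld, power = 0.5, lambda = 0)
  expect_equal(v2, v1 / 2, tolerance = 1e-12)
})

test_that("data generated exactly at the model mean make truth stationary", {
  cfg <- fit_config(seed = 1, horizon = 1250)
  gt <- c(0, 5, 15, 30, 50, 80, 125)
  # truth defined on the fitting grid itself, so the generating model lies
  # inside the searched family
  truth <- demographic_model(gt, c(3000, 5000, 9000, 16000, 20000,
                                   20000, 20000), t_max = 125)
  u_cm <- seq(0.75, 29.75, by = 0.5)
  mu <- expected_ld(truth, u_cm, 100)
  df <- do.call(rbind, lapply(sprintf("r%02d", 1:6), function(r)
    data.frame(region = r, bin_lo = u_cm - 0.25, bin_hi = u_cm + 0.25,
               y = mu, n_pairs = 500, var = 1e-8)))
  ld <- binned_ld(df, n_eff = 100, ploidy = "diploid")
  fd <- recne:::build_fit_data(ld, NULL, cfg)
  obj <- recne:::make_objective(fd, gt, cfg, power = 1, lambda = 0)
  g <- obj$gr(truth$log_ne)
  expect_lt(sqrt(sum(g^2)), 1e-4)
})

test_that("infinite regularisation approaches the single-exponential family", {
  ld <- fixture("grad_ld", function()
    simulate_ld_summaries(scenario("constant"), 50, tiny_genome(6, 5),
                          seed = 3))
  cfg_inf <- fit_config(seed = 1, lambda = 1e9, power = 1)
  fit_inf <- fit_map(ld, cfg_inf)
  tr <- ne_at(fit_inf$map_model, 1:125)
  # first differences crushed: the trajectory is flat in log space
  expect_lt(max(abs(diff(log(tr)))), 1e-3)
  fd <- recne:::build_fit_data(ld, NULL, cfg_inf)
  const <- recne:::constant_pilot(fd, cfg_inf)
  expect_equal(geomean(tr), exp(const$log_ne[1]), tolerance = 0.05)
})

test_that("power selection tracks residual bin correlation", {
  set.seed(6)
  m <- scenario("constant")
  u_cm <- seq(0.75, 29.75, by = 0.5)
  mu <- expected_ld(m, u_cm, 100)
  mk <- function(noise_per_region) {
    df <- do.call(rbind, lapply(seq_along(noise_per_region), function(i)
      data.frame(region = sprintf("r%02d", i), bin_lo = u_cm - 0.25,
                 bin_hi = u_cm + 0.25, y = mu + noise_per_region[[i]],
                 n_pairs = 500, var = 1e-8)))
    binned_ld(df, n_eff = 100, ploidy = "diploid")
  }
  sd0 <- 2e-4
  # independent bins: c = 1
  indep <- mk(lapply(1:8, function(i) rnorm(length(u_cm), 0, sd0)))
  expect_equal(select_power(indep, fit_config(), model = m), 1)
  # duplicated bins (each noise value repeated twice): c = 1/2
  dup <- mk(lapply(1:8, function(i)
    rep(rnorm(ceiling(length(u_cm) / 2), 0, sd0),
        each = 2)[seq_along(u_cm)]))
  expect_equal(select_power(dup, fit_config(), model = m), 0.5,
               tolerance = 0.3)
  # fully correlated region (one shared level shift): c -> 1/n_bins
  flat <- mk(lapply(1:8, function(i) rep(rnorm(1, 0, sd0), length(u_cm))))
  expect_equal(select_power(flat, fit_config(), model = m),
               1 / length(u_cm), tolerance = 1e-9)
})

test_that("IBD dispersion estimates track the simulated overdispersion", {
  m <- scenario("bottleneck")
  gen <- synthetic_genome(39, 36.23)
  gm <- genome_map(gen)
  n_pairs <- 2000
  # Poisson data: dispersion concentrates near 1
  phis <- c()
  for (s in 1:6) {
    segs <- simulate_pairwise_ibd(m, n_pairs, gen, seed = 50 + s)
    h <- build_ibd_histogram(segs, gm, n_pairs = n_pairs)
    phi <- estimate_dispersion_ibd(h, m)
    keep <- tapply(h$count, h$bin_lo, sum) > 200
    phis <- c(phis, phi[keep])
  }
  # the max(1, .) floor lifts the null mean slightly above 1
  expect_gt(mean(phis), 0.95)
  expect_lt(mean(phis), 1.18)
  # doubling counts by duplicating each segment gives variance 2 mu
  segs <- simulate_pairwise_ibd(m, n_pairs, gen, seed = 77)
  h2 <- build_ibd_histogram(rbind(segs, segs), gm, n_pairs = 2 * n_pairs)
  phi2 <- estimate_dispersion_ibd(h2, m)
  keep <- tapply(h2$count, h2$bin_lo, sum) > 400
  expect_equal(mean(phi2[keep]), 2, tolerance = 0.25)
  # single region: dispersion 1 by convention
  one <- subset_regions(h, names(attr(h, "region_lengths"))[1])
  expect_true(all(estimate_dispersion_ibd(one, m) == 1))
})

test_that("fits are deterministic given the seed", {
  ld <- constant_ld_20(seed = 42)
  f1 <- fit_map(ld, fit_config(seed = 9))
  f2 <- fit_map(ld, fit_config(seed = 9))
  expect_identical(f1$map_model$log_ne, f2$map_model$log_ne)
  expect_identical(f1$diagnostics$lambda, f2$diagnostics$lambda)
})

test_that("bootstrap bands behave correctly in the degenerate cases", {
  u_cm <- seq(0.75, 29.75, by = 0.5)
  m <- scenario("constant")
  mu <- expected_ld(m, u_cm, 100)
  df <- do.call(rbind, lapply(sprintf("r%02d", 1:5), function(r)
    data.frame(region = r, bin_lo = u_cm - 0.25, bin_hi = u_cm + 0.25,
               y = mu, n_pairs = 500, var = 1e-8)))
  ld <- binned_ld(df, n_eff = 100, ploidy = "diploid")
  cfg <- fit_config(seed = 3, n_bootstrap = 8, lambda = 10, power = 1)
  post <- bootstrap_ci(ld, cfg)
  # identical regions: resampling changes nothing, bands have zero width
  expect_lt(max(post$quantiles$q97.5 / post$quantiles$q2.5) - 1, 1e-6)
  expect_true(all(post$quantiles$q2.5 <= post$quantiles$q25 &
                    post$quantiles$q25 <= post$quantiles$q75 &
                    post$quantiles$q75 <= post$quantiles$q97.5))
  # a single bootstrap replicate pins all four quantiles to it
  cfg1 <- fit_config(seed = 4, n_bootstrap = 1, lambda = 10, power = 1)
  ld2 <- constant_ld_20(seed = 13)
  post1 <- bootstrap_ci(ld2, cfg1)
  expect_equal(post1$quantiles$q2.5, post1$quantiles$q97.5)
  expect_equal(length(post1$boot_models), 1)
})

test_that("bootstrap bands cover a constant truth at generation 25", {
  hits <- 0; n_data <- 6
  for (s in seq_len(n_data)) {
    ld <- simulate_ld_summaries(scenario("constant"), 100,
                                synthetic_genome(12, 11), seed = 880 + s)
    cfg <- fit_config(seed = s, n_bootstrap = 30)
    post <- bootstrap_ci(ld, cfg)
    q <- post$quantiles[post$quantiles$generation == 25, ]
    hits <- hits + (q$q2.5 <= 20000 && 20000 <= q$q97.5)
  }
  expect_gte(hits, n_data - 1)
})

test_that("LD and IBD modes agree on oracle data from one demography", {
  gen <- synthetic_genome(20, 18)
  for (nm in c("constant", "collapse")) {
    m <- scenario(nm)
    ld <- simulate_ld_summaries(m, 100, gen, seed = 321)
    fit_ld <- fit_map(ld, fit_config(seed = 1))
    segs <- simulate_pairwise_ibd(m, 2e4, gen, seed = 321)
    h <- build_ibd_histogram(segs, genome_map(gen), n_pairs = 2e4)
    fit_ibd <- fit_map(h, fit_config(seed = 1))
    expect_lt(rmsle(fit_ld$map_model, fit_ibd$map_model), 0.35)
  }
})

test_that("stronger LD signal never raises the inferred recent size", {
  ld <- constant_ld_20(seed = 66)
  beta <- attr(ld, "baseline")$beta
  boost <- as.data.frame(ld)
  boost$y <- beta + (boost$y - beta) * 1.6       # scale signal above baseline
  ld_hi <- binned_ld(boost, n_eff = attr(ld, "n_eff"),
                     ploidy = attr(ld, "ploidy"))
  f_lo <- fit_map(ld, fit_config(seed = 2, power = 1, lambda = 100))
  f_hi <- fit_map(ld_hi, fit_config(seed = 2, power = 1, lambda = 100))
  hm <- function(m) 1 / mean(1 / ne_at(m, 1:50))
  expect_lt(hm(f_hi$map_model), hm(f_lo$map_model))
})
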