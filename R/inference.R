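#' Fit configuration
#'
#' Collects the tunable parameters of the trajectory fit.
#'
#' @param t_max trajectory horizon in generations (default 125; the size
#'   is constant beyond it).
#' @param n_intervals number of piecewise-exponential time intervals
#'   (default 16; knot placement is adapted to the data-bearing epochs).
#' @param power likelihood exponent `c` in (0, 1], or `"auto"` to tune it
#'   from residual autocorrelation (see [select_power()]).
#' @param lambda regularisation strength for the squared first differences
#'   of log N_e, or `"auto"` for cross-validated selection over
#'   `lambda_grid`.
#' @param lambda_grid candidate regularisation strengths.
#' @param n_bootstrap bootstrap replicates for confidence bands.
#' @param ne_bounds allowed haploid size range.
#' @param horizon coalescent truncation horizon (default `10 * t_max`).
#' @param n_folds folds for the region-held-out lambda score.
#' @param seed master seed (fans out to folds and bootstrap replicates).
#' @param optim_control passed to [stats::optim()].
#' @return a list of class `fit_config`.
#' @export
fit_config <- function(t_max = 125, n_intervals = 16, power = "auto",
                       lambda = "auto",
                       lambda_grid = 10^seq(-2, 3, by = 1),
                       n_bootstrap = 100, ne_bounds = c(10, 1e8),
                       horizon = NULL, n_folds = 5, seed = 1,
                       optim_control = list(maxit = 300)) {
  if (!identical(power, "auto")) {
    if (!is.numeric(power) || power <= 0 || power > 1)
      stop_input("'power' must be in (0, 1] or \"auto\"")
  }
  if (n_bootstrap < 1) stop_input("'n_bootstrap' must be >= 1")
  structure(list(t_max = t_max, n_intervals = n_intervals, power = power,
                 lambda = lambda, lambda_grid = lambda_grid,
                 n_bootstrap = n_bootstrap, ne_bounds = ne_bounds,
                 horizon = horizon %||% (10 * t_max), n_folds = n_folds,
                 seed = seed, optim_control = optim_control),
            class = "fit_config")
}

## ---- internal fit data layout ------------------------------------------

# Reshape summary objects into matrices shared by the objective builders.
build_fit_data <- function(data, ages = NULL, config = fit_config()) {
  if (inherits(data, "binned_ld")) {
    bins <- sort(unique(data$bin_lo))
    regions <- unique(data$region)
    Y <- matrix(NA_real_, length(regions), length(bins),
                dimnames = list(regions, as.character(bins)))
    Y[cbind(data$region, as.character(data$bin_lo))] <- data$y
    width <- stats::median(data$bin_hi - data$bin_lo)
    u <- (bins + width / 2) / 100                      # Morgans
    ok_bin <- colSums(!is.na(Y)) >= 2
    Y <- Y[, ok_bin, drop = FALSE]; u <- u[ok_bin]
    sigma2 <- apply(Y, 2, stats::var, na.rm = TRUE)
    # reported within-bin variances act as a floor: if regions happen to
    # agree closely the weights must not blow up
    rep_var <- tapply(data$var, data$bin_lo, stats::median, na.rm = TRUE)
    rep_var <- rep_var[as.character(bins[ok_bin])]
    rep_var[is.na(rep_var)] <- 0
    floor_s <- stats::median(sigma2, na.rm = TRUE) * 1e-3
    sigma2 <- pmax(sigma2, rep_var, max(floor_s, 1e-16, na.rm = TRUE))
    names(sigma2) <- colnames(Y)
    bl <- attr(data, "baseline")
    dens <- if (is.null(ages)) NULL else
      if (inherits(ages, "pair_age_density")) ages else pair_age_density(ages)
    list(type = "ld", Y = Y, u = u, sigma2 = sigma2, beta = bl$beta,
         regions = regions, n_bins = ncol(Y), density = dens)
  } else if (inherits(data, "ibd_histogram")) {
    if (!is.null(ages))
      warning("sample ages are only modelled for LD data; ignoring them")
    bins <- sort(unique(data$bin_lo))
    lens <- attr(data, "region_lengths")
    regions <- names(lens)
    Y <- matrix(0, length(regions), length(bins),
                dimnames = list(regions, as.character(bins)))
    Y[cbind(data$region, as.character(data$bin_lo))] <- data$count
    width <- stats::median(data$bin_hi - data$bin_lo)
    edges <- c(bins, max(bins) + width) / 100          # Morgans
    off <- lens[regions] * attr(data, "n_pairs")
    list(type = "ibd", Y = Y, edges = edges, off = as.numeric(off),
         regions = regions, n_bins = ncol(Y),
         phi2 = stats::setNames(rep(1, ncol(Y)), colnames(Y)),
         density = NULL)
  } else stop_input("'data' must be a binned_ld or ibd_histogram object")
}

# Linear-interpolation weight matrix mapping knot values of log N_e to
# per-generation values (constant beyond t_max).
interp_matrix <- function(grid_times, horizon) {
  K <- length(grid_times)
  g <- pmin(seq_len(horizon), grid_times[K])
  W <- matrix(0, horizon, K)
  iv <- findInterval(g, grid_times, rightmost.closed = TRUE)
  iv <- pmin(iv, K - 1L)
  frac <- (g - grid_times[iv]) / (grid_times[iv + 1L] - grid_times[iv])
  W[cbind(seq_len(horizon), iv)] <- 1 - frac
  W[cbind(seq_len(horizon), iv + 1L)] <- frac
  W
}

# Model components: list of (M [B x G], start_gen, weight) such that the
# demography-driven mean is sum_c weight_c * (M_c %*% q_c) with q_c the
# coalescence pmf restricted to generations > start_gen.
build_components <- function(fd, config) {
  G <- config$horizon
  g <- seq_len(G)
  if (fd$type == "ibd") {
    br <- 2 * g
    E <- exp(-outer(fd$edges, br))
    M <- sweep(E[-length(fd$edges), , drop = FALSE] -
                 E[-1, , drop = FALSE], 2, br, "*")
    return(list(list(M = M, start = 0L, weight = 1)))
  }
  if (is.null(fd$density)) {
    M <- exp(-outer(fd$u, 2 * g))
    return(list(list(M = M, start = 0L, weight = 1)))
  }
  comps <- list()
  for (a in unique(fd$density$a_old)) {
    sel <- fd$density$a_old == a
    wa <- sum(fd$density$weight[sel])
    gapfac <- as.vector(exp(-outer(fd$u, fd$density$gap[sel])) %*%
                          (fd$density$weight[sel] / wa))
    M <- exp(-outer(fd$u, pmax(2 * g - 2 * a, 0))) * gapfac
    M[, g <= a] <- 0
    comps[[length(comps) + 1L]] <- list(M = M, start = as.integer(a),
                                        weight = wa)
  }
  comps
}

# The pseudo-posterior core: value and gradient of
#   c * nll(Y | mu(theta)) + lambda * sum(diff(theta)^2)
# for theta = log N_e at the grid knots.
make_objective <- function(fd, grid_times, config, power = 1, lambda = 0) {
  W <- interp_matrix(grid_times, config$horizon)
  comps <- build_components(fd, config)
  G <- config$horizon
  cache <- new.env(parent = emptyenv())
  evaluate <- function(theta, want_grad = TRUE) {
    a_log <- as.vector(W %*% theta)
    h_full <- exp(-a_log)
    h_full <- pmin(h_full, 0.5)       # N_e >= 2 inside the optimiser
    p <- numeric(length(comps[[1]]$M[, 1]))
    qs <- vector("list", length(comps))
    for (ci in seq_along(comps)) {
      cmp <- comps[[ci]]
      h <- h_full
      if (cmp$start > 0L) h[seq_len(cmp$start)] <- 0
      S <- cumprod(1 - h)
      q <- h * c(1, S[-G])
      qs[[ci]] <- list(q = q, h = h)
      p <- p + cmp$weight * as.vector(cmp$M %*% q)
    }
    if (fd$type == "ld") {
      mu <- fd$beta + (1 - fd$beta) * p
      R <- sweep(fd$Y, 2, mu)                          # residuals
      nll <- sum(R^2 / rep(2 * fd$sigma2, each = nrow(fd$Y)), na.rm = TRUE)
      dmu <- -colSums(R, na.rm = TRUE) / fd$sigma2
      dp <- dmu * (1 - fd$beta)
    } else {
      p <- pmax(p, 1e-300)
      MU <- outer(fd$off, p)
      Ypos <- fd$Y
      nll <- sum((ifelse(Ypos > 0, Ypos * log(Ypos / MU), 0) -
                    (Ypos - MU)) / rep(fd$phi2, each = nrow(fd$Y)))
      dmu_ib <- (1 - fd$Y / MU) / rep(fd$phi2, each = nrow(fd$Y))
      dp <- colSums(dmu_ib * fd$off)
    }
    d <- diff(theta)
    value <- power * nll + lambda * sum(d^2)
    if (!want_grad) return(list(value = value))
    da <- numeric(G)
    for (ci in seq_along(comps)) {
      cmp <- comps[[ci]]
      q <- qs[[ci]]$q; h <- qs[[ci]]$h
      tvec <- cmp$weight * as.vector(crossprod(cmp$M, dp))
      tq <- tvec * q
      Cm <- rev(cumsum(rev(tq))) - tq                  # sum over g > m
      da <- da + (-tq + h * Cm / (1 - h))
    }
    # da is d(nll)/d(log N_e at generation m): the chain rule through
    # h = e^{-a} contributes the -h factor already folded in above
    grad <- power * as.vector(crossprod(W, da)) +
      2 * lambda * (c(0, d) - c(d, 0))
    list(value = value, grad = grad)
  }
  get_both <- function(theta) {
    key <- cache$theta
    if (!is.null(key) && identical(key, theta)) return(cache$res)
    res <- evaluate(theta)
    cache$theta <- theta; cache$res <- res
    res
  }
  list(
    fn = function(theta) get_both(theta)$value,
    gr = function(theta) get_both(theta)$grad,
    value_only = function(theta) evaluate(theta, want_grad = FALSE)$value,
    components = comps, W = W, fd = fd
  )
}

#' Negative log pseudo-posterior of a trajectory
#'
#' Evaluates \eqn{c \sum_{i,b} \mathrm{nll}(Y_{i,b} \mid \mu(\theta)) +
#' \lambda \sum_k (\Delta_k \log N_e)^2} for a piecewise-exponential model
#' (Normal likelihood for LD data, quasi-Poisson deviance for IBD counts).
#'
#' @param model a [demographic_model()]; its grid carries the parameters.
#' @param data a [binned_ld()] or IBD histogram.
#' @param config a [fit_config()].
#' @param ages optional [sample_age_table()] (LD only).
#' @param power,lambda likelihood exponent and penalty strength.
#' @return a scalar objective value.
#' @export
neg_log_pseudo_posterior <- function(model, data, config = fit_config(),
                                     ages = NULL, power = 1, lambda = 0) {
  fd <- build_fit_data(data, ages, config)
  obj <- make_objective(fd, model$grid_times, config, power, lambda)
  v <- obj$fn(model$log_ne)
  if (!is.finite(v)) warning("non-finite objective")
  v
}

## ---- hyperparameters ----------------------------------------------------

#' Estimate per-bin overdispersion of IBD counts
#'
#' Quasi-likelihood dispersion factors: for each length bin,
#' \eqn{\phi^2_b = \max(1, X^2_b / (n_{regions} - 1))} where \eqn{X^2_b}
#' is the Pearson statistic of the observed counts around the model means
#' \eqn{\mu_b L_i n_{pairs}}.  With a single region the dispersion is 1 by
#' convention.
#'
#' @param hist an IBD histogram.
#' @param model a fitted or pilot [demographic_model()].
#' @param config a [fit_config()].
#' @return numeric vector of per-bin dispersion factors.
#' @export
estimate_dispersion_ibd <- function(hist, model, config = fit_config()) {
  fd <- build_fit_data(hist, NULL, config)
  comps <- build_components(fd, config)
  cp <- coalescent_pmf(model, config$horizon)
  p <- as.vector(comps[[1]]$M %*% cp$pmf)
  MU <- outer(fd$off, pmax(p, 1e-300))
  n_r <- nrow(fd$Y)
  if (n_r < 2L)
    return(stats::setNames(rep(1, ncol(fd$Y)), colnames(fd$Y)))
  X2 <- colSums((fd$Y - MU)^2 / MU)
  stats::setNames(pmax(1, X2 / (n_r - 1)), colnames(fd$Y))
}

#' Select the power-likelihood exponent
#'
#' The exponent `c` discounts correlation between the distance/length bins
#' of a region.  It is estimated from the mean absolute lag-1
#' autocorrelation \eqn{\bar\rho} of the standardized within-region
#' residuals under a pilot fit: the effective number of independent bins
#' is taken as \eqn{n_{bins} (1 - \bar\rho)}, giving \eqn{c = 1 -
#' \bar\rho}, snapped to the candidate grid
#' \eqn{\{1, 1/2, 1/4, \ldots, 1/n_{bins}\}}.
#'
#' @param data a [binned_ld()] or IBD histogram.
#' @param config a [fit_config()].
#' @param model pilot model (default: the moment-matched constant fit).
#' @param ages optional age table (LD only).
#' @return the selected exponent.
#' @export
select_power <- function(data, config = fit_config(), model = NULL,
                         ages = NULL) {
  fd <- build_fit_data(data, ages, config)
  if (is.null(model)) model <- constant_pilot(fd, config)
  comps <- build_components(fd, config)
  cp_list <- lapply(comps, function(cmp)
    coalescent_pmf(model, config$horizon, start_gen = cmp$start))
  p <- Reduce(`+`, Map(function(cmp, cp) cmp$weight *
                         as.vector(cmp$M %*% cp$pmf), comps, cp_list))
  if (fd$type == "ld") {
    mu <- fd$beta + (1 - fd$beta) * p
    R <- sweep(fd$Y, 2, mu)
    R <- sweep(R, 2, sqrt(fd$sigma2), "/")
  } else {
    MU <- outer(fd$off, pmax(p, 1e-300))
    R <- (fd$Y - MU) / sqrt(MU * rep(fd$phi2, each = nrow(fd$Y)))
  }
  # lag-1 correlation of residuals at adjacent bins, pooled over regions
  # (a shared level shift within regions then shows up as correlation ~1,
  # which per-region centred autocorrelations would miss)
  x <- as.vector(R[, -ncol(R), drop = FALSE])
  y <- as.vector(R[, -1, drop = FALSE])
  ok <- !is.na(x) & !is.na(y)
  rho_bar <- if (sum(ok) > 2 && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0)
    abs(stats::cor(x[ok], y[ok])) else 0
  if (!is.finite(rho_bar)) rho_bar <- 0
  c_raw <- max(1 - rho_bar, 1 / fd$n_bins)
  grid <- 2^-(0:ceiling(log2(fd$n_bins)))
  grid <- pmax(grid, 1 / fd$n_bins)
  grid[which.min(abs(log(grid) - log(c_raw)))]
}

# Moment-matched constant model: 1-D likelihood search over log N.
constant_pilot <- function(fd, config) {
  gt <- c(0, config$t_max)
  obj <- make_objective(fd, gt, config, power = 1, lambda = 0)
  f <- function(ln) obj$value_only(rep(ln, 2))
  opt <- stats::optimize(f, log(config$ne_bounds))
  demographic_model(gt, rep(exp(opt$minimum), 2), config$t_max)
}

# Best single-exponential model (2 parameters: log sizes at 0 and t_max).
exponential_pilot <- function(fd, config, start = NULL) {
  gt <- c(0, config$t_max)
  obj <- make_objective(fd, gt, config, power = 1, lambda = 0)
  st <- start %||% rep(log(2e4), 2)
  opt <- stats::optim(st, fn = obj$fn, gr = obj$gr, method = "L-BFGS-B",
                      lower = log(config$ne_bounds[1]),
                      upper = log(config$ne_bounds[2]),
                      control = list(maxit = 200))
  demographic_model(gt, exp(opt$par), config$t_max)
}

# Cross-validated regularisation strength: regions are split into folds;
# each candidate lambda is scored by the held-out unpenalised likelihood
# of the model fitted on the remaining regions.  Because the held-out
# score discriminates weakly exactly when the data carry little
# information about recent fluctuations, the one-standard-error rule is
# applied: the largest (most regularised) lambda whose score is within
# one SE of the minimum is selected, which favours models with minimal
# population-size fluctuations unless the data demand them.
select_lambda <- function(fd, grid_times, config, power, start_theta) {
  regions <- seq_len(nrow(fd$Y))
  n_folds <- min(config$n_folds, length(regions))
  if (n_folds < 2) return(stats::median(config$lambda_grid))
  folds <- with_local_seed(config$seed + 31L,
    sample(rep(seq_len(n_folds), length.out = length(regions))))
  scores <- matrix(NA_real_, length(config$lambda_grid), n_folds)
  for (li in seq_along(config$lambda_grid)) {
    lam <- config$lambda_grid[li]
    for (f in seq_len(n_folds)) {
      tr <- subset_fd(fd, regions[folds != f])
      te <- subset_fd(fd, regions[folds == f])
      obj_tr <- make_objective(tr, grid_times, config, power, lam)
      fit <- stats::optim(start_theta, fn = obj_tr$fn, gr = obj_tr$gr,
                          method = "L-BFGS-B",
                          lower = log(config$ne_bounds[1]),
                          upper = log(config$ne_bounds[2]),
                          control = config$optim_control)
      obj_te <- make_objective(te, grid_times, config, 1, 0)
      scores[li, f] <- obj_te$value_only(fit$par)
    }
  }
  # Walk down from the most regularised candidate; adopt a smaller
  # lambda only when its held-out improvement is significant in a paired
  # one-sided t-test across folds (5% level).  Recent generations are
  # weakly identified, so the default is the smoothest model and the data
  # must earn additional flexibility.
  ord <- order(config$lambda_grid, decreasing = TRUE)
  cur <- ord[1]
  tcrit <- stats::qt(0.95, n_folds - 1)
  for (li in ord[-1]) {
    imp <- scores[cur, ] - scores[li, ]
    se <- stats::sd(imp) / sqrt(n_folds)
    if (se == 0) next
    if (mean(imp) / se > tcrit) cur <- li
  }
  config$lambda_grid[cur]
}

subset_fd <- function(fd, idx) {
  out <- fd
  out$Y <- fd$Y[idx, , drop = FALSE]
  if (fd$type == "ibd") out$off <- fd$off[idx]
  out$regions <- fd$regions[idx]
  out
}

## ---- MAP fit and bootstrap ---------------------------------------------

#' Maximum a posteriori trajectory fit
#'
#' Fits a piecewise-exponential \eqn{N_e(t)} to binned LD or IBD summary
#' data by bounded quasi-Newton optimisation of the regularised power
#' likelihood.  The fit proceeds in stages: a moment-matched constant and
#' a best single-exponential model provide starting points; IBD
#' dispersions, the power exponent and the regularisation strength are
#' tuned on a pilot fit; the time grid is re-adapted once so that each
#' interval carries an equal share of expected segment ancestors; and the
#' final model is refitted on the adapted grid.  Everything is
#' deterministic given the configuration seed.
#'
#' @param data a [binned_ld()] or IBD histogram (already region-filtered).
#' @param config a [fit_config()].
#' @param ages optional [sample_age_table()] for time-heterogeneous LD
#'   panels.
#' @return an object of class `ne_posterior` holding `map_model` and a
#'   `diagnostics` list (`power`, `lambda`, `objective`, `convergence`,
#'   dispersion/variance vectors); bootstrap bands are added by
#'   [bootstrap_ci()].
#' @export
fit_map <- function(data, config = fit_config(), ages = NULL) {
  fd <- build_fit_data(data, ages, config)
  ## stage 1: pilots on the 2-knot grid
  const <- constant_pilot(fd, config)
  expo <- exponential_pilot(fd, config, start = const$log_ne)
  ## stage 2: dispersion from the better pilot (IBD)
  pilot <- expo
  if (fd$type == "ibd") {
    fd$phi2 <- estimate_dispersion_ibd(data, pilot, config)
  }
  ## stage 3: hyperparameters
  power <- if (identical(config$power, "auto"))
    select_power(data, config, model = pilot, ages = ages) else config$power
  grid0 <- adapt_time_grid_from(pilot, config)
  theta0 <- ne_at(pilot, grid0)
  start_theta <- log(theta0)
  lambda <- if (identical(config$lambda, "auto"))
    select_lambda(fd, grid0, config, power, start_theta) else config$lambda
  ## stage 4: fit, re-grid once, refit
  fit1 <- optimize_theta(fd, grid0, config, power, lambda, start_theta,
                         alt_starts = list(rep(const$log_ne[1],
                                               length(start_theta))))
  model1 <- demographic_model(grid0, exp(fit1$par), config$t_max)
  grid1 <- adapt_time_grid_from(model1, config)
  fit2 <- optimize_theta(fd, grid1, config, power, lambda,
                         log(ne_at(model1, grid1)))
  map_model <- demographic_model(grid1, exp(fit2$par), config$t_max)
  diagnostics <- list(power = power, lambda = lambda,
                      objective = fit2$value,
                      convergence = fit2$convergence,
                      converged = fit2$convergence == 0,
                      grid_times = grid1,
                      sigma2 = if (fd$type == "ld") fd$sigma2 else NULL,
                      phi2 = if (fd$type == "ibd") fd$phi2 else NULL,
                      n_regions = nrow(fd$Y), type = fd$type)
  if (!diagnostics$converged)
    warning("optimiser did not report convergence; best model returned")
  structure(list(map_model = map_model, boot_models = NULL,
                 quantiles = NULL, diagnostics = diagnostics,
                 config = config, ages = ages),
            class = "ne_posterior")
}

# Equal-segment-ancestor grid for the configured interval count.
adapt_time_grid_from <- function(model, config) {
  m <- adapt_time_grid(model, config$n_intervals,
                       u_min = 0.02, max_rounds = 5)
  m$grid_times
}

optimize_theta <- function(fd, grid_times, config, power, lambda,
                           start_theta, alt_starts = NULL) {
  obj <- make_objective(fd, grid_times, config, power, lambda)
  run <- function(st) {
    stats::optim(st, fn = obj$fn, gr = obj$gr, method = "L-BFGS-B",
                 lower = log(config$ne_bounds[1]),
                 upper = log(config$ne_bounds[2]),
                 control = config$optim_control)
  }
  best <- run(start_theta)
  for (st in alt_starts %||% list()) {
    st <- rep_len(st, length(start_theta))
    cand <- try(run(st), silent = TRUE)
    if (!inherits(cand, "try-error") && cand$value < best$value)
      best <- cand
  }
  list(par = best$par, value = best$value, convergence = best$convergence)
}

#' Chromosome-arm bootstrap confidence bands
#'
#' Resamples the regions of the input data with replacement, refits the
#' trajectory with the time grid, power exponent, dispersion and
#' regularisation frozen at the values of the point fit, and reports the
#' 2.5/25/75/97.5 percentiles of \eqn{N_e(t)} at every generation (50% and
#' 95% bands).  Replicates are seeded from the master seed; isolated
#' replicate failures (up to 10%) are tolerated and recorded.
#'
#' @param data the summary object passed to [fit_map()].
#' @param config a [fit_config()].
#' @param ages optional age table (LD only).
#' @param fit an existing [fit_map()] result (computed if omitted).
#' @return the `ne_posterior` with `boot_models` and `quantiles` filled;
#'   `quantiles` is a data.frame (generation, ne_map, q2.5, q25, q75,
#'   q97.5).
#' @export
bootstrap_ci <- function(data, config = fit_config(), ages = NULL,
                         fit = NULL) {
  fit <- fit %||% fit_map(data, config, ages)
  diag <- fit$diagnostics
  grid_times <- diag$grid_times
  start_theta <- fit$map_model$log_ne
  regions <- if (inherits(data, "binned_ld")) unique(data$region) else
    names(attr(data, "region_lengths"))
  seeds <- derive_seeds(config$seed, config$n_bootstrap)
  boot <- vector("list", config$n_bootstrap)
  failures <- 0L
  for (r in seq_len(config$n_bootstrap)) {
    pick <- with_local_seed(seeds[r],
      sample(regions, length(regions), replace = TRUE))
    rep_data <- subset_regions(data, pick)
    res <- try({
      fd <- build_fit_data(rep_data, ages, config)
      if (fd$type == "ld") {
        frozen <- diag$sigma2[colnames(fd$Y)]
        fd$sigma2 <- ifelse(is.na(frozen), fd$sigma2, frozen)
      } else {
        frozen <- diag$phi2[colnames(fd$Y)]
        fd$phi2 <- ifelse(is.na(frozen), fd$phi2, frozen)
      }
      opt <- optimize_theta(fd, grid_times, config, diag$power,
                            diag$lambda, start_theta)
      demographic_model(grid_times, exp(opt$par), config$t_max)
    }, silent = TRUE)
    if (inherits(res, "try-error")) failures <- failures + 1L
    else boot[[r]] <- res
  }
  boot <- boot[!vapply(boot, is.null, logical(1))]
  if (failures > 0.1 * config$n_bootstrap)
    stop_input(failures, " of ", config$n_bootstrap,
               " bootstrap replicates failed")
  gens <- seq_len(config$t_max)
  NE <- vapply(boot, function(m) ne_at(m, gens), numeric(length(gens)))
  qs <- apply(NE, 1, stats::quantile,
              probs = c(0.025, 0.25, 0.75, 0.975), names = FALSE)
  fit$boot_models <- boot
  fit$quantiles <- data.frame(generation = gens,
                              ne_map = ne_at(fit$map_model, gens),
                              q2.5 = qs[1, ], q25 = qs[2, ],
                              q75 = qs[3, ], q97.5 = qs[4, ])
  fit$diagnostics$bootstrap_failures <- failures
  fit
}

#' @export
print.ne_posterior <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("Recent N_e fit (%s data): %d regions, c = %.3g, lambda = %.3g%s\n",
              d$type, d$n_regions, d$power, d$lambda,
              if (!d$converged) " [convergence warning]" else ""))
  gm <- geomean(ne_at(x$map_model, 1:50))
  cat(sprintf("  geometric mean N_e over generations 1-50: %.0f haploids\n", gm))
  if (!is.null(x$quantiles))
    cat(sprintf("  with %d bootstrap replicates (50%% and 95%% bands)\n",
                length(x$boot_models)))
  invisible(x)
}

#' Write a fitted trajectory with confidence bands as TSV
#'
#' @param posterior an `ne_posterior` (after [bootstrap_ci()] for bands;
#'   otherwise the band columns repeat the MAP trajectory).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ne_posterior <- function(posterior, path) {
  q <- posterior$quantiles
  if (is.null(q)) {
    gens <- seq_len(posterior$config$t_max)
    nem <- ne_at(posterior$map_model, gens)
    q <- data.frame(generation = gens, ne_map = nem, q2.5 = nem,
                    q25 = nem, q75 = nem, q97.5 = nem)
  }
  write_tsv(q, path)
}
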