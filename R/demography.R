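#' Piecewise-exponential demographic models
#'
#' A `demog_model` describes a haploid effective population size trajectory
#' \eqn{N_e(t)} over discrete generations before present.  Between
#' consecutive grid times the trajectory is exponential (i.e. \eqn{\log
#' N_e} is linear in \eqn{t}), and beyond `t_max` the size stays constant at
#' its value at `t_max`.  Sizes are expressed in haploid individuals; a
#' diploid census of `N` individuals corresponds to roughly `2 N` haploids.
#'
#' @param times numeric vector of grid times in generations, strictly
#'   increasing, starting at 0 and ending at `t_max`.
#' @param ne positive haploid effective sizes at `times`.
#' @param t_max horizon (generations) after which the size is constant.
#'   Defaults to the last grid time.
#' @return an object of class `demog_model` with fields `grid_times`,
#'   `log_ne` and `t_max`.
#' @examples
#' m <- demographic_model(c(0, 50), c(200000, 20000))
#' ne_at(m, 25)   # geometric midpoint, ~63245.6
#' @export
demographic_model <- function(times, ne, t_max = NULL) {
  times <- as.numeric(times)
  ne <- as.numeric(ne)
  if (length(times) != length(ne) || length(times) < 1L)
    stop_input("'times' and 'ne' must have equal positive length")
  if (any(!is.finite(times)) || any(!is.finite(ne)))
    stop_input("grid times and sizes must be finite")
  if (times[1] != 0)
    stop_input("the first grid time must be 0")
  if (is.unsorted(times, strictly = TRUE))
    stop_input("grid times must be strictly increasing")
  if (any(ne <= 0))
    stop_input("effective sizes must be positive")
  t_max <- t_max %||% times[length(times)]
  if (length(times) == 1L) {           # constant model shorthand
    times <- c(0, t_max)
    ne <- rep(ne, 2L)
  }
  if (abs(times[length(times)] - t_max) > 1e-9)
    stop_input("the last grid time must equal t_max")
  structure(list(grid_times = times, log_ne = log(ne), t_max = t_max),
            class = "demog_model")
}

#' @export
print.demog_model <- function(x, ...) {
  cat(sprintf("Piecewise-exponential demographic model (%d intervals, t_max = %g)\n",
              length(x$grid_times) - 1L, x$t_max))
  show <- unique(round(seq(1, length(x$grid_times), length.out = min(8, length(x$grid_times)))))
  cat(sprintf("  t = %s\n", paste(signif(x$grid_times[show], 4), collapse = ", ")))
  cat(sprintf("  Ne = %s\n", paste(signif(exp(x$log_ne[show]), 4), collapse = ", ")))
  invisible(x)
}

#' Effective size at a set of times
#'
#' Evaluates \eqn{N_e(t)} by exponential (log-linear) interpolation within
#' the model grid; for `t > t_max` the size at `t_max` is returned.
#'
#' @param model a [demographic_model()].
#' @param t vector of times in generations, all `>= 0`.
#' @return numeric vector of haploid effective sizes.
#' @export
ne_at <- function(model, t) {
  stopifnot(inherits(model, "demog_model"))
  t <- as.numeric(t)
  if (any(t < 0)) stop_input("times must be non-negative")
  tt <- pmin(t, model$t_max)
  exp(stats::approx(model$grid_times, model$log_ne, xout = tt,
                    rule = 2)$y)
}

#' Discrete pair coalescence time distribution
#'
#' Probability mass function of the generation at which a random pair of
#' haploid lineages coalesces, under the discrete-generation pair
#' coalescent: \eqn{q(g) = N_e(g)^{-1} \prod_{u<g} (1 - N_e(u)^{-1})}.
#' When `start_gen > 0` the two lineages only co-exist from generation
#' `start_gen` backwards (the situation for a pair of samples whose older
#' member lived `start_gen` generations ago), so the hazard is zero before
#' that point.
#'
#' @param model a [demographic_model()].
#' @param horizon truncation horizon G in generations (`>= t_max`); mass
#'   beyond it is reported as `tail_mass`.  Defaults to `10 * t_max`.
#' @param start_gen first generation at which coalescence is possible.
#' @return a list of class `coal_pmf` with `times` (1..G), `pmf` and
#'   `tail_mass`; `sum(pmf) + tail_mass == 1` up to rounding.
#' @export
coalescent_pmf <- function(model, horizon = NULL, start_gen = 0) {
  stopifnot(inherits(model, "demog_model"))
  horizon <- horizon %||% (10 * model$t_max)
  if (horizon < model$t_max) stop_input("'horizon' must be >= t_max")
  g <- seq_len(horizon)
  ne <- ne_at(model, g)
  if (any(ne <= 1))
    stop_input("invalid model: N_e(t) must exceed 1 at every generation")
  haz <- 1 / ne
  if (start_gen > 0) haz[g <= start_gen] <- 0
  surv <- cumprod(1 - haz)            # P(not coalesced by g)
  pmf <- haz * c(1, surv[-horizon])
  structure(list(times = g, pmf = pmf, tail_mass = surv[horizon]),
            class = "coal_pmf")
}

#' Root mean squared log-error between two trajectories
#'
#' \eqn{\sqrt{ \mathrm{mean}_t (\log \hat N_e(t) - \log N_e(t))^2 }}
#' over integer generations in `t_range` (natural logarithm, default the
#' first 50 generations).
#'
#' @param estimate,truth [demographic_model()] objects.
#' @param t_range integer generations to average over.
#' @return a non-negative scalar.
#' @export
rmsle <- function(estimate, truth, t_range = 1:50) {
  d <- log(ne_at(estimate, t_range)) - log(ne_at(truth, t_range))
  sqrt(mean(d^2))
}

# Expected observable-segment weight per generation: ancestors at
# generation g contribute segments >= u_min (Morgans) at density
# q(g) * 2g * exp(-2 g u_min) per Morgan.
segment_weight <- function(model, u_min = 0.02, horizon = NULL) {
  cp <- coalescent_pmf(model, horizon)
  g <- cp$times
  w <- cp$pmf * 2 * g * exp(-2 * g * u_min)
  list(g = g, w = w)
}

#' Adapt the time discretisation to the data-bearing epochs
#'
#' Re-places the grid knots of a piecewise-exponential model so that each
#' time interval in `(0, t_max]` carries an equal share of the expected
#' ancestors of observable IBD segments, i.e. equal mass of
#' \eqn{w(g) \propto q(g)\, 2g\, e^{-2 g u_{\min}}}.  Values of the input
#' model are re-interpolated onto the new grid.  The knot placement is
#' iterated to a fixed point (largest knot movement below one generation),
#' which in practice takes one or two rounds.
#'
#' @param model a [demographic_model()].
#' @param n_intervals number of intervals (`>= 1`).
#' @param u_min minimum observable segment length in Morgans (default 0.02,
#'   i.e. the 2 cM IBD detection threshold).
#' @param max_rounds upper bound on fixed-point iterations.
#' @return a [demographic_model()] on the adapted grid.
#' @export
adapt_time_grid <- function(model, n_intervals, u_min = 0.02,
                            max_rounds = 5) {
  stopifnot(inherits(model, "demog_model"))
  if (n_intervals < 1) stop_input("'n_intervals' must be >= 1")
  t_max <- model$t_max
  if (n_intervals == 1)
    return(demographic_model(c(0, t_max), ne_at(model, c(0, t_max)),
                             t_max = t_max))
  knots <- seq(0, t_max, length.out = n_intervals + 1)
  cur <- model
  for (round in seq_len(max_rounds)) {
    sw <- segment_weight(cur, u_min)
    keep <- sw$g <= t_max
    g <- sw$g[keep]; w <- sw$w[keep]
    tot <- sum(w)
    if (!is.finite(tot) || tot <= 0 || sum(w > 0) < 2) {
      warning("degenerate segment-ancestor weight; falling back to a uniform grid")
      knots_new <- seq(0, t_max, length.out = n_intervals + 1)
    } else {
      cw <- cumsum(w) / tot
      probs <- seq_len(n_intervals - 1) / n_intervals
      inner <- stats::approx(c(0, cw), c(0, g), xout = probs,
                             ties = "ordered", rule = 2)$y
      knots_new <- c(0, inner, t_max)
      # enforce strict increase with at least 0.5-generation spacing
      for (k in 2:length(knots_new))
        knots_new[k] <- max(knots_new[k], knots_new[k - 1] + 0.5)
      knots_new[length(knots_new)] <- t_max
      knots_new <- knots_new[knots_new <= t_max]
      if (length(knots_new) < n_intervals + 1)
        knots_new <- seq(0, t_max, length.out = n_intervals + 1)
    }
    moved <- max(abs(knots_new - knots))
    knots <- knots_new
    cur <- demographic_model(knots, ne_at(model, knots), t_max = t_max)
    if (moved < 1) break
  }
  cur
}

#' Write / read a demographic model as two-column TSV
#'
#' The on-disk format is one row per integer generation `0..t_max` with
#' columns `generation` and `ne`, which plots directly and round-trips
#' through [read_demography()] (the reading side rebuilds a fine grid).
#'
#' @param model a [demographic_model()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_demography <- function(model, path) {
  t <- 0:model$t_max
  write_tsv(data.frame(generation = t, ne = ne_at(model, t)), path)
}

#' @rdname write_demography
#' @export
read_demography <- function(path) {
  df <- read_tsv(path)
  if (!all(c("generation", "ne") %in% names(df)))
    stop_input("expected columns 'generation' and 'ne' in ", path)
  df <- df[order(df$generation), ]
  demographic_model(df$generation, df$ne)
}
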