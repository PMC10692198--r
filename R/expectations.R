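#' Expected IBD segment density per length bin
#'
#' Under the sequentially Markovian approximation, a pair of haplotypes
#' whose lineages coalesce \eqn{g} generations ago is tiled by IBD
#' segments whose boundaries arrive at rate \eqn{2g} per Morgan, with
#' segment lengths exponential with the same rate.  The expected number of
#' segments per haplotype pair per Morgan with length in
#' \eqn{[u_{lo}, u_{hi})} Morgans is therefore
#' \deqn{\mu_b = \sum_g q(g)\, 2g \left(e^{-2 g u_{lo}} - e^{-2 g
#' u_{hi}}\right),}
#' with \eqn{q(g)} the pair coalescence pmf of the model.  Multiplying by
#' the region length \eqn{L_i} (Morgans) and the number of analysed
#' haplotype pairs gives the Poisson mean of an observed bin count.
#'
#' @param model a [demographic_model()].
#' @param bin_edges increasing vector of bin edges in Morgans (at least 2).
#' @param horizon coalescent truncation horizon (generations).
#' @return numeric vector of per-bin densities (length
#'   `length(bin_edges) - 1`).
#' @export
expected_ibd_density <- function(model, bin_edges, horizon = NULL) {
  bin_edges <- as.numeric(bin_edges)
  if (length(bin_edges) < 2L || is.unsorted(bin_edges))
    stop_input("'bin_edges' must be an increasing vector of length >= 2")
  cp <- coalescent_pmf(model, horizon)
  mu_from_pmf(cp, bin_edges)
}

# Shared kernel: per-bin expected counts per pair per Morgan from a
# coalescence pmf, with per-generation total branch length 'branch'
# (default 2g for contemporaneous pairs).
mu_from_pmf <- function(cp, bin_edges, branch = NULL) {
  g <- cp$times
  branch <- branch %||% (2 * g)
  E <- exp(-outer(bin_edges, branch))          # (edges) x (generations)
  diff_e <- E[-nrow(E), , drop = FALSE] - E[-1, , drop = FALSE]
  as.vector(diff_e %*% (cp$pmf * branch))
}

# P(random haplotype pair unbroken by recombination across u Morgans):
# p_IBD(u) = sum_g q(g) exp(-branch(g) * u).
p_ibd_from_pmf <- function(cp, u, branch = NULL) {
  g <- cp$times
  branch <- branch %||% (2 * g)
  as.vector(exp(-outer(as.numeric(u), branch)) %*% cp$pmf)
}

#' Probability that a haplotype pair is IBD across a distance
#'
#' \eqn{p_{IBD}(u) = \sum_g q(g) e^{-2gu}}: the chance that two random
#' haplotypes descend from a common ancestor with no recombination on
#' either lineage over `u` Morgans.  This is the demography-dependent part
#' of the expected LD curve.
#'
#' @param model a [demographic_model()].
#' @param u distances in Morgans.
#' @param horizon coalescent truncation horizon.
#' @return numeric vector, one value per distance.
#' @export
p_ibd <- function(model, u, horizon = NULL) {
  cp <- coalescent_pmf(model, horizon)
  p_ibd_from_pmf(cp, u)
}

#' Expected binned LD curve
#'
#' The expected mean R-squared at genetic distance \eqn{u} is
#' \deqn{\mu(u) = p_{IBD}(u) + (1 - p_{IBD}(u))\,\beta(n),}
#' where \eqn{\beta(n)} is the finite-sample baseline of the pairwise
#' R-squared estimator under independence (see [ld_baseline()]) for the
#' effective number of samples `n_samples` entering each pairwise sum.
#'
#' @param model a [demographic_model()].
#' @param bin_centers_cm distances in centimorgans.
#' @param n_samples effective number of jointly observed individuals.
#' @param ploidy panel ploidy (drives the baseline).
#' @param horizon coalescent truncation horizon.
#' @return numeric vector of expected mean R-squared per bin.
#' @export
expected_ld <- function(model, bin_centers_cm, n_samples,
                        ploidy = "diploid", horizon = NULL) {
  if (n_samples < 2) stop_input("'n_samples' must be at least 2")
  p <- p_ibd(model, bin_centers_cm / 100, horizon)
  beta <- ld_baseline(n_samples, ploidy)$beta
  p + (1 - p) * beta
}

## ---- sampling-time heterogeneity ---------------------------------------

#' Per-sample age tables
#'
#' Stores, for each sample, an age interval `[lo, hi]` in generations
#' before the reference time (all zeros for a modern panel); ages are
#' treated as uniform over the interval, discretised to integer
#' generations.
#'
#' @param sample_id character vector.
#' @param age_lo,age_hi numeric vectors, `0 <= lo <= hi < Inf`.
#' @return a data.frame of class `sample_age_table`.
#' @export
sample_age_table <- function(sample_id, age_lo, age_hi = age_lo) {
  df <- data.frame(sample_id = as.character(sample_id),
                   age_lo = as.numeric(age_lo),
                   age_hi = as.numeric(age_hi), stringsAsFactors = FALSE)
  if (any(df$age_lo < 0) || any(df$age_hi < df$age_lo) ||
      any(!is.finite(df$age_hi)))
    stop_input("age intervals must satisfy 0 <= lo <= hi < Inf")
  class(df) <- c("sample_age_table", "data.frame")
  df
}

#' Read / write an age table TSV
#'
#' Columns `sample_id`, `age_lo_gen`, `age_hi_gen`.  [years_to_generations()]
#' converts calendar ages to generations with a configurable generation
#' time (default 29 years).
#'
#' @param path file path.
#' @return a [sample_age_table()].
#' @export
read_age_table <- function(path) {
  df <- read_tsv(path, colClasses = c(sample_id = "character"))
  sample_age_table(df$sample_id, df$age_lo_gen, df$age_hi_gen)
}

#' @rdname read_age_table
#' @param ages a [sample_age_table()].
#' @export
write_age_table <- function(ages, path) {
  write_tsv(data.frame(sample_id = ages$sample_id,
                       age_lo_gen = ages$age_lo,
                       age_hi_gen = ages$age_hi), path)
}

#' @rdname read_age_table
#' @param years numeric vector of ages in years.
#' @param generation_time years per generation (default 29).
#' @export
years_to_generations <- function(years, generation_time = 29) {
  years / generation_time
}

#' Age density of a random pair of samples
#'
#' Each sample's age is uniform over its interval (discretised to integer
#' generations); a pair of distinct samples is drawn uniformly.  The
#' density is reported over `(a_old, gap)` where `a_old` is the age of the
#' older sample and `gap = a_old - a_young >= 0` the generation gap.
#'
#' @param ages a [sample_age_table()] with at least 2 samples.
#' @param max_support cap on the number of distinct sample pairs fully
#'   enumerated; beyond it, pairs of age *profiles* (unique intervals) are
#'   enumerated with multiplicity weights, which is exact.
#' @return a data.frame of class `pair_age_density` with columns `a_old`,
#'   `gap`, `weight` (weights sum to 1).
#' @export
pair_age_density <- function(ages, max_support = Inf) {
  stopifnot(inherits(ages, "sample_age_table"))
  if (nrow(ages) < 2L) stop_input("need at least 2 samples")
  lo <- as.integer(round(ages$age_lo)); hi <- as.integer(round(ages$age_hi))
  prof <- paste(lo, hi)
  uq <- !duplicated(prof)
  ulo <- lo[uq]; uhi <- hi[uq]
  cnt <- as.vector(table(factor(prof, levels = prof[uq])))
  K <- length(ulo)
  acc <- new.env(parent = emptyenv())
  add <- function(a_old, gap, w) {
    key <- paste(a_old, gap)
    acc[[key]] <- (acc[[key]] %||% 0) + w
  }
  for (i in seq_len(K)) for (j in i:K) {
    mult <- if (i == j) cnt[i] * (cnt[i] - 1) / 2 else cnt[i] * cnt[j]
    if (mult == 0) next
    ai <- ulo[i]:uhi[i]; aj <- ulo[j]:uhi[j]
    wij <- mult / (length(ai) * length(aj))
    for (a in ai) {
      older <- pmax(a, aj); gap <- abs(a - aj)
      for (k in seq_along(aj)) add(older[k], gap[k], wij)
    }
  }
  keys <- ls(acc)
  parts <- do.call(rbind, strsplit(keys, " "))
  out <- data.frame(a_old = as.integer(parts[, 1]),
                    gap = as.integer(parts[, 2]),
                    weight = vapply(keys, function(k) acc[[k]], numeric(1)))
  out$weight <- out$weight / sum(out$weight)
  out <- out[order(out$a_old, out$gap), ]
  rownames(out) <- NULL
  class(out) <- c("pair_age_density", "data.frame")
  out
}

# p_IBD marginalised over the pair-age density: the older lineage spans
# t - a_old generations, the younger t - a_old + gap, so the total branch
# length separating the haplotypes is 2 t - 2 a_old + gap, and coalescence
# is only possible for t >= a_old.
p_ibd_time_het <- function(model, u, density, horizon = NULL) {
  u <- as.numeric(u)
  out <- numeric(length(u))
  key <- paste(density$a_old)
  for (a in unique(density$a_old)) {
    cp <- coalescent_pmf(model, horizon, start_gen = a)
    sel <- density$a_old == a
    for (k in which(sel)) {
      branch <- pmax(2 * cp$times - 2 * a + density$gap[k], 0)
      out <- out + density$weight[k] * p_ibd_from_pmf(cp, u, branch)
    }
  }
  out
}

#' Expected LD curve under heterogeneous sampling times
#'
#' Marginalises the IBD-survival probability over the age of the older
#' sample and the generation gap of a random pair (see
#' [pair_age_density()]): coalescence for a pair whose older member lived
#' `a_old` generations ago follows the pmf started at `a_old`, and the
#' branch length exposed to recombination is `2t - 2 a_old + gap`.  With
#' all ages zero this reduces exactly to [expected_ld()].
#'
#' @inheritParams expected_ld
#' @param ages a [sample_age_table()] (or a precomputed
#'   `pair_age_density`).
#' @return numeric vector of expected mean R-squared per bin.
#' @export
expected_ld_time_het <- function(model, ages, bin_centers_cm, n_samples,
                                 ploidy = "diploid", horizon = NULL) {
  density <- if (inherits(ages, "pair_age_density")) ages else
    pair_age_density(ages)
  p <- p_ibd_time_het(model, bin_centers_cm / 100, density, horizon)
  beta <- ld_baseline(n_samples, ploidy)$beta
  p + (1 - p) * beta
}
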