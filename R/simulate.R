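#' Simulate pair coalescence times generation by generation
#'
#' Brute-force oracle for [coalescent_pmf()]: each pair of lineages is
#' followed backwards one generation at a time, coalescing at generation
#' `g` with probability `1 / N_e(g)`, independently across pairs.  Pairs
#' that have not coalesced by `horizon` are reported as `NA`.
#'
#' @param model a [demographic_model()].
#' @param n number of pairs.
#' @param horizon last generation simulated (default `10 * t_max`).
#' @param seed RNG seed.
#' @return integer vector of coalescence generations (`NA` = beyond the
#'   horizon).
#' @export
simulate_coalescence_times <- function(model, n, horizon = NULL, seed = 1) {
  horizon <- horizon %||% (10 * model$t_max)
  ne <- ne_at(model, seq_len(horizon))
  if (any(ne <= 1)) stop_input("invalid model: N_e must exceed 1")
  with_local_seed(seed, {
    out <- rep(NA_integer_, n)
    active <- seq_len(n)
    for (g in seq_len(horizon)) {
      if (!length(active)) break
      hit <- stats::runif(length(active)) < 1 / ne[g]
      out[active[hit]] <- g
      active <- active[!hit]
    }
    out
  })
}

# Thinned segment process shared by the IBD and LD simulators: segments
# with coalescence generation g arrive along the genome as a Poisson
# process with per-Morgan rate q(g) * branch(g) * exp(-branch(g) * u_thin)
# and have full length u_thin + Exp(branch(g)).  This reproduces exactly
# the per-Morgan density of segments longer than u_thin implied by the
# renewal tiling of the pair coalescent (stationary convention, no
# arm-edge truncation).
draw_thinned_segments <- function(pmf, branch, u_thin, morgans) {
  w <- pmf * branch * exp(-branch * u_thin)
  lambda <- sum(w) * morgans
  n <- stats::rpois(1L, lambda)
  if (n == 0L) return(data.frame(g = integer(0), len = numeric(0),
                                 pos = numeric(0)))
  gi <- sample.int(length(w), n, replace = TRUE, prob = w)
  data.frame(g = gi,
             len = u_thin + stats::rexp(n, rate = branch[gi]),
             pos = stats::runif(n, 0, morgans))
}

# Resolve per-pair (a_old, gap) classes: modern pairs are a single (0, 0)
# class; with an age table, classes and weights come from the pair-age
# density.
age_classes <- function(model, ages, horizon) {
  if (is.null(ages)) {
    cp <- coalescent_pmf(model, horizon)
    return(list(list(weight = 1, pmf = cp$pmf,
                     branch = 2 * cp$times)))
  }
  dens <- if (inherits(ages, "pair_age_density")) ages else
    pair_age_density(ages)
  out <- list()
  for (a in unique(dens$a_old)) {
    cp <- coalescent_pmf(model, horizon, start_gen = a)
    for (k in which(dens$a_old == a)) {
      br <- pmax(2 * cp$times - 2 * a + dens$gap[k], 1e-9)
      out[[length(out) + 1L]] <- list(weight = dens$weight[k],
                                      pmf = cp$pmf, branch = br)
    }
  }
  out
}

#' Simulate pairwise IBD segment sharing
#'
#' Draws, for every haplotype pair and chromosome arm, the IBD segments
#' longer than `u_min` implied by the pair coalescent under `model`.  In
#' the default `"fast"` mode segments arrive as a thinned marked Poisson
#' process whose per-bin counts match [expected_ibd_density()] exactly in
#' expectation; `"tiling"` mode lays i.i.d. segments end to end along the
#' arm (including the unobservably short ones, so it is only practical for
#' strong recent demographies) and serves as a structurally independent
#' oracle.
#'
#' @param model a [demographic_model()].
#' @param n_pairs number of haplotype pairs.
#' @param genome a data.frame from [synthetic_genome()] (columns `region`,
#'   `chrom`, `arm`, `length_morgans`).
#' @param u_min minimum segment length in Morgans (default 0.02 = 2 cM).
#' @param mode `"fast"` or `"tiling"`.
#' @param ages optional [sample_age_table()] / `pair_age_density`; each
#'   pair draws an (older age, gap) class from it.
#' @param edge `"stationary"` places segment starts uniformly and lets
#'   segments overhang the arm end (the per-Morgan counting convention
#'   matched by [expected_ibd_density()]); `"truncate"` keeps every
#'   segment inside the arm (use for file fixtures; slightly depletes the
#'   longest bins near arm ends).
#' @param horizon coalescent truncation horizon.
#' @param seed RNG seed.
#' @return an `ibd_segments` data.frame (ids `p<k>` with haplotype labels)
#'   with an attribute `coal_times` recording each segment's coalescence
#'   generation.
#' @export
simulate_pairwise_ibd <- function(model, n_pairs, genome = synthetic_genome(),
                                  u_min = 0.02,
                                  mode = c("fast", "tiling"),
                                  ages = NULL,
                                  edge = c("stationary", "truncate"),
                                  horizon = NULL, seed = 1) {
  mode <- match.arg(mode)
  edge <- match.arg(edge)
  horizon <- horizon %||% (10 * model$t_max)
  classes <- age_classes(model, ages, horizon)
  wts <- vapply(classes, `[[`, numeric(1), "weight")
  gm <- genome_map(genome)
  at <- arm_table(gm)
  offs <- stats::setNames(at$cm_lo, at$region)
  with_local_seed(seed, {
    cls <- sample.int(length(classes), n_pairs, replace = TRUE, prob = wts)
    members <- split(seq_len(n_pairs), cls)
    res <- list()
    for (a in seq_len(nrow(genome))) {
      L <- genome$length_morgans[a]
      for (ci in names(members)) {
        cl <- classes[[as.integer(ci)]]
        ids <- members[[ci]]
        if (mode == "fast") {
          # pool the independent Poisson processes of all pairs in the
          # class, then attribute segments to pairs uniformly
          w <- cl$pmf * cl$branch * exp(-cl$branch * u_min)
          n <- stats::rpois(1L, sum(w) * L * length(ids))
          if (n == 0L) next
          gi <- sample.int(length(w), n, replace = TRUE, prob = w)
          len <- u_min + stats::rexp(n, cl$branch[gi])
          pos <- if (edge == "stationary") stats::runif(n, 0, L) else
            stats::runif(n) * pmax(L - len, 0)
          if (edge == "truncate") len <- pmin(len, L)
          seg <- data.frame(g = gi, len = len, pos = pos)
          pair_of <- ids[sample.int(length(ids), n, replace = TRUE)]
        } else {
          seg <- do.call(rbind, lapply(ids, function(k) {
            s <- tile_arm_segments(cl$pmf, cl$branch, L, u_min,
                                   ne_tail = ne_at(model, model$t_max))
            if (!nrow(s)) return(NULL)
            s$pair <- k
            s
          }))
          if (is.null(seg) || !nrow(seg)) next
          pair_of <- seg$pair
        }
        res[[length(res) + 1L]] <- data.frame(
          pair = pair_of, region = genome$region[a],
          chrom = genome$chrom[a], arm = genome$arm[a],
          pos = seg$pos, len = seg$len, g = seg$g)
      }
    }
    if (!length(res)) {
      out <- empty_ibd_segments()
      attr(out, "coal_times") <- integer(0)
      return(out)
    }
    df <- do.call(rbind, res)
    start_cm <- offs[df$region] + df$pos * 100
    out <- data.frame(
      id1 = sprintf("p%06d_a", df$pair), hap1 = "1",
      id2 = sprintf("p%06d_b", df$pair), hap2 = "1",
      chrom = df$chrom, arm = df$arm, region = df$region,
      start_bp = round(start_cm * 1e6),
      end_bp = round((start_cm + df$len * 100) * 1e6),
      start_cm = start_cm, end_cm = start_cm + df$len * 100,
      length_cm = df$len * 100, stringsAsFactors = FALSE)
    rownames(out) <- NULL
    class(out) <- c("ibd_segments", "data.frame")
    attr(out, "coal_times") <- df$g
    attr(out, "n_pairs") <- n_pairs
    out
  })
}

# True renewal tiling: i.i.d. (g, length) segments laid end to end until
# the arm is covered.  Segment coalescence times are drawn with
# probability proportional to q(g) * branch(g) (the length-bias
# correction that makes the locus-wise marginal equal q(g)); mass beyond
# the horizon is represented by a constant-size geometric continuation at
# N_e(t_max).  Structurally independent of the thinned-Poisson fast mode,
# hence usable as its oracle, but slow for weak demographies where the
# mean segment is ~1/(2 E[g]) Morgans.
tile_arm_segments <- function(pmf, branch, morgans, u_min, ne_tail = NULL) {
  G <- length(pmf)
  tail_mass <- max(0, 1 - sum(pmf))
  ne_tail <- ne_tail %||% 2
  # expected branch length of a tail segment: 2 * (G + E[geometric])
  w <- c(pmf * branch, tail_mass * 2 * (G + ne_tail))
  segs_g <- integer(0); segs_len <- numeric(0); covered <- 0
  while (covered < morgans) {
    gi <- sample.int(length(w), 512L, replace = TRUE, prob = w)
    deep <- gi > G
    gg <- gi
    if (any(deep))
      gg[deep] <- G + stats::rgeom(sum(deep), 1 / ne_tail) + 1L
    br <- ifelse(deep, 2 * gg, branch[pmin(gi, G)])
    ln <- stats::rexp(length(gi), rate = br)
    segs_g <- c(segs_g, gg); segs_len <- c(segs_len, ln)
    covered <- covered + sum(ln)
  }
  pos <- cumsum(c(0, segs_len[-length(segs_len)]))
  keep <- pos < morgans & segs_len >= u_min
  data.frame(g = segs_g[keep], len = segs_len[keep], pos = pos[keep])
}

# Genetic map for a synthetic genome: two anchors per arm, arms of one
# chromosome laid out consecutively in cM (centromere at the junction).
#' Genetic map for a synthetic genome layout
#' @param genome a data.frame from [synthetic_genome()].
#' @return a [genetic_map()] with two anchors per arm.
#' @export
genome_map <- function(genome) {
  rows <- list()
  for (ch in unique(genome$chrom)) {
    sub <- genome[genome$chrom == ch, , drop = FALSE]
    off <- 0
    for (r in seq_len(nrow(sub))) {
      L <- sub$length_morgans[r] * 100
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, arm = sub$arm[r], cm = c(off, off + L),
        bp = round(c(off, off + L) * 1e6))
      off <- off + L
    }
  }
  df <- do.call(rbind, rows)
  genetic_map(df$chrom, df$arm, df$bp, df$cm)
}

#' Simulate binned LD summary data
#'
#' Segment-level generator for the LD inference pipeline.  For each
#' chromosome arm, `2 * n_samples` quasi-independent haplotype-pair
#' ancestries are drawn (thinned segment processes as in
#' [simulate_pairwise_ibd()]); the realised fraction of the arm over which
#' a pair remains unbroken across each bin distance gives the genealogical
#' part of the regional LD curve.  A measurement layer then adds the
#' finite-sample baseline of the R-squared estimator: the bin mean of
#' `n_site_pairs` independent estimator draws with mean \eqn{\beta(n)} and
#' standard deviation \eqn{\tau(n)} (see [ld_baseline()]).
#'
#' @param model a [demographic_model()].
#' @param n_samples number of diploid samples the panel emulates.
#' @param genome a [synthetic_genome()] layout.
#' @param window_cm,bin_width_cm distance window and bin width (cM).
#' @param ages optional [sample_age_table()]; pair age classes are drawn
#'   from its pair-age density.
#' @param n_site_pairs effective number of independent site pairs per
#'   region-bin in the measurement layer (default 500).
#' @param ploidy panel type being emulated.
#' @param horizon coalescent truncation horizon.
#' @param seed RNG seed.
#' @return a [binned_ld()] object.
#' @export
simulate_ld_summaries <- function(model, n_samples,
                                  genome = synthetic_genome(),
                                  window_cm = c(0.5, 30),
                                  bin_width_cm = 0.5, ages = NULL,
                                  n_site_pairs = 500,
                                  ploidy = "diploid", horizon = NULL,
                                  seed = 1) {
  horizon <- horizon %||% (10 * model$t_max)
  classes <- age_classes(model, ages, horizon)
  wts <- vapply(classes, `[[`, numeric(1), "weight")
  edges <- seq(window_cm[1], window_cm[2], by = bin_width_cm)
  centers_m <- (edges[-length(edges)] + edges[-1]) / 2 / 100
  u_thin <- window_cm[1] / 100
  n_eff <- n_samples            # beta depends on jointly observed samples
  bl <- ld_baseline(n_eff, ploidy)
  # Effective number of independent pair genealogies behind a regional
  # mean: the O(n^2) haplotype pairs are positively correlated through
  # the shared regional genealogy, so the count grows super-linearly but
  # sub-quadratically in n; n^2/10 gives a between-region coefficient of
  # variation of ~10% at the shortest distances, matching the smooth
  # per-arm LD curves of large panels.
  K <- max(2L * n_samples, ceiling(n_samples^2 / 10))
  with_local_seed(seed, {
    rows <- list()
    for (a in seq_len(nrow(genome))) {
      L <- genome$length_morgans[a]
      cls <- sample.int(length(classes), K, replace = TRUE, prob = wts)
      shares <- matrix(0, K, length(centers_m))
      for (k in seq_len(K)) {
        cl <- classes[[cls[k]]]
        seg <- draw_thinned_segments(cl$pmf, cl$branch, u_thin, L)
        if (!nrow(seg)) next
        shares[k, ] <- colSums(pmax(outer(seg$len, centers_m, "-"), 0)) / L
      }
      ybar <- colMeans(shares)
      gvar <- apply(shares, 2, stats::var) / K
      meas <- stats::rnorm(length(centers_m), mean = bl$beta,
                           sd = bl$tau / sqrt(n_site_pairs))
      y <- ybar + (1 - ybar) * meas
      rows[[length(rows) + 1L]] <- data.frame(
        region = genome$region[a], bin_lo = edges[-length(edges)],
        bin_hi = edges[-1], y = y,
        n_pairs = n_site_pairs,
        var = gvar + (1 - ybar)^2 * bl$tau^2 / n_site_pairs,
        stringsAsFactors = FALSE)
    }
    binned_ld(do.call(rbind, rows), n_eff = n_eff, ploidy = ploidy)
  })
}

#' Pseudo-haploidise a diploid panel
#'
#' Emulates low-coverage ancient-DNA genotyping: at every site of every
#' individual one allele is sampled at random and stored doubled, and the
#' call is set missing with probability `m` (or `m = exp(-coverage)` when
#' a coverage is given, the chance that no read spans the site).
#'
#' @param panel a diploid [genotype_panel()].
#' @param coverage mean sequencing depth C; implies `m = exp(-C)`.
#' @param missingness per-call missing probability in `[0, 1)`.
#' @param seed RNG seed.
#' @return a pseudo-haploid [genotype_panel()].
#' @export
pseudo_haploidize <- function(panel, coverage = NULL, missingness = NULL,
                              seed = 1) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (is.null(missingness) == is.null(coverage))
    stop_input("give exactly one of 'coverage' or 'missingness'")
  m <- missingness %||% exp(-coverage)
  if (m < 0 || m >= 1) stop_input("missingness must be in [0, 1)")
  g <- panel$genotypes
  with_local_seed(seed, {
    out <- g
    het <- !is.na(g) & g == 1L
    out[het] <- 2L * stats::rbinom(sum(het), 1L, 0.5)
    drop <- stats::runif(length(out)) < m
    out[drop] <- NA_integer_
    genotype_panel(out, panel$sites, "pseudo_haploid", panel$sample_ids)
  })
}

#' Sequencing effort implied by a target missingness
#'
#' Under the simple model of a genome of length `genome_length` covered
#' by reads of length `read_length`, the missing fraction after `N` reads
#' is \eqn{m = (1 - L/G)^N}, so reaching missingness `m` across
#' `n_samples` individuals requires
#' \eqn{N = -s \log(m) / z} reads with \eqn{z = -\log(1 - L/G)}.
#'
#' @param missingness target per-site missing probability in (0, 1).
#' @param n_samples number of individuals `s`.
#' @param read_length,genome_length read and genome lengths in bases.
#' @return total number of reads.
#' @export
reads_for_missingness <- function(missingness, n_samples,
                                  read_length = 150,
                                  genome_length = 3e9) {
  if (missingness <= 0 || missingness >= 1)
    stop_input("'missingness' must be in (0, 1)")
  z <- -log(1 - read_length / genome_length)
  -n_samples * log(missingness) / z
}

#' Draw heterogeneous sampling times
#'
#' Assigns each sample an age drawn uniformly from `0..delta_t`
#' generations before present (the study design for time-heterogeneous
#' ancient panels).
#'
#' @param n_samples number of samples (or a [genotype_panel()], whose
#'   sample ids are reused).
#' @param delta_t maximum age offset in generations (`>= 0`).
#' @param seed RNG seed.
#' @return a [sample_age_table()] with point ages (`lo == hi`).
#' @export
assign_sampling_times <- function(n_samples, delta_t, seed = 1) {
  ids <- if (inherits(n_samples, "genotype_panel")) n_samples$sample_ids
  else sprintf("sample%04d", seq_len(n_samples))
  if (delta_t < 0) stop_input("'delta_t' must be >= 0")
  ages <- with_local_seed(seed,
    sample.int(floor(delta_t) + 1L, length(ids), replace = TRUE) - 1L)
  sample_age_table(ids, ages, ages)
}

## ---- genotype-level simulation -----------------------------------------

#' Two-locus Wright-Fisher ancestry for a sample of haplotypes
#'
#' Simulates, backwards in time and one generation per step, the ancestry
#' of `n_hap` haplotypes at two loci a genetic distance `u` Morgans apart:
#' lineages carrying both loci recombine apart with probability `u` per
#' generation, and lineages coalesce by drawing parents uniformly from the
#' `N_e(g)` haploid ancestors alive in generation `g`.  At the truncation
#' horizon every surviving root lineage receives independent
#' Bernoulli(`p`) founder alleles at the loci it carries (the
#' constant-allele-frequency convention), and alleles propagate to the
#' sampled haplotypes.  This is the genotype-level Monte-Carlo oracle for
#' [expected_ld()].
#'
#' @param model a [demographic_model()].
#' @param n_hap number of sampled haplotypes.
#' @param u distance between the loci in Morgans (use 0.5 for unlinked).
#' @param p_x,p_y founder allele frequencies.
#' @param horizon truncation generation.
#' @param admixture optional [admixture_scenario()]; lineages then choose
#'   one of the two diverged branches at the admixture time.
#' @return a list with integer allele vectors `x` and `y` (0/1 per
#'   haplotype).  Not seeded internally: callers wrap replicate loops in
#'   their own seed scope.
#' @export
sim_two_locus <- function(model, n_hap, u, p_x, p_y, horizon = NULL,
                          admixture = NULL) {
  horizon <- horizon %||% (10 * model$t_max)
  ne <- ne_at(model, seq_len(horizon))
  # lineage state: mat (1 = x only, 2 = y only, 3 = both), pop label
  mat <- rep(3L, n_hap)
  pop <- rep(1L, n_hap)
  curx <- seq_len(n_hap)          # lineage carrying haplotype h's x locus
  cury <- seq_len(n_hap)
  nlin <- n_hap
  for (g in seq_len(horizon)) {
    ## recombination: lineages with both loci split with prob u
    both <- which(mat == 3L)
    if (length(both) && u > 0) {
      split <- both[stats::runif(length(both)) < u]
      for (l in split) {
        nlin <- nlin + 1L
        mat[l] <- 1L                       # keeps x
        mat[nlin] <- 2L                    # new lineage carries y
        pop[nlin] <- pop[l]
        cury[cury == l] <- nlin
      }
    }
    ## population membership through an admixture history
    if (!is.null(admixture)) {
      if (g == admixture$t_adm + 1L) {
        live <- which(mat > 0L)
        pop[live] <- 1L + (stats::runif(length(live)) < 0.5)
      } else if (g == admixture$t_split + 1L) {
        pop[mat > 0L] <- 1L
      }
      Ng <- if (g <= admixture$t_adm) admixture$n_merged
      else if (g <= admixture$t_split) admixture$n_branch
      else admixture$n_anc
    } else Ng <- ne[g]
    ## coalescence: parents drawn uniformly within population
    live <- which(mat > 0L)
    if (length(live) <= 1L) break
    par <- numeric(length(live))
    for (pp in unique(pop[live])) {
      sel <- pop[live] == pp
      par[sel] <- sample.int(max(2L, round(Ng)), sum(sel),
                             replace = TRUE) + pp * 1e10
    }
    dup <- split(live, par)
    for (grp in dup) {
      if (length(grp) < 2L) next
      keep <- grp[1]
      for (l in grp[-1]) {
        mat[keep] <- bitwOr(mat[keep], mat[l])
        mat[l] <- 0L
        curx[curx == l] <- keep
        cury[cury == l] <- keep
      }
    }
    live <- which(mat > 0L)
    if (sum(mat[live] %in% c(1L, 3L)) <= 1L &&
        sum(mat[live] %in% c(2L, 3L)) <= 1L) break
  }
  roots <- which(mat > 0L)
  ax <- ay <- rep(NA_integer_, max(roots))
  ax[roots] <- stats::rbinom(length(roots), 1L, p_x)
  ay[roots] <- stats::rbinom(length(roots), 1L, p_y)
  list(x = ax[curx], y = ay[cury])
}

#' Simulate a genotype panel
#'
#' Two layouts are available.  `"independent"` draws every site
#' independently (`Bin(2, p)` genotypes), the exact zero-LD /
#' infinite-size limit used for null calibration of the cross-chromosome
#' test.  `"pairs"` places site *pairs* at controlled distances spanning
#' the LD window and simulates each pair's joint ancestry with
#' [sim_two_locus()]; distinct pairs are independent and are spaced more
#' than the window width apart so that only the simulated pairs enter the
#' binned curve.  Minor allele frequencies are drawn from `maf_sampler`
#' (default uniform on (0.25, 0.5), matching the LD pipeline's MAF
#' filter).
#'
#' @param model a [demographic_model()].
#' @param n_samples number of diploid samples.
#' @param genome a [synthetic_genome()] layout.
#' @param layout `"independent"` or `"pairs"`.
#' @param sites_per_arm sites per arm for the independent layout.
#' @param pair_distances_cm distances at which site pairs are placed
#'   (pairs layout).
#' @param maf_sampler function(n) returning allele frequencies.
#' @param horizon truncation generation for the pairs layout.
#' @param seed RNG seed.
#' @return a [genotype_panel()].
#' @export
simulate_ld_panel <- function(model, n_samples,
                              genome = synthetic_genome(10, 10),
                              layout = c("independent", "pairs"),
                              sites_per_arm = 40,
                              pair_distances_cm = c(1, 2, 5),
                              maf_sampler = function(n) stats::runif(n, 0.25, 0.5),
                              horizon = NULL, seed = 1) {
  layout <- match.arg(layout)
  with_local_seed(seed, {
    if (layout == "independent") {
      sites <- do.call(rbind, lapply(seq_len(nrow(genome)), function(a) {
        L <- genome$length_morgans[a] * 100
        data.frame(chrom = genome$chrom[a], arm = genome$arm[a],
                   cm = sort(stats::runif(sites_per_arm, 0, L)),
                   stringsAsFactors = FALSE)
      }))
      p <- maf_sampler(nrow(sites))
      g <- matrix(stats::rbinom(n_samples * nrow(sites), 2L,
                                rep(p, each = n_samples)),
                  nrow = n_samples)
      return(genotype_panel(g, sites, "diploid"))
    }
    ## pairs layout
    n_hap <- 2L * n_samples
    gap_cm <- 35                       # > default window: pairs stay isolated
    sites <- list(); cols <- list()
    for (a in seq_len(nrow(genome))) {
      L <- genome$length_morgans[a] * 100
      at <- gap_cm / 2
      d_idx <- 1L
      while (at + max(pair_distances_cm) < L - 1) {
        d <- pair_distances_cm[(d_idx - 1L) %% length(pair_distances_cm) + 1L]
        d_idx <- d_idx + 1L
        p2 <- maf_sampler(2L)
        tl <- sim_two_locus(model, n_hap, d / 100, p2[1], p2[2], horizon)
        gx <- tl$x[seq(1, n_hap, by = 2)] + tl$x[seq(2, n_hap, by = 2)]
        gy <- tl$y[seq(1, n_hap, by = 2)] + tl$y[seq(2, n_hap, by = 2)]
        sites[[length(sites) + 1L]] <- data.frame(
          chrom = rep(genome$chrom[a], 2), arm = rep(genome$arm[a], 2),
          cm = c(at, at + d), stringsAsFactors = FALSE)
        cols[[length(cols) + 1L]] <- cbind(gx, gy)
        at <- at + d + gap_cm
      }
    }
    if (!length(cols))
      stop_input("genome arms too short for the requested pair layout")
    genotype_panel(do.call(cbind, cols), do.call(rbind, sites), "diploid")
  })
}

#' Simulate a structured (two-source) genotype panel
#'
#' Generates panels whose LD is driven by population structure rather than
#' demography, for exercising the cross-chromosome LD test and the
#' admixture-bias diagnostics.  Site frequencies in the two source
#' populations drift apart to a target fixation index under the
#' Balding-Nichols model.  In `"pooled"` mode half the individuals come
#' from each source (maximal structure); in `"admixed"` mode every
#' haplotype is an ancestry mosaic with switch rate `t_adm` per Morgan and
#' equal contributions, emulating a panel sampled `t_adm` generations
#' after an admixture event.
#'
#' @param n_samples diploid sample count.
#' @param fst divergence between the two sources.
#' @param genome a [synthetic_genome()] layout.
#' @param sites_per_arm sites per arm.
#' @param t_adm generations since admixture (admixed mode).
#' @param mode `"pooled"` or `"admixed"`.
#' @param maf_sampler ancestral frequency sampler.
#' @param seed RNG seed.
#' @return a diploid [genotype_panel()].
#' @export
simulate_structured_panel <- function(n_samples, fst,
                                      genome = synthetic_genome(10, 10),
                                      sites_per_arm = 40, t_adm = 10,
                                      mode = c("pooled", "admixed"),
                                      maf_sampler = function(n)
                                        stats::runif(n, 0.3, 0.7),
                                      seed = 1) {
  mode <- match.arg(mode)
  if (fst <= 0 || fst >= 1) stop_input("'fst' must be in (0, 1)")
  with_local_seed(seed, {
    sites <- do.call(rbind, lapply(seq_len(nrow(genome)), function(a) {
      L <- genome$length_morgans[a] * 100
      data.frame(chrom = genome$chrom[a], arm = genome$arm[a],
                 cm = sort(stats::runif(sites_per_arm, 0, L)),
                 stringsAsFactors = FALSE)
    }))
    m <- nrow(sites)
    p0 <- maf_sampler(m)
    shape <- (1 - fst) / fst
    pA <- stats::rbeta(m, p0 * shape, (1 - p0) * shape)
    pB <- stats::rbeta(m, p0 * shape, (1 - p0) * shape)
    pA <- pmin(pmax(pA, 0.02), 0.98); pB <- pmin(pmax(pB, 0.02), 0.98)
    n_hap <- 2L * n_samples
    H <- matrix(0L, n_hap, m)
    if (mode == "pooled") {
      anc_ind <- rep(c(0L, 1L), length.out = n_samples)
      anc <- rep(anc_ind, each = 2L)
      for (h in seq_len(n_hap)) {
        p <- if (anc[h] == 0L) pA else pB
        H[h, ] <- stats::rbinom(m, 1L, p)
      }
    } else {
      arm_key <- paste(sites$chrom, sites$arm)
      for (h in seq_len(n_hap)) {
        anc_site <- integer(m)
        for (a in unique(arm_key)) {
          idx <- which(arm_key == a)
          cm <- sites$cm[idx]
          state <- stats::rbinom(1L, 1L, 0.5)
          last <- cm[1]
          for (k in seq_along(idx)) {
            gap_m <- (cm[k] - last) / 100
            nsw <- stats::rpois(1L, t_adm * gap_m)
            if (nsw > 0) state <- stats::rbinom(1L, 1L, 0.5)
            anc_site[idx[k]] <- state
            last <- cm[k]
          }
        }
        p <- ifelse(anc_site == 0L, pA, pB)
        H[h, ] <- stats::rbinom(m, 1L, p)
      }
    }
    g <- H[seq(1, n_hap, 2), , drop = FALSE] + H[seq(2, n_hap, 2), , drop = FALSE]
    genotype_panel(g, sites[c("chrom", "arm", "cm")], "diploid")
  })
}
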