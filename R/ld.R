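#' Standardize a genotype panel
#'
#' Centres and scales allele counts site by site using the estimated
#' allele frequency \eqn{\hat p_x}: diploid panels use
#' \eqn{G = (\tilde G - 2\hat p)/\sqrt{2 \hat p (1-\hat p)}}; pseudo-haploid
#' panels use the sampled-allele (Bernoulli) normalisation
#' \eqn{G = (x - \hat p)/\sqrt{\hat p(1-\hat p)}} with \eqn{x} the sampled
#' allele indicator.  Missing entries remain missing.  Monomorphic sites or
#' sites with fewer than two observations must be removed beforehand (see
#' [filter_sites()]).
#'
#' @param panel a [genotype_panel()].
#' @param scale `"native"` uses the ploidy-appropriate normalisation above;
#'   `"dosage"` applies the diploid formula regardless of ploidy (used by
#'   the cross-chromosome LD test, where pseudo-haploid calls stay on the
#'   doubled-dosage scale).
#' @return a samples-by-sites numeric matrix of standardized genotypes.
#' @export
standardize_genotypes <- function(panel, scale = c("native", "dosage")) {
  scale <- match.arg(scale)
  g <- panel$genotypes
  p <- colMeans(g, na.rm = TRUE) / 2
  if (any(!is.finite(p)) || any(p <= 0 | p >= 1))
    stop_input("internal error: monomorphic or empty site reached standardization; run filter_sites() first")
  if (panel$ploidy == "pseudo_haploid" && scale == "native") {
    x <- g / 2
    out <- sweep(x, 2, p) / rep(sqrt(p * (1 - p)), each = nrow(g))
  } else {
    out <- sweep(g, 2, 2 * p) / rep(sqrt(2 * p * (1 - p)), each = nrow(g))
  }
  out
}

#' Pairwise unbiased-style R-squared
#'
#' For two standardized genotype columns the LD statistic is
#' \deqn{R^2 = \frac{(\sum_i G_{i,x} G_{i,y})^2 - \sum_i G_{i,x}^2
#' G_{i,y}^2}{s(s-1)},}
#' with sums over the \eqn{s} jointly non-missing individuals.  The
#' subtraction makes the statistic unbiased for the squared population
#' correlation, so individual values can be negative.
#'
#' @param gx,gy standardized genotype vectors of equal length (may contain
#'   `NA`).
#' @return the R-squared value, or `NA` if fewer than 2 individuals are
#'   jointly observed.
#' @export
pairwise_r2 <- function(gx, gy) {
  ok <- !is.na(gx) & !is.na(gy)
  s <- sum(ok)
  if (s < 2L) return(NA_real_)
  x <- gx[ok]; y <- gy[ok]
  ((sum(x * y))^2 - sum(x^2 * y^2)) / (s * (s - 1))
}

## ---- finite-sample baseline --------------------------------------------

# Exact expectation of the squared standardized genotype E[G^2] for a
# diploid site with s samples and allele frequency p, by enumeration over
# the multinomial genotype counts (conditioning on the site being
# polymorphic in-sample).  For pseudo-haploid sites the sample variance of
# a Bernoulli equals phat*(1-phat) identically, so E[G^2] = 1 exactly.
e2_diploid_exact <- function(s, p) {
  grid <- expand.grid(n1 = 0:s, n2 = 0:s)
  grid <- grid[grid$n1 + grid$n2 <= s, ]
  n0 <- s - grid$n1 - grid$n2
  q <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  logw <- lgamma(s + 1) - lgamma(n0 + 1) - lgamma(grid$n1 + 1) -
    lgamma(grid$n2 + 1) + n0 * log(q[1]) + grid$n1 * log(q[2]) +
    grid$n2 * log(q[3])
  w <- exp(logw)
  tot <- grid$n1 + 2 * grid$n2
  ph <- tot / (2 * s)
  poly <- ph > 0 & ph < 1
  m2 <- (n0 * (0 - 2 * ph)^2 + grid$n1 * (1 - 2 * ph)^2 +
           grid$n2 * (2 - 2 * ph)^2) / s
  val <- m2 / (2 * ph * (1 - ph))
  sum(w[poly] * val[poly]) / sum(w[poly])
}

.ld_baseline_cache <- new.env(parent = emptyenv())

#' Finite-sample baseline of the R-squared estimator
#'
#' Expected value (`beta`) and standard deviation (`tau`) of the pairwise
#' R-squared statistic for a pair of truly independent sites, as a function
#' of the number of samples whose genotypes enter each pairwise sum.  The
#' mean is \eqn{\beta = \bar e_2^2/(s-1)^2} where \eqn{\bar e_2 = E[G^2]}
#' is computed by exact enumeration for diploid panels and equals 1 for
#' pseudo-haploid panels; the standard deviation uses the large-sample
#' chi-square approximation \eqn{\tau \approx \sqrt{2}\, \bar e_2/(s-1)}.
#' Both quantities are what the model expectations and the summary-level
#' simulator use for the no-LD limit.
#'
#' @param n_samples number of (jointly observed) individuals `s`.
#' @param ploidy `"diploid"` or `"pseudo_haploid"`.
#' @param maf vector of allele frequencies over which to average the
#'   enumeration (e.g. the panel's site frequencies); defaults to a uniform
#'   grid on (0.25, 0.5).
#' @return a list with `beta`, `tau` and `e2`.
#' @export
ld_baseline <- function(n_samples, ploidy = c("diploid", "pseudo_haploid"),
                        maf = NULL) {
  ploidy <- match.arg(ploidy)
  s <- as.integer(round(n_samples))
  if (s < 2L) stop_input("need at least 2 samples for the LD baseline")
  if (ploidy == "pseudo_haploid") {
    e2 <- 1
  } else {
    maf <- maf %||% seq(0.26, 0.49, by = 0.01)
    key <- sprintf("d_%d_%s", s, digest_nums(maf))
    e2 <- .ld_baseline_cache[[key]]
    if (is.null(e2)) {
      e2 <- mean(vapply(maf, function(p) e2_diploid_exact(s, p), numeric(1)))
      .ld_baseline_cache[[key]] <- e2
    }
  }
  list(beta = e2^2 / (s - 1)^2, tau = sqrt(2) * e2 / (s - 1), e2 = e2)
}

digest_nums <- function(x) {
  paste(format(sum(x) * 1e6, digits = 12), length(x), sep = "_")
}

## ---- binned LD curve ----------------------------------------------------

#' Binned LD decay curve
#'
#' Computes the mean pairwise R-squared in genetic-distance bins within
#' chromosome arms.  Sites are filtered to minor allele frequency above
#' `maf_min`; pairs are restricted to the same arm and to distances inside
#' `window_cm`; bins are half-open `[lo, hi)` intervals of width
#' `bin_width_cm`.  When an arm-bin holds more than `max_pairs` site pairs
#' a seeded subsample is used.
#'
#' @param panel a [genotype_panel()].
#' @param window_cm length-2 numeric: minimum and maximum pair distance in
#'   cM (default `c(0.5, 30)`).
#' @param maf_min minor allele frequency threshold (default 0.25).
#' @param bin_width_cm bin width in cM (default 0.5).
#' @param max_pairs cap on pairs per arm-bin (default 1e6).
#' @param seed seed for pair subsampling.
#' @return an object of class `binned_ld`: a data.frame with columns
#'   `region`, `bin_lo`, `bin_hi` (cM), `y` (mean R-squared), `n_pairs`,
#'   `var` (variance of the bin mean, using an effective pair count that
#'   discounts shared-site multiplicity), plus attributes `n_eff` (mean
#'   jointly-observed sample count), `ploidy` and `baseline`.
#' @export
bin_ld_curve <- function(panel, window_cm = c(0.5, 30), maf_min = 0.25,
                         bin_width_cm = 0.5, max_pairs = 1e6, seed = 1) {
  stopifnot(inherits(panel, "genotype_panel"))
  panel <- filter_sites(panel, maf_min)
  if (ncol(panel$genotypes) < 2L)
    stop_input("fewer than two usable sites after MAF filtering")
  G <- standardize_genotypes(panel, scale = "native")
  edges <- seq(window_cm[1], window_cm[2], by = bin_width_cm)
  if (length(edges) < 2L) stop_input("window too narrow for the bin width")
  regions <- unique(panel$sites$region)
  rows <- list()
  n_eff_acc <- 0; n_eff_n <- 0
  for (r in regions) {
    idx <- which(panel$sites$region == r)
    if (length(idx) < 2L) next
    cm <- panel$sites$cm[idx]
    pr <- utils::combn(seq_along(idx), 2L)
    d <- abs(cm[pr[1, ]] - cm[pr[2, ]])
    inwin <- d >= window_cm[1] & d < window_cm[2]
    pr <- pr[, inwin, drop = FALSE]; d <- d[inwin]
    if (!length(d)) next
    bin <- findInterval(d, edges)
    for (b in sort(unique(bin))) {
      sel <- which(bin == b)
      if (length(sel) > max_pairs)
        sel <- with_local_seed(seed + b, sample(sel, max_pairs))
      i1 <- idx[pr[1, sel]]; i2 <- idx[pr[2, sel]]
      vals <- numeric(length(sel)); svals <- numeric(length(sel))
      for (k in seq_along(sel)) {
        gx <- G[, i1[k]]; gy <- G[, i2[k]]
        ok <- !is.na(gx) & !is.na(gy)
        svals[k] <- sum(ok)
        vals[k] <- if (svals[k] < 2L) NA_real_ else
          ((sum(gx[ok] * gy[ok]))^2 - sum(gx[ok]^2 * gy[ok]^2)) /
            (svals[k] * (svals[k] - 1))
      }
      keep <- !is.na(vals)
      if (!any(keep)) next
      vals <- vals[keep]
      # effective count: pairs divided by the mean number of retained
      # pairs each participating site appears in (adjacent pairs reuse
      # sites and are correlated)
      mult <- mean(table(c(i1[keep], i2[keep])))
      n_eff_pairs <- max(1, length(vals) / max(1, mult))
      v <- if (length(vals) > 1L) stats::var(vals) / n_eff_pairs else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        region = r, bin_lo = edges[b], bin_hi = edges[b] + bin_width_cm,
        y = mean(vals), n_pairs = length(vals), var = v,
        stringsAsFactors = FALSE)
      n_eff_acc <- n_eff_acc + sum(svals[keep]); n_eff_n <- n_eff_n + sum(keep)
    }
  }
  if (!length(rows)) stop_input("no site pairs fall inside the LD window")
  out <- do.call(rbind, rows)
  n_eff <- n_eff_acc / n_eff_n
  binned_ld(out, n_eff = n_eff, ploidy = panel$ploidy)
}

#' Construct a binned LD object
#'
#' Low-level constructor used by [bin_ld_curve()], the summary-level
#' simulator and the TSV reader.
#'
#' @param df data.frame with columns `region`, `bin_lo`, `bin_hi`, `y`,
#'   `n_pairs`, `var`.
#' @param n_eff mean number of jointly observed samples behind each
#'   pairwise statistic (drives the finite-sample baseline).
#' @param ploidy panel ploidy the statistics were computed under.
#' @return a `binned_ld` object.
#' @export
binned_ld <- function(df, n_eff, ploidy = "diploid") {
  need <- c("region", "bin_lo", "bin_hi", "y", "n_pairs", "var")
  if (!all(need %in% names(df))) stop_input("missing binned LD columns")
  df <- df[order(df$region, df$bin_lo), ]
  rownames(df) <- NULL
  structure(df, class = c("binned_ld", "data.frame"),
            n_eff = n_eff, ploidy = ploidy,
            baseline = ld_baseline(n_eff, ploidy))
}

#' @export
print.binned_ld <- function(x, ...) {
  cat(sprintf("binned LD: %d regions x %d bins [%g, %g) cM, n_eff = %.1f (%s)\n",
              length(unique(x$region)),
              length(unique(x$bin_lo)), min(x$bin_lo), max(x$bin_hi),
              attr(x, "n_eff"), attr(x, "ploidy")))
  invisible(x)
}

#' Read / write binned LD as TSV
#' @param x a `binned_ld` object.
#' @param path file path.
#' @return the object (read) or `path` (write, invisibly).
#' @export
write_binned_ld <- function(x, path) {
  df <- as.data.frame(x)
  df$n_eff <- attr(x, "n_eff")
  df$ploidy <- attr(x, "ploidy")
  write_tsv(df, path)
}

#' @rdname write_binned_ld
#' @export
read_binned_ld <- function(path) {
  df <- read_tsv(path)
  binned_ld(df[c("region", "bin_lo", "bin_hi", "y", "n_pairs", "var")],
            n_eff = df$n_eff[1], ploidy = df$ploidy[1])
}

## ---- cross-chromosome LD test ------------------------------------------

#' Cross-chromosome LD test for population structure
#'
#' In a panmictic panel, correlation between sites on different chromosomes
#' reflects only finite sample size.  For each cross-chromosome site pair
#' the statistic
#' \deqn{\mathrm{mean}_{i \ne j}\left[G_{i,x} G_{i,y} G_{j,x}
#' G_{j,y}\right] - \frac{4}{(N_x - 1)(N_y - 1)}}
#' has expectation zero under panmixia, where \eqn{N_x}, \eqn{N_y} are the
#' numbers of observed haplotypes at the two sites (twice the jointly
#' observed individuals for diploid panels).  The statistic is averaged per
#' chromosome pair and a two-sided one-sample t-test across chromosome
#' pairs checks the zero-mean hypothesis; admixture or population
#' structure pushes the mean positive.
#'
#' @param panel a [genotype_panel()].
#' @param maf_min minor allele frequency filter (default 0.25).
#' @param max_pairs cap on site pairs per chromosome pair (seeded
#'   subsample beyond it).
#' @param seed subsampling seed.
#' @param alpha significance level for the `significant` flag.
#' @return a list of class `ccld_report` with `pair_means` (per
#'   chromosome-pair data.frame), `pooled_mean`, `t_stat`, `p_value`,
#'   `significant`, `n_chrom_pairs`.
#' @export
ccld_test <- function(panel, maf_min = 0.25, max_pairs = 1e6, seed = 1,
                      alpha = 0.05) {
  stopifnot(inherits(panel, "genotype_panel"))
  panel <- filter_sites(panel, maf_min)
  chroms <- unique(panel$sites$chrom)
  if (length(chroms) < 2L) {
    warning("cross-chromosome LD test needs at least 2 chromosomes; skipping")
    return(structure(list(pair_means = NULL, pooled_mean = NA_real_,
                          t_stat = NA_real_, p_value = NA_real_,
                          significant = FALSE, n_chrom_pairs = 0L),
                     class = "ccld_report"))
  }
  G <- standardize_genotypes(panel, scale = "dosage")
  hap_per_ind <- if (panel$ploidy == "pseudo_haploid") 1L else 2L
  obs <- !is.na(G)
  G0 <- G; G0[!obs] <- 0
  cp <- utils::combn(chroms, 2L)
  res <- data.frame(chrom1 = cp[1, ], chrom2 = cp[2, ],
                    mean_stat = NA_real_, n_pairs = NA_integer_,
                    stringsAsFactors = FALSE)
  for (k in seq_len(ncol(cp))) {
    ix <- which(panel$sites$chrom == cp[1, k])
    iy <- which(panel$sites$chrom == cp[2, k])
    if (length(ix) * length(iy) > max_pairs) {
      pick <- with_local_seed(seed + k, {
        list(x = sample(ix, min(length(ix), ceiling(sqrt(max_pairs)))),
             y = sample(iy, min(length(iy), ceiling(sqrt(max_pairs)))))
      })
      ix <- pick$x; iy <- pick$y
    }
    Gx <- G0[, ix, drop = FALSE]; Gy <- G0[, iy, drop = FALSE]
    Ox <- obs[, ix, drop = FALSE] + 0; Oy <- obs[, iy, drop = FALSE] + 0
    S <- crossprod(Gx, Gy)                       # sum_i Gx Gy over overlap
    Q <- crossprod(Gx^2, Gy^2)                   # sum_i Gx^2 Gy^2
    sxy <- crossprod(Ox, Oy)                     # overlap counts
    ok <- sxy >= 2
    stat <- matrix(NA_real_, nrow(S), ncol(S))
    stat[ok] <- (S[ok]^2 - Q[ok]) / (sxy[ok] * (sxy[ok] - 1))
    N <- sxy * hap_per_ind
    stat[ok] <- stat[ok] - 4 / ((N[ok] - 1) * (N[ok] - 1))
    res$mean_stat[k] <- mean(stat, na.rm = TRUE)
    res$n_pairs[k] <- sum(ok)
  }
  if (nrow(res) >= 2L && stats::sd(res$mean_stat) > 0) {
    tt <- stats::t.test(res$mean_stat, mu = 0)
    t_stat <- unname(tt$statistic); p_value <- tt$p.value
  } else {
    warning("too few chromosome pairs for the zero-mean t-test")
    t_stat <- NA_real_; p_value <- NA_real_
  }
  structure(list(pair_means = res, pooled_mean = mean(res$mean_stat),
                 t_stat = t_stat, p_value = p_value,
                 significant = isTRUE(p_value < alpha),
                 n_chrom_pairs = nrow(res)),
            class = "ccld_report")
}

#' Write a cross-chromosome LD report as TSV
#'
#' One row per chromosome pair plus a pooled summary row.
#'
#' @param x a `ccld_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ccld_report <- function(x, path) {
  if (is.null(x$pair_means)) {
    df <- data.frame(chrom1 = NA, chrom2 = NA, mean_stat = NA,
                     n_pairs = NA)
  } else df <- x$pair_means
  df <- rbind(df, data.frame(chrom1 = "pooled", chrom2 = "",
                             mean_stat = x$pooled_mean,
                             n_pairs = sum(df$n_pairs)))
  df$t_stat <- c(rep(NA, nrow(df) - 1), x$t_stat)
  df$p_value <- c(rep(NA, nrow(df) - 1), x$p_value)
  write_tsv(df, path)
}

#' @export
print.ccld_report <- function(x, ...) {
  if (is.null(x$pair_means)) {
    cat("cross-chromosome LD test: not applicable (single chromosome)\n")
  } else {
    cat(sprintf("cross-chromosome LD: pooled mean %.3e over %d chromosome pairs; t = %.2f, p = %.3g%s\n",
                x$pooled_mean, x$n_chrom_pairs, x$t_stat, x$p_value,
                if (x$significant) "  ** admixture LD detected **" else ""))
  }
  invisible(x)
}
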