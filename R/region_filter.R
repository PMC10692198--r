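#' Filter chromosome arms with outlying LD
#'
#' For every distance bin a robust centre and scale are estimated across
#' regions (centre = median, scale = IQR/1.349, the normal-consistent
#' robust estimator).  A region is discarded when
#'
#' * any of its bins deviates from the bin median by more than
#'   `z_max` scale units, or
#' * its bin values never cross the median: all strictly above or all
#'   strictly below (values tying the median count as crossing).
#'
#' The rules target localised outliers (selection, structural variation)
#' and systematic one-sided shifts respectively.  Filtering only changes
#' membership, never values, and is idempotent given stable medians.
#'
#' @param ld a [binned_ld()] object.
#' @param z_max deviation threshold in robust SD units (default 6).
#' @return a list with `kept` (region ids), `dropped`, and `report` (per
#'   region: worst absolute z-score, crossing status, decision).
#' @export
filter_ld_regions <- function(ld, z_max = 6) {
  stopifnot(inherits(ld, "binned_ld"))
  regions <- unique(ld$region)
  if (length(regions) < 3L)
    stop_input("LD region filtering needs at least 3 regions")
  bins <- sort(unique(ld$bin_lo))
  Y <- matrix(NA_real_, length(regions), length(bins),
              dimnames = list(regions, as.character(bins)))
  Y[cbind(ld$region, as.character(ld$bin_lo))] <- ld$y
  med <- apply(Y, 2, stats::median, na.rm = TRUE)
  iqr <- apply(Y, 2, stats::IQR, na.rm = TRUE)
  scale <- iqr / 1.349
  scale[scale <= 0 | !is.finite(scale)] <- Inf   # ties: no z-based drops
  dev <- sweep(Y, 2, med)
  z <- sweep(dev, 2, scale, "/")
  worst <- apply(abs(z), 1, max, na.rm = TRUE)
  crosses <- apply(dev, 1, function(d) {
    d <- d[!is.na(d)]
    any(d >= 0) && any(d <= 0)
  })
  drop <- worst > z_max | !crosses
  report <- data.frame(region = regions, worst_z = worst,
                       crosses_median = crosses,
                       decision = ifelse(drop, "drop", "keep"),
                       stringsAsFactors = FALSE)
  kept <- regions[!drop]
  if (!length(kept))
    stop_input("all regions rejected by the LD filter; inspect the input")
  list(kept = kept, dropped = regions[drop], report = report)
}

#' Filter chromosome arms with outlying IBD counts
#'
#' For each region, per-bin Poisson means and dispersion factors are
#' estimated from all other regions (leave-one-out, proportional to region
#' genetic length).  The region's summed squared Poisson deviance
#' residuals, scaled by the dispersion, are compared to the central
#' \eqn{1 - 2\alpha} mass of a chi-square distribution with one degree of
#' freedom per bin; regions in either tail are discarded.  The whole
#' procedure runs a second time on the surviving set so that gross
#' outliers cannot mask milder ones.
#'
#' @param hist an [build_ibd_histogram()] object.
#' @param alpha tail probability (default `1e-12`).
#' @return a list with `kept`, `dropped`, and `report` (per region and
#'   pass: deviance statistic, degrees of freedom, bounds, decision).
#' @export
filter_ibd_regions <- function(hist, alpha = 1e-12) {
  stopifnot(inherits(hist, "ibd_histogram"))
  lens <- attr(hist, "region_lengths")
  regions <- names(lens)
  if (length(regions) < 3L)
    stop_input("IBD region filtering needs at least 3 regions")
  bins <- sort(unique(hist$bin_lo))
  Y <- matrix(0, length(regions), length(bins),
              dimnames = list(regions, as.character(bins)))
  Y[cbind(hist$region, as.character(hist$bin_lo))] <- hist$count
  L <- lens[regions]
  reports <- list()
  active <- regions
  for (pass in 1:2) {
    if (length(active) < 3L) break
    Ya <- Y[active, , drop = FALSE]
    La <- L[active]
    stat <- df_used <- numeric(length(active))
    for (k in seq_along(active)) {
      oth <- setdiff(seq_along(active), k)
      rate <- colSums(Ya[oth, , drop = FALSE]) / sum(La[oth])  # per Morgan
      mu <- rate * La[k]
      y <- Ya[k, ]
      # dispersion per bin from the other regions
      mu_oth <- outer(La[oth], rate)
      phi <- colSums((Ya[oth, , drop = FALSE] - mu_oth)^2 /
                       pmax(mu_oth, 1e-12)) / max(1, length(oth) - 1)
      phi <- pmax(phi, 1)
      d2 <- poisson_dev2(y, mu) / phi
      # the chi-square reference is only valid for bins with appreciable
      # expected counts; near-empty bins would deflate the statistic and
      # trigger spurious lower-tail drops.  Bins with surprisingly large
      # observed counts stay in regardless, so gross excesses are caught.
      use <- mu >= 1 | y >= 5
      stat[k] <- sum(d2[use])
      df_used[k] <- max(1L, sum(use))
    }
    lo <- stats::qchisq(alpha, df_used)
    hi <- stats::qchisq(1 - alpha, df_used)
    drop <- stat < lo | stat > hi
    reports[[pass]] <- data.frame(region = active, pass = pass,
                                  statistic = stat, df = df_used,
                                  lower = lo, upper = hi,
                                  decision = ifelse(drop, "drop", "keep"),
                                  stringsAsFactors = FALSE)
    active <- active[!drop]
  }
  if (!length(active))
    stop_input("all regions rejected by the IBD filter; inspect the input")
  list(kept = active, dropped = setdiff(regions, active),
       report = do.call(rbind, reports))
}

# Squared Poisson deviance residuals with the usual conventions for zero
# observations (y log(y/mu) -> 0 as y -> 0) and empty cells (y = mu = 0
# contributes 0); y > 0 with mu = 0 would be infinite and is clamped via a
# small floor, flagging the region deterministically.
poisson_dev2 <- function(y, mu) {
  mu <- pmax(mu, 1e-12)
  term <- ifelse(y > 0, y * log(y / mu), 0)
  2 * (term - (y - mu))
}

#' Write a region-filter report as TSV
#' @param report a data.frame from [filter_ld_regions()] or
#'   [filter_ibd_regions()] (`$report`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) write_tsv(report, path)

#' Restrict summary data to a set of regions
#'
#' @param x a `binned_ld` or `ibd_histogram`.
#' @param regions character vector of region ids to keep (duplicates allowed:
#'   a region listed twice appears twice, which is what the chromosome-arm
#'   bootstrap needs).
#' @return an object of the same class.
#' @export
subset_regions <- function(x, regions) {
  if (inherits(x, "binned_ld")) {
    parts <- lapply(seq_along(regions), function(k) {
      d <- as.data.frame(x)[x$region == regions[k], , drop = FALSE]
      d$region <- sprintf("%s.%d", regions[k], k)
      d
    })
    return(binned_ld(do.call(rbind, parts), n_eff = attr(x, "n_eff"),
                     ploidy = attr(x, "ploidy")))
  }
  if (inherits(x, "ibd_histogram")) {
    lens <- attr(x, "region_lengths")
    parts <- lapply(seq_along(regions), function(k) {
      d <- as.data.frame(x)[x$region == regions[k], , drop = FALSE]
      d$region <- sprintf("%s.%d", regions[k], k)
      d
    })
    df <- do.call(rbind, parts)
    rownames(df) <- NULL
    newlens <- stats::setNames(lens[regions],
                               sprintf("%s.%d", regions, seq_along(regions)))
    return(structure(df, class = c("ibd_histogram", "data.frame"),
                     region_lengths = newlens,
                     n_pairs = attr(x, "n_pairs"),
                     u_min = attr(x, "u_min")))
  }
  stop_input("unsupported class for subset_regions")
}
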