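#' Genetic maps and chromosome-arm regions
#'
#' A `genetic_map` is a table of map anchor points with columns `chrom`
#' (chromosome label), `arm` (`"p"`/`"q"` or any label; the chromosome arm
#' is the unit of independence for region filtering and bootstrap
#' resampling), `bp` (physical position) and `cm` (genetic position in
#' centimorgans).  Genetic positions must be non-decreasing within a
#' chromosome.
#'
#' @param chrom,arm,bp,cm vectors of equal length describing the anchors.
#' @return a data.frame of class `genetic_map`, sorted by chromosome and
#'   position, with a `region` column identifying each chromosome arm.
#' @export
genetic_map <- function(chrom, arm, bp, cm) {
  df <- data.frame(chrom = as.character(chrom), arm = as.character(arm),
                   bp = as.numeric(bp), cm = as.numeric(cm),
                   stringsAsFactors = FALSE)
  if (any(!is.finite(df$bp)) || any(!is.finite(df$cm)))
    stop_input("map positions must be finite")
  df <- df[order(df$chrom, df$bp), ]
  for (ch in unique(df$chrom)) {
    i <- df$chrom == ch
    if (is.unsorted(df$cm[i]))
      stop_input("genetic positions must be non-decreasing within chromosome ", ch)
  }
  df$region <- paste(df$chrom, df$arm, sep = "_")
  rownames(df) <- NULL
  class(df) <- c("genetic_map", "data.frame")
  df
}

#' Summarise the chromosome arms of a genetic map
#'
#' @param map a [genetic_map()].
#' @return a data.frame with one row per arm: `region`, `chrom`, `arm`,
#'   `cm_lo`, `cm_hi` and `length_morgans`.
#' @export
arm_table <- function(map) {
  stopifnot(inherits(map, "genetic_map"))
  sp <- split(seq_len(nrow(map)), map$region)
  out <- do.call(rbind, lapply(names(sp), function(r) {
    i <- sp[[r]]
    data.frame(region = r, chrom = map$chrom[i[1]], arm = map$arm[i[1]],
               cm_lo = min(map$cm[i]), cm_hi = max(map$cm[i]),
               stringsAsFactors = FALSE)
  }))
  out$length_morgans <- (out$cm_hi - out$cm_lo) / 100
  out[order(out$chrom, out$cm_lo), ]
}

# Interpolate genetic positions (cM) for physical positions on one
# chromosome; linear between anchors, constant extrapolation at the ends.
interp_cm <- function(map, chrom, bp) {
  i <- map$chrom == as.character(chrom)
  if (!any(i)) return(rep(NA_real_, length(bp)))
  x <- map$bp[i]; y <- map$cm[i]
  if (sum(i) == 1L) return(rep(y, length(bp)))
  stats::approx(x, y, xout = bp, rule = 2, ties = "ordered")$y
}

# Arm label containing a cM position on a chromosome (boundary at the
# centromere, taken as the midpoint between the last anchor of one arm and
# the first anchor of the next).
arm_at <- function(map, chrom, cm) {
  i <- which(map$chrom == as.character(chrom))
  if (!length(i)) return(rep(NA_character_, length(cm)))
  arms <- unique(map$arm[i])
  if (length(arms) == 1L) return(rep(arms, length(cm)))
  bounds <- numeric(0)
  for (k in seq_len(length(arms) - 1L)) {
    hi <- max(map$cm[i][map$arm[i] == arms[k]])
    lo <- min(map$cm[i][map$arm[i] == arms[k + 1L]])
    bounds <- c(bounds, (hi + lo) / 2)
  }
  arms[findInterval(cm, bounds) + 1L]
}

#' Read / write a genetic map TSV
#'
#' The on-disk format is a tab-separated table with header columns `chrom`,
#' `arm`, `bp`, `cm` (extra columns are preserved on read and ignored).
#'
#' @param path file path.
#' @return [read_genetic_map()] returns a [genetic_map()];
#'   [write_genetic_map()] returns `path` invisibly.
#' @export
read_genetic_map <- function(path) {
  df <- read_tsv(path, colClasses = NA)
  need <- c("chrom", "arm", "bp", "cm")
  if (!all(need %in% names(df)))
    stop_input("genetic map file must have columns chrom, arm, bp, cm")
  genetic_map(df$chrom, df$arm, df$bp, df$cm)
}

#' @rdname read_genetic_map
#' @param map a [genetic_map()].
#' @export
write_genetic_map <- function(map, path) {
  write_tsv(as.data.frame(map)[c("chrom", "arm", "bp", "cm")], path)
}

#' Synthetic genome layout
#'
#' Builds the arm structure used by the simulators: `n_arms` independent
#' chromosome arms with genetic lengths summing to `total_morgans`
#' (defaults mirror a human autosomal genome: 39 arms, 36.23 Morgans).
#' Arm lengths follow a fixed linear ramp between roughly 0.4 and 1.5
#' Morgans so that the layout is deterministic.  Physical positions are
#' laid out at 1 Mb per cM.
#'
#' @param n_arms number of chromosome arms.
#' @param total_morgans total genetic length in Morgans.
#' @return a data.frame with columns `region`, `chrom`, `arm`,
#'   `length_morgans`.
#' @export
synthetic_genome <- function(n_arms = 39, total_morgans = 36.23) {
  if (n_arms < 1) stop_input("'n_arms' must be >= 1")
  ramp <- 1 + 2 * (seq_len(n_arms) - 1) / max(1, n_arms - 1)  # 1..3
  len <- total_morgans * ramp / sum(ramp)
  # alternate p/q arms over ceiling(n_arms/2) chromosomes
  chrom <- as.character(rep(seq_len(ceiling(n_arms / 2)), each = 2)[seq_len(n_arms)])
  arm <- rep(c("p", "q"), length.out = n_arms)
  data.frame(region = paste(chrom, arm, sep = "_"), chrom = chrom,
             arm = arm, length_morgans = len, stringsAsFactors = FALSE)
}

# Build a site-level genetic_map for sites placed on a synthetic genome.
# 'sites' is a data.frame with chrom, arm, cm.
map_from_sites <- function(chrom, arm, cm) {
  genetic_map(chrom, arm, bp = round(cm * 1e6), cm = cm)
}
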