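#' Read an IBD segment file
#'
#' Parses tab-separated IBD segment lists in the format emitted by common
#' haplotype-based IBD detectors: columns
#' `id1, hap1, id2, hap2, chrom, start_bp, end_bp[, extra]` with optional
#' trailing LOD / length columns, plain or gzipped.  Genetic coordinates
#' are interpolated from the map; segments spanning a chromosome-arm
#' boundary are split at the boundary so that arms stay disjoint units for
#' resampling.  Malformed lines are counted and reported; more than 10%
#' malformed lines is an error.  Segments on chromosomes absent from the
#' map are skipped with a warning.
#'
#' @param path segment file (`.ibd` or `.ibd.gz`).
#' @param map a [genetic_map()].
#' @return a data.frame of class `ibd_segments` with columns `id1`, `hap1`,
#'   `id2`, `hap2`, `chrom`, `arm`, `region`, `start_bp`, `end_bp`,
#'   `start_cm`, `end_cm`, `length_cm`.
#' @export
read_ibd <- function(path, map) {
  stopifnot(inherits(map, "genetic_map"))
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty IBD file: ", path)
    return(empty_ibd_segments())
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfld <- lengths(parts)
  bad <- nfld < 7L
  rows <- lapply(parts[!bad], function(p) p[1:7])
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("id1", "hap1", "id2", "hap2", "chrom", "start_bp", "end_bp")
  df$start_bp <- suppressWarnings(as.numeric(df$start_bp))
  df$end_bp <- suppressWarnings(as.numeric(df$end_bp))
  malformed <- bad[!bad] | FALSE       # placeholder for numeric failures
  numbad <- is.na(df$start_bp) | is.na(df$end_bp) | df$end_bp <= df$start_bp
  n_malformed <- sum(bad) + sum(numbad)
  if (n_malformed > 0.1 * length(lines))
    stop_input(sprintf("%d of %d IBD lines are malformed (> 10%%)",
                       n_malformed, length(lines)))
  if (n_malformed > 0)
    message(sprintf("read_ibd: skipped %d malformed of %d lines",
                    n_malformed, length(lines)))
  df <- df[!numbad, , drop = FALSE]
  known <- df$chrom %in% unique(map$chrom)
  if (any(!known)) {
    warning(sprintf("skipping %d segments on chromosomes absent from the map",
                    sum(!known)))
    df <- df[known, , drop = FALSE]
  }
  if (!nrow(df)) return(empty_ibd_segments())
  df$start_cm <- NA_real_; df$end_cm <- NA_real_
  for (ch in unique(df$chrom)) {
    i <- df$chrom == ch
    df$start_cm[i] <- interp_cm(map, ch, df$start_bp[i])
    df$end_cm[i] <- interp_cm(map, ch, df$end_bp[i])
  }
  # split centromere-spanning segments at the arm boundary
  out <- list()
  for (ch in unique(df$chrom)) {
    i <- which(df$chrom == ch)
    a1 <- arm_at(map, ch, df$start_cm[i])
    a2 <- arm_at(map, ch, df$end_cm[i])
    same <- a1 == a2
    d <- df[i[same], , drop = FALSE]
    d$arm <- a1[same]
    out[[length(out) + 1L]] <- d
    for (k in i[!same]) {
      # boundary position: midpoint between adjacent arm anchor extremes
      armk1 <- arm_at(map, ch, df$start_cm[k])
      armk2 <- arm_at(map, ch, df$end_cm[k])
      j <- map$chrom == ch
      hi <- max(map$cm[j][map$arm[j] == armk1])
      lo <- min(map$cm[j][map$arm[j] == armk2])
      cut_cm <- (hi + lo) / 2
      cut_bp <- stats::approx(map$cm[j], map$bp[j], xout = cut_cm,
                              rule = 2, ties = "ordered")$y
      left <- df[k, , drop = FALSE]
      left$end_cm <- cut_cm; left$end_bp <- cut_bp; left$arm <- armk1
      right <- df[k, , drop = FALSE]
      right$start_cm <- cut_cm; right$start_bp <- cut_bp; right$arm <- armk2
      out[[length(out) + 1L]] <- rbind(left, right)
    }
  }
  df <- do.call(rbind, out)
  df$region <- paste(df$chrom, df$arm, sep = "_")
  df$length_cm <- df$end_cm - df$start_cm
  df <- df[df$length_cm > 0, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("ibd_segments", "data.frame")
  df
}

empty_ibd_segments <- function() {
  df <- data.frame(id1 = character(0), hap1 = character(0),
                   id2 = character(0), hap2 = character(0),
                   chrom = character(0), start_bp = numeric(0),
                   end_bp = numeric(0), start_cm = numeric(0),
                   end_cm = numeric(0), arm = character(0),
                   region = character(0), length_cm = numeric(0),
                   stringsAsFactors = FALSE)
  class(df) <- c("ibd_segments", "data.frame")
  df
}

#' Write IBD segments in the tab-separated detector format
#' @param segments an `ibd_segments` data.frame (or any data.frame with
#'   columns `id1, hap1, id2, hap2, chrom, start_bp, end_bp`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ibd <- function(segments, path) {
  df <- as.data.frame(segments)[c("id1", "hap1", "id2", "hap2", "chrom",
                                  "start_bp", "end_bp")]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Build the per-region IBD length histogram
#'
#' Counts IBD segments per (chromosome arm, length bin).  Bins are
#' half-open `[lo, hi)` intervals of width `bin_width_cm` starting at
#' `u_min` and ending at the longest retained segment; segments shorter
#' than `u_min` are dropped.  A segment is assigned to the arm containing
#' its midpoint.  Region genetic lengths come from the map; `n_pairs` is
#' the number of analysed haplotype pairs (4 per unordered pair of diploid
#' individuals) and is required for model expectations.
#'
#' @param segments an `ibd_segments` data.frame from [read_ibd()] or the
#'   simulator.
#' @param map a [genetic_map()] (used for region lengths).
#' @param u_min minimum segment length in cM (default 2).
#' @param bin_width_cm bin width in cM (default 0.5).
#' @param n_pairs number of analysed haplotype pairs; by default inferred
#'   as `4 * choose(k, 2)` from the `k` distinct individual ids seen in the
#'   segment list (only safe when every pair was scanned).
#' @return an object of class `ibd_histogram`: data.frame with columns
#'   `region`, `bin_lo`, `bin_hi`, `count`, plus attributes
#'   `region_lengths` (named vector, Morgans), `n_pairs`, `u_min`.
#' @export
build_ibd_histogram <- function(segments, map, u_min = 2,
                                bin_width_cm = 0.5, n_pairs = NULL) {
  segments <- as.data.frame(segments)
  segments <- segments[segments$length_cm >= u_min, , drop = FALSE]
  if (!nrow(segments))
    stop_input("no IBD segments of length >= ", u_min,
               " cM; cannot build a histogram")
  if (is.null(n_pairs)) {
    ids <- unique(c(segments$id1, segments$id2))
    n_pairs <- 4 * choose(length(ids), 2)
  }
  at <- arm_table(map)
  lens <- stats::setNames(at$length_morgans, at$region)
  # arm of the midpoint (segments were already split at arm boundaries on
  # read, so midpoint assignment is a no-op there; simulator output uses it)
  mid <- (segments$start_cm + segments$end_cm) / 2
  if (is.null(segments$region) || anyNA(segments$region)) {
    segments$arm <- vapply(seq_len(nrow(segments)), function(k)
      arm_at(map, segments$chrom[k], mid[k]), character(1))
    segments$region <- paste(segments$chrom, segments$arm, sep = "_")
  }
  maxlen <- max(segments$length_cm)
  edges <- seq(u_min, maxlen + bin_width_cm, by = bin_width_cm)
  bins <- findInterval(segments$length_cm, edges)
  regions <- names(lens)
  counts <- table(factor(segments$region, levels = regions),
                  factor(bins, levels = seq_len(length(edges) - 1L)))
  df <- expand.grid(region = regions, bin = seq_len(length(edges) - 1L),
                    stringsAsFactors = FALSE)
  df$bin_lo <- edges[df$bin]
  df$bin_hi <- edges[df$bin + 1L]
  df$count <- as.vector(counts[cbind(df$region, as.character(df$bin))])
  df <- df[order(df$region, df$bin_lo), c("region", "bin_lo", "bin_hi",
                                          "count")]
  rownames(df) <- NULL
  structure(df, class = c("ibd_histogram", "data.frame"),
            region_lengths = lens, n_pairs = n_pairs, u_min = u_min)
}

#' @export
print.ibd_histogram <- function(x, ...) {
  cat(sprintf("IBD histogram: %d regions x %d length bins [%g, %g) cM, %d segments, %g haplotype pairs\n",
              length(attr(x, "region_lengths")),
              length(unique(x$bin_lo)), min(x$bin_lo), max(x$bin_hi),
              sum(x$count), attr(x, "n_pairs")))
  invisible(x)
}

#' Read / write an IBD histogram as TSV
#'
#' The table carries one row per (region, bin) with the region genetic
#' length and pair count repeated, so a written histogram reads back
#' identically.
#'
#' @param x an `ibd_histogram`.
#' @param path file path.
#' @return the histogram (read) or `path` (write, invisibly).
#' @export
write_ibd_histogram <- function(x, path) {
  df <- as.data.frame(x)
  df$length_morgans <- attr(x, "region_lengths")[df$region]
  df$n_pairs <- attr(x, "n_pairs")
  df$u_min <- attr(x, "u_min")
  write_tsv(df, path)
}

#' @rdname write_ibd_histogram
#' @export
read_ibd_histogram <- function(path) {
  df <- read_tsv(path, colClasses = c(region = "character"))
  lens <- tapply(df$length_morgans, df$region, `[`, 1L)
  out <- df[c("region", "bin_lo", "bin_hi", "count")]
  out <- out[order(out$region, out$bin_lo), ]
  rownames(out) <- NULL
  structure(out, class = c("ibd_histogram", "data.frame"),
            region_lengths = stats::setNames(as.vector(lens), names(lens)),
            n_pairs = df$n_pairs[1], u_min = df$u_min[1])
}
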