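#' Genotype panels
#'
#' A `genotype_panel` stores unphased allele counts for `n` samples at `m`
#' sites as an `n x m` integer matrix with values 0, 1, 2 and `NA` for
#' missing calls.  Pseudo-haploid panels (one sequencing allele sampled per
#' site, the standard representation for low-coverage ancient DNA) store
#' the sampled allele doubled, so only 0 and 2 occur.
#'
#' @param genotypes samples-by-sites matrix of allele counts.
#' @param sites a data.frame with one row per site and columns `chrom`,
#'   `arm`, `cm` (and optionally `bp`, `id`).
#' @param ploidy `"diploid"` or `"pseudo_haploid"`.
#' @param sample_ids optional sample identifiers.
#' @return an object of class `genotype_panel`.
#' @export
genotype_panel <- function(genotypes, sites,
                           ploidy = c("diploid", "pseudo_haploid"),
                           sample_ids = NULL) {
  ploidy <- match.arg(ploidy)
  genotypes <- as.matrix(genotypes)
  if (!all(genotypes %in% c(0L, 1L, 2L, NA)))
    stop_input("genotypes must be 0, 1, 2 or NA")
  if (ploidy == "pseudo_haploid" && any(genotypes == 1L, na.rm = TRUE))
    stop_input("pseudo-haploid panels cannot contain heterozygous calls")
  sites <- as.data.frame(sites)
  need <- c("chrom", "arm", "cm")
  if (!all(need %in% names(sites)))
    stop_input("'sites' must have columns chrom, arm, cm")
  if (nrow(sites) != ncol(genotypes))
    stop_input("'sites' must have one row per genotype column")
  if (is.null(sites$bp)) sites$bp <- round(sites$cm * 1e6)
  if (is.null(sites$id)) sites$id <- sprintf("snp%06d", seq_len(nrow(sites)))
  sites$region <- paste(sites$chrom, sites$arm, sep = "_")
  sample_ids <- sample_ids %||% sprintf("sample%04d", seq_len(nrow(genotypes)))
  storage.mode(genotypes) <- "integer"
  dimnames(genotypes) <- list(sample_ids, sites$id)
  structure(list(genotypes = genotypes, sites = sites, ploidy = ploidy,
                 sample_ids = sample_ids),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  miss <- mean(is.na(x$genotypes))
  cat(sprintf("%s genotype panel: %d samples x %d sites (%.1f%% missing), %d regions\n",
              x$ploidy, nrow(x$genotypes), ncol(x$genotypes), 100 * miss,
              length(unique(x$sites$region))))
  invisible(x)
}

# Observed minor allele frequency per site (from non-missing entries,
# allele dosage scale 0..1).
panel_freq <- function(panel) {
  colMeans(panel$genotypes, na.rm = TRUE) / 2
}

# Number of non-missing calls per site.
panel_nobs <- function(panel) {
  colSums(!is.na(panel$genotypes))
}

# Drop sites failing a MAF threshold or with < 2 observations.
filter_sites <- function(panel, maf_min = 0) {
  p <- panel_freq(panel)
  maf <- pmin(p, 1 - p)
  keep <- which(panel_nobs(panel) >= 2L & maf > maf_min & maf < 0.5 + 1e-12 &
                  p > 0 & p < 1)
  genotype_panel(panel$genotypes[, keep, drop = FALSE],
                 panel$sites[keep, , drop = FALSE], panel$ploidy,
                 panel$sample_ids)
}

## ---- PLINK BED/BIM/FAM codec -------------------------------------------
## Minimal reader/writer for the PLINK 1 binary genotype format
## (SNP-major, 2-bit codes: 00 hom minor=2, 01 missing, 10 het=1,
## 11 hom major=0).  Implemented in-package because no installed package
## provides it; round-trip tested.

#' Read or write a genotype panel in PLINK 1 binary format
#'
#' `write_plink_panel()` emits `<prefix>.bed/.bim/.fam` plus
#' `<prefix>.armmap.tsv` carrying the chromosome-arm assignment (the `.bim`
#' format has no arm column).  `read_plink_panel()` reads them back; when
#' the arm map file is absent each chromosome becomes a single arm.
#'
#' @param panel a [genotype_panel()].
#' @param prefix file prefix (no extension).
#' @param ploidy interpretation of the genotypes on read.
#' @return the panel (read) or `prefix` (write, invisibly).
#' @export
write_plink_panel <- function(panel, prefix) {
  g <- panel$genotypes
  s <- panel$sites
  fam <- data.frame(fid = panel$sample_ids, iid = panel$sample_ids,
                    pat = 0, mat = 0, sex = 0, phe = -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  bim <- data.frame(chrom = s$chrom, id = s$id, cm = s$cm, bp = s$bp,
                    a1 = "A", a2 = "G")
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_tsv(s[c("id", "chrom", "arm")], paste0(prefix, ".armmap.tsv"))
  n <- nrow(g)
  codes <- matrix(1L, n, ncol(g))         # 01 = missing
  codes[!is.na(g) & g == 0L] <- 3L        # 11 hom major
  codes[!is.na(g) & g == 1L] <- 2L        # 10 het
  codes[!is.na(g) & g == 2L] <- 0L        # 00 hom minor
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  nbytes <- ceiling(n / 4)
  pad <- nbytes * 4 - n
  for (j in seq_len(ncol(g))) {
    cj <- c(codes[, j], rep(1L, pad))
    quads <- matrix(cj, nrow = 4)
    bytes <- quads[1, ] + quads[2, ] * 4L + quads[3, ] * 16L + quads[4, ] * 64L
    writeBin(as.raw(bytes), con)
  }
  invisible(prefix)
}

#' @rdname write_plink_panel
#' @export
read_plink_panel <- function(prefix, ploidy = c("diploid", "pseudo_haploid")) {
  ploidy <- match.arg(ploidy)
  fam <- utils::read.table(paste0(prefix, ".fam"), stringsAsFactors = FALSE)
  bim <- utils::read.table(paste0(prefix, ".bim"), stringsAsFactors = FALSE)
  names(bim) <- c("chrom", "id", "cm", "bp", "a1", "a2")
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = 3 + ceiling(n / 4) * m)
  if (length(raw) < 3 || raw[1] != 0x6c || raw[2] != 0x1b)
    stop_input("not a PLINK .bed file: ", prefix, ".bed")
  if (raw[3] != 0x01) stop_input("only SNP-major .bed files are supported")
  body <- as.integer(raw[-(1:3)])
  nbytes <- ceiling(n / 4)
  quads <- rbind(body %% 4L, (body %/% 4L) %% 4L,
                 (body %/% 16L) %% 4L, (body %/% 64L) %% 4L)
  codes <- matrix(as.vector(quads), nrow = nbytes * 4)[seq_len(n), ,
                                                       drop = FALSE]
  g <- matrix(NA_integer_, n, m)
  g[codes == 3L] <- 0L
  g[codes == 2L] <- 1L
  g[codes == 0L] <- 2L
  armfile <- paste0(prefix, ".armmap.tsv")
  if (file.exists(armfile)) {
    am <- read_tsv(armfile, colClasses = "character")
    arm <- am$arm[match(bim$id, am$id)]
    arm[is.na(arm)] <- "whole"
  } else arm <- rep("whole", m)
  sites <- data.frame(chrom = as.character(bim$chrom), arm = arm,
                      cm = bim$cm, bp = bim$bp, id = bim$id,
                      stringsAsFactors = FALSE)
  genotype_panel(g, sites, ploidy, sample_ids = as.character(fam[[2]]))
}

#' Read a genotype panel from an uncompressed VCF file
#'
#' Uses the `vcfR` package to parse the VCF and converts `GT` fields to
#' allele counts; positions are mapped to cM with the supplied genetic map
#' and each site is assigned to a chromosome arm.
#'
#' @param path VCF file.
#' @param map a [genetic_map()] providing cM coordinates and arm labels.
#' @param ploidy panel interpretation, as in [genotype_panel()].
#' @return a [genotype_panel()].
#' @export
read_vcf_panel <- function(path, map, ploidy = c("diploid", "pseudo_haploid")) {
  ploidy <- match.arg(ploidy)
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop_input("reading VCF requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(x) {
    out <- rep(NA_integer_, length(x))
    ok <- !is.na(x) & x != "." & x != "./." & x != ".|."
    alleles <- gsub("\\|", "/", x[ok])
    out[ok] <- vapply(strsplit(alleles, "/"),
                      function(a) sum(a == "1"), integer(1))
    out
  }
  g <- t(apply(gt, 1, count_alt))           # sites x samples
  g <- t(g)                                  # samples x sites
  chrom <- as.character(vcfR::getCHROM(v))
  bp <- as.numeric(vcfR::getPOS(v))
  cm <- vapply(seq_along(bp), function(k) interp_cm(map, chrom[k], bp[k]),
               numeric(1))
  arm <- vapply(seq_along(bp), function(k) arm_at(map, chrom[k], cm[k]),
                character(1))
  if (ploidy == "pseudo_haploid") g[g == 1L] <- NA_integer_
  sites <- data.frame(chrom = chrom, arm = arm, cm = cm, bp = bp,
                      id = vcfR::getID(v), stringsAsFactors = FALSE)
  genotype_panel(g, sites, ploidy, sample_ids = colnames(gt))
}
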