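# Shared fixtures, built in code and memoised across test files.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# Small genome layouts
tiny_genome <- function(n_arms = 6, morgans = 5) synthetic_genome(n_arms, morgans)

# Five single-arm chromosomes of 1 Morgan each (cross-chromosome tests)
five_chrom_genome <- function() {
  data.frame(region = paste0(1:5, "_w"), chrom = as.character(1:5),
             arm = "w", length_morgans = 1, stringsAsFactors = FALSE)
}

# A demography with effectively no coalescence over the horizon:
# the zero-LD / baseline-only limit.
huge_ne_model <- function() demographic_model(c(0, 125), c(1e7, 1e7))

# Non-uniform genetic map used by the IBD reader tests: one chromosome,
# two arms, deliberately non-linear bp <-> cM relation.
reader_map <- function() {
  genetic_map(chrom = rep("7", 6), arm = rep(c("p", "q"), each = 3),
              bp = c(0, 2e6, 6e6, 8e6, 12e6, 20e6),
              cm = c(0, 1, 5, 6, 12, 16))
}

# Constant-scenario LD summaries at the standard test scale.
constant_ld_20 <- function(seed = 101) {
  simulate_ld_summaries(scenario("constant"), 100, synthetic_genome(20, 18),
                        seed = seed)
}

# Deterministic hand-built binned LD object (3+ regions, simple values).
toy_binned_ld <- function(values) {
  regs <- names(values)
  bins <- seq(0.5, by = 0.5, length.out = length(values[[1]]))
  df <- do.call(rbind, lapply(regs, function(r)
    data.frame(region = r, bin_lo = bins, bin_hi = bins + 0.5,
               y = values[[r]], n_pairs = 100, var = 1e-8,
               stringsAsFactors = FALSE)))
  binned_ld(df, n_eff = 50, ploidy = "diploid")
}
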