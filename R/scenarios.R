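#' Built-in demographic scenarios
#'
#' A small library of single-population haploid demographic histories used
#' throughout the package for simulation studies and tests:
#'
#' * `"constant"`: \eqn{N_e \equiv 20000}.
#' * `"expansion"`: exponential growth from 20,000 at generation 50 to
#'   200,000 haploids at present; constant 20,000 earlier.
#' * `"collapse"`: exponential decline from 20,000 at generation 100 to
#'   2,000 haploids at present.
#' * `"bottleneck"`: 200,000 at present, contracting exponentially to 2,000
#'   at generation 25 and recovering to 20,000 at generation 50; constant
#'   earlier.
#'
#' Sizes are haploid counts (a diploid census of N corresponds to ~2N).
#' All scenarios are defined on a grid extending to `t_max`.
#'
#' @param name one of `"constant"`, `"expansion"`, `"collapse"`,
#'   `"bottleneck"`.
#' @param t_max horizon in generations (default 125).
#' @return a [demographic_model()].
#' @examples
#' ne_at(scenario("bottleneck"), 25)   # 2000
#' @export
scenario <- function(name = c("constant", "expansion", "collapse",
                              "bottleneck"), t_max = 125) {
  name <- match.arg(name)
  switch(name,
    constant = demographic_model(c(0, t_max), c(20000, 20000), t_max),
    expansion = demographic_model(c(0, 50, t_max),
                                  c(200000, 20000, 20000), t_max),
    collapse = demographic_model(c(0, 100, t_max),
                                 c(2000, 20000, 20000), t_max),
    bottleneck = demographic_model(c(0, 25, 50, t_max),
                                   c(200000, 2000, 20000, 20000), t_max)
  )
}

#' Two-population admixture scenario parameters
#'
#' Describes a pooled or recently admixed pair of populations: an ancestral
#' population of 10,000 haploids splits at `t_split` into two groups of
#' 5,000 each, which merge again at `t_adm` with equal contributions into a
#' population of 10,000.  For convenience the divergence can be given as a
#' fixation index via [fst_to_tsplit()].
#'
#' @param t_split split time in generations (> `t_adm`).
#' @param t_adm admixture (merge) time in generations (`>= 0`).
#' @param n_anc,n_branch,n_merged haploid sizes of the ancestral
#'   population, each diverged branch, and the merged population.
#' @return a list of class `admixture_scenario`.
#' @export
admixture_scenario <- function(t_split, t_adm = 25, n_anc = 10000,
                               n_branch = 5000, n_merged = 10000) {
  if (t_split <= t_adm) stop_input("'t_split' must exceed 't_adm'")
  structure(list(t_split = t_split, t_adm = t_adm, n_anc = n_anc,
                 n_branch = n_branch, n_merged = n_merged,
                 fst = 1 - exp(-(t_split - t_adm) / (2 * n_branch))),
            class = "admixture_scenario")
}

#' Map a target fixation index to a split time
#'
#' Uses the drift approximation \eqn{F_{st} \approx 1 - e^{-T/(2N)}} where
#' `T` is the time each branch evolves independently and `N` the branch
#' haploid size; used only to label admixture scenarios.
#'
#' @param fst target fixation index in (0, 1).
#' @param t_adm admixture time (generations).
#' @param n_branch haploid size of each diverged branch.
#' @return split time in generations.
#' @export
fst_to_tsplit <- function(fst, t_adm = 25, n_branch = 5000) {
  if (fst <= 0 || fst >= 1) stop_input("'fst' must be in (0, 1)")
  t_adm - 2 * n_branch * log(1 - fst)
}
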