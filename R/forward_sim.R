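#' Configure a forward-in-time simulation
#'
#' Parameters of a single panmictic, cyclically parthenogenetic diploid
#' population simulated with discrete non-overlapping generations and soft
#' selection to a constant census size `N`. Reproduction is clonal except
#' every `sex_interval`-th generation, which is sexual: each offspring then
#' draws two distinct parents and receives one recombinant gamete from each
#' (crossover count Poisson(`rec * (L - 1)`)). New mutations arise at
#' Poisson(`2 * N * L * mu`) per generation; each is nonsynonymous with
#' probability `nonsyn_fraction` and, if so, gets a selection coefficient
#' from `dfe` (synonymous mutations are neutral). Fitness is multiplicative
#' across sites with per-site contribution `1 + s` for homozygotes and
#' `1 + dominance_h * s` for heterozygotes.
#'
#' @param N Census (= target effective) population size, individuals.
#' @param L Length of the simulated coding sequence, base pairs.
#' @param mu Mutation rate per site per generation.
#' @param rec Crossover rate per site per generation.
#' @param sex_interval Generations between sexual episodes; 1 means fully
#'   sexual, the default 8 matches one sexual generation per season of roughly
#'   eight clonal ones in rock-pool *Daphnia*.
#' @param nonsyn_fraction Fraction of mutational opportunity that is
#'   nonsynonymous (default 0.70, the standard coding-DNA convention of about
#'   2.3:1 nonsynonymous:synonymous sites).
#' @param dfe A [dfe_spec()] for nonsynonymous mutations.
#' @param dominance_h Dominance coefficient (default 0.5, additive).
#' @param burnin_multiplier Burn-in length in multiples of `N` generations
#'   (default 10); used by [run_equilibrium()].
#' @param n_generations_total Total generations for substitution-tracking
#'   runs; used by [run_substitutions()].
#' @param seed Integer seed; `NULL` leaves the RNG stream untouched.
#'
#' @return An object of class `sim_config`.
#' @examples
#' sim_config(N = 100, L = 1e4, mu = 1e-7)
#' @export
sim_config <- function(N, L, mu, rec = 1e-8, sex_interval = 8,
                       nonsyn_fraction = 0.70,
                       dfe = dfe_spec("fixed_zero"),
                       dominance_h = 0.5, burnin_multiplier = 10,
                       n_generations_total = NULL, seed = NULL) {
  if (N < 2) abort("`N` must be >= 2.")
  if (L < 1) abort("`L` must be >= 1.")
  if (mu < 0) abort("`mu` must be >= 0.")
  if (rec < 0) abort("`rec` must be >= 0.")
  if (sex_interval < 1) abort("`sex_interval` must be >= 1.")
  if (nonsyn_fraction <= 0 || nonsyn_fraction >= 1)
    abort("`nonsyn_fraction` must lie in (0, 1).")
  stopifnot(inherits(dfe, "dfe_spec"))
  structure(
    list(N = as.integer(N), L = as.numeric(L), mu = mu, rec = rec,
         sex_interval = as.integer(sex_interval),
         nonsyn_fraction = nonsyn_fraction, dfe = dfe,
         dominance_h = dominance_h,
         burnin_multiplier = burnin_multiplier,
         n_generations_total = n_generations_total, seed = seed),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> N =", x$N, " L =", format(x$L, big.mark = ","),
      " mu =", x$mu, "\n  sex every", x$sex_interval,
      "generations; nonsyn fraction", x$nonsyn_fraction,
      "; DFE:", x$dfe$kind, "\n")
  invisible(x)
}

dfe_kind_code <- function(dfe) {
  switch(dfe$kind, fixed_zero = 0L, gamma_deleterious = 1L,
         gamma_plus_beneficial = 2L)
}

run_sim_once <- function(config, n_generations, track) {
  sim_forward_cpp(
    N = config$N, L = config$L, mu = config$mu, rec = config$rec,
    sex_interval = config$sex_interval,
    nonsyn_fraction = config$nonsyn_fraction,
    dfe_kind = dfe_kind_code(config$dfe),
    gamma_mean = config$dfe$gamma_mean,
    gamma_shape = config$dfe$gamma_shape,
    beneficial_fraction = config$dfe$beneficial_fraction,
    beneficial_s = config$dfe$beneficial_s,
    dominance_h = config$dominance_h,
    n_generations = as.integer(n_generations),
    track_substitutions = track
  )
}

#' Simulate to mutation-drift equilibrium and report class-wise diversity
#'
#' Starts from a monomorphic population, runs `burnin_multiplier * N`
#' generations, and returns nucleotide diversity at nonsynonymous and
#' synonymous sites. Per segregating site the unbiased heterozygosity
#' `2 p (1 - p) * 2N / (2N - 1)` is accumulated and divided by the number of
#' sites of that class (`L * nonsyn_fraction` or `L * (1 - nonsyn_fraction)`).
#'
#' @param config A [sim_config()].
#' @param reps Number of replicate simulations.
#' @return A tibble with one row per replicate: `rep`, `pi_n`, `pi_s`,
#'   `n_seg_n`, `n_seg_s`.
#' @examples
#' cfg <- sim_config(N = 50, L = 5e3, mu = 1e-6, seed = 1)
#' run_equilibrium(cfg)
#' @export
run_equilibrium <- function(config, reps = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  gens <- round(config$burnin_multiplier * config$N)
  purrr::map_dfr(seq_len(reps), function(r) {
    res <- run_sim_once(config, gens, track = FALSE)
    tibble::tibble(rep = r, pi_n = res$pi_n, pi_s = res$pi_s,
                   n_seg_n = as.integer(res$n_seg_n),
                   n_seg_s = as.integer(res$n_seg_s))
  })
}

#' Simulate with substitution tracking
#'
#' Same dynamics as [run_equilibrium()], but mutations reaching frequency 1
#' across all `2N` haplotypes are removed from the segregating set and counted
#' as substitutions of their class. Runs for `n_generations_total` generations.
#'
#' @param config A [sim_config()] with `n_generations_total` set.
#' @param reps Number of replicate simulations.
#' @return A tibble with one row per replicate: polymorphism counts `P_n`,
#'   `P_s` (segregating sites at the final generation), cumulative fixation
#'   counts `D_n`, `D_s`, and per-site rates `d_n = D_n / (L * f)`,
#'   `d_s = D_s / (L * (1 - f))` where `f = nonsyn_fraction`.
#' @examples
#' cfg <- sim_config(N = 50, L = 5e3, mu = 1e-6,
#'                   n_generations_total = 2000, seed = 1)
#' run_substitutions(cfg)
#' @export
run_substitutions <- function(config, reps = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(config$n_generations_total))
    abort("`n_generations_total` must be set for substitution runs.")
  if (!is.null(config$seed)) set.seed(config$seed)
  f <- config$nonsyn_fraction
  purrr::map_dfr(seq_len(reps), function(r) {
    res <- run_sim_once(config, config$n_generations_total, track = TRUE)
    tibble::tibble(
      rep = r,
      P_n = as.integer(res$n_seg_n), P_s = as.integer(res$n_seg_s),
      D_n = as.integer(res$D_n), D_s = as.integer(res$D_s),
      d_n = res$D_n / (config$L * f),
      d_s = res$D_s / (config$L * (1 - f))
    )
  })
}

#' Class-wise diversity from a haplotype matrix
#'
#' Computes nucleotide diversity per site class from explicit haplotypes.
#' Rows are haplotypes (`2N` of them), columns are variant sites; entries are
#' allele states (any atomic type). Per column the unbiased heterozygosity
#' `(1 - sum p_a^2) * 2N / (2N - 1)` is accumulated into its class and divided
#' by the class site total (`total_sites * nonsyn_fraction` or
#' `total_sites * (1 - nonsyn_fraction)`).
#'
#' @param haplotypes Matrix of allele states, one row per haplotype.
#' @param site_class Character vector, one per column, `"nonsyn"` or `"syn"`.
#' @param total_sites Total sequence length the variant columns come from.
#' @param nonsyn_fraction Fraction of `total_sites` that is nonsynonymous.
#' @return A tibble with `pi_n`, `pi_s`, `n_seg_n`, `n_seg_s`.
#' @examples
#' h <- rbind(c("A"), c("G"))
#' class_pi_from_haplotypes(h, "nonsyn", total_sites = 90,
#'                          nonsyn_fraction = 2 / 3)
#' @export
class_pi_from_haplotypes <- function(haplotypes, site_class, total_sites,
                                     nonsyn_fraction) {
  if (!is.matrix(haplotypes)) haplotypes <- as.matrix(haplotypes)
  n_hap <- nrow(haplotypes)
  if (n_hap < 2) abort("At least 2 haplotypes are required.")
  if (length(site_class) != ncol(haplotypes))
    abort("`site_class` must have one entry per haplotype column.")
  if (!all(site_class %in% c("nonsyn", "syn")))
    abort("`site_class` entries must be \"nonsyn\" or \"syn\".")
  corr <- n_hap / (n_hap - 1)
  het <- apply(haplotypes, 2, function(col) {
    p <- table(col) / n_hap
    (1 - sum(p^2)) * corr
  })
  seg <- het > 0
  nons <- site_class == "nonsyn"
  tibble::tibble(
    pi_n = sum(het[nons]) / (total_sites * nonsyn_fraction),
    pi_s = sum(het[!nons]) / (total_sites * (1 - nonsyn_fraction)),
    n_seg_n = sum(seg & nons),
    n_seg_s = sum(seg & !nons)
  )
}
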