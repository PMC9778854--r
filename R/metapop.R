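#' Configure the propagule-model metapopulation simulator
#'
#' Patches (rock pools) on a map undergo yearly extinction, colonization with
#' a strong founder bottleneck (usually a single diploid colonizer), clonal
#' expansion, distance-decaying gene flow, and binomial drift. Defaults follow
#' the long-term demography of the Tvärminne *Daphnia magna* system: about 20%
#' of occupied ponds go extinct per year, about 5% of empty ponds are
#' colonized per year, and ~90% of colonizations are by a single founder. With
#' 300 patches at ~20% equilibrium occupancy the simulator yields on the order
#' of 60 occupied subpopulations, the size of a realistic pond survey.
#'
#' @param n_patches Number of habitat patches.
#' @param coords Optional two-column matrix/data frame of patch coordinates
#'   (`lat`, `lon`, decimal degrees). `NULL` generates island-clustered
#'   coordinates in a ~2 km archipelago.
#' @param extinction_rate Yearly extinction probability per occupied patch.
#' @param colonization_rate Yearly colonization probability per empty patch.
#' @param single_founder_prob Probability a colonization is by one diploid
#'   founder (otherwise two).
#' @param migration_rate Immigration intensity scale: a patch receives
#'   Poisson(`migration_rate * S_i`) immigrants per year, where `S_i` is the
#'   kernel-weighted mass of occupied neighbor patches
#'   (`sum_j exp(-d_ij * migration_decay)`), so immigration declines with
#'   isolation as dispersal decays with distance.
#' @param migration_decay Exponential kernel decay, 1/meters (default 1/200).
#' @param n_loci Number of unlinked biallelic loci.
#' @param source_freq_alpha,source_freq_beta Beta shape parameters of the
#'   metapopulation-wide (ancestral) allele frequencies.
#' @param deme_size Individuals per occupied patch after clonal expansion;
#'   `Inf` disables drift and dilutes immigrants to nothing (a drift-off
#'   proxy).
#' @param years Simulated span in years.
#' @param init_occupancy Fraction of patches occupied at the start.
#' @param drift If `FALSE`, skip the binomial drift step.
#' @param stochastic_migrants If `FALSE`, founder and immigrant allele dosages
#'   are replaced by their expectations (deterministic convex mixing; useful
#'   for conservation checks).
#' @param seed Integer seed; `NULL` leaves the RNG stream untouched.
#'
#' @return An object of class `metapop_config`.
#' @examples
#' metapop_config(n_patches = 50, n_loci = 100, years = 10)
#' @export
metapop_config <- function(n_patches = 300, coords = NULL,
                           extinction_rate = 0.20, colonization_rate = 0.05,
                           single_founder_prob = 0.90, migration_rate = 5,
                           migration_decay = 1 / 200, n_loci = 2000,
                           source_freq_alpha = 0.7, source_freq_beta = 0.7,
                           deme_size = 100, years = 30,
                           init_occupancy = 0.20, drift = TRUE,
                           stochastic_migrants = TRUE, seed = NULL) {
  for (r in c(extinction_rate, colonization_rate, single_founder_prob,
              init_occupancy))
    if (r < 0 || r > 1) abort("Rates and probabilities must lie in [0, 1].")
  if (n_loci < 1) abort("`n_loci` must be >= 1.")
  if (deme_size < 1) abort("`deme_size` must be >= 1.")
  if (!is.null(coords)) {
    coords <- as.data.frame(coords)
    if (!all(c("lat", "lon") %in% names(coords)))
      abort("`coords` must have columns `lat` and `lon`.")
    if (nrow(coords) != n_patches)
      abort("`coords` must have one row per patch.")
  }
  structure(
    list(n_patches = as.integer(n_patches), coords = coords,
         extinction_rate = extinction_rate,
         colonization_rate = colonization_rate,
         single_founder_prob = single_founder_prob,
         migration_rate = migration_rate,
         migration_decay = migration_decay,
         n_loci = as.integer(n_loci),
         source_freq_alpha = source_freq_alpha,
         source_freq_beta = source_freq_beta,
         deme_size = deme_size, years = as.integer(years),
         init_occupancy = init_occupancy, drift = drift,
         stochastic_migrants = stochastic_migrants, seed = seed),
    class = "metapop_config"
  )
}

# Rock-pool field around 59.82 N, 23.25 E: overlapping shoreline clusters
# plus a sparse background, giving a continuous gradient from dense
# neighborhoods to isolated ponds (pair distances ~20 m to ~2 km).
default_pond_coords <- function(n_patches, n_clusters = 6) {
  lat0 <- 59.82
  lon0 <- 23.25
  m_per_deg_lat <- 111320
  m_per_deg_lon <- m_per_deg_lat * cos(lat0 * pi / 180)
  cx <- runif(n_clusters, -750, 750)
  cy <- runif(n_clusters, -750, 750)
  cl <- sample.int(n_clusters, n_patches, replace = TRUE)
  bg <- runif(n_patches) < 0.15
  x <- ifelse(bg, runif(n_patches, -750, 750), cx[cl] + rnorm(n_patches, sd = 150))
  y <- ifelse(bg, runif(n_patches, -750, 750), cy[cl] + rnorm(n_patches, sd = 150))
  data.frame(lat = lat0 + y / m_per_deg_lat, lon = lon0 + x / m_per_deg_lon)
}

#' Pairwise haversine distances between ponds, in meters
#'
#' Spherical Earth with radius 6,371,000 m.
#'
#' @param lat,lon Decimal-degree coordinate vectors.
#' @return A symmetric matrix of distances in meters.
#' @export
pond_distances <- function(lat, lon) {
  geosphere::distm(cbind(lon, lat),
                   fun = function(x, y)
                     geosphere::distHaversine(x, y, r = 6371000))
}

#' Initialize a metapopulation state
#'
#' Draws per-locus metapopulation-wide allele frequencies from the configured
#' Beta distribution, occupies `init_occupancy` of the patches, and founds
#' each initial subpopulation with a single diploid colonizer sampled at
#' Hardy-Weinberg proportions from those source frequencies.
#'
#' @param config A [metapop_config()].
#' @return An object of class `metapop_state`.
#' @export
metapop_init <- function(config) {
  stopifnot(inherits(config, "metapop_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_patches
  coords <- if (is.null(config$coords)) default_pond_coords(n)
            else config$coords
  source_p <- rbeta(config$n_loci, config$source_freq_alpha,
                    config$source_freq_beta)
  occupied <- runif(n) < config$init_occupancy
  freq <- matrix(NA_real_, nrow = n, ncol = config$n_loci)
  founders_k <- rep(NA_integer_, n)
  for (i in which(occupied)) {
    dosage <- founder_dosage(1L, source_p, config$stochastic_migrants)
    freq[i, ] <- dosage / 2
    founders_k[i] <- 1L
  }
  structure(
    list(
      patches = tibble::tibble(
        patch = sprintf("P%03d", seq_len(n)),
        lat = coords$lat, lon = coords$lon,
        occupied = occupied,
        age = ifelse(occupied, 0, NA_real_),
        founders_k = founders_k,
        n_foundings = as.integer(occupied)
      ),
      freq = freq,
      source_p = source_p,
      dist = pond_distances(coords$lat, coords$lon),
      year = 0L
    ),
    class = "metapop_state"
  )
}

#' @export
print.metapop_state <- function(x, ...) {
  cat("<metapop_state> year", x$year, ":", sum(x$patches$occupied), "of",
      nrow(x$patches), "patches occupied;", ncol(x$freq), "loci\n")
  invisible(x)
}

founder_dosage <- function(k, p, stochastic = TRUE) {
  if (stochastic) rbinom(length(p), 2L * k, p) else 2 * k * p
}

kernel_mixture <- function(state, config, focal, sources) {
  w <- exp(-state$dist[focal, sources] * config$migration_decay)
  if (sum(w) <= 0) w <- rep(1, length(sources))
  p <- drop(w %*% state$freq[sources, , drop = FALSE]) / sum(w)
  pmin(pmax(p, 0), 1) # guard floating-point spill outside [0, 1]
}

#' Advance a metapopulation by one year
#'
#' In order: (1) each occupied patch goes extinct with probability
#' `extinction_rate`; (2) each patch that was empty at the start of the year
#' is colonized with probability `colonization_rate`, by one diploid founder
#' with probability `single_founder_prob` (else two), sampled at
#' Hardy-Weinberg proportions from the kernel-weighted frequency mixture of
#' surviving occupied patches (falling back to the Beta source distribution
#' when none exist); (3) surviving occupied patches receive
#' Poisson(`migration_rate * S_i`) immigrants drawn from the kernel mixture
#' of the other occupied patches, admixed in proportion
#' `arrivals / deme_size`;
#' (4) binomial drift resamples each surviving patch's frequencies as
#' `Binomial(2 * deme_size, p) / (2 * deme_size)`; (5) surviving patches age
#' by one year while patches founded this year stay at age 0 (founder
#' frequencies are preserved through clonal expansion).
#'
#' @param state A [metapop_init()] state.
#' @param config The matching [metapop_config()].
#' @return The advanced `metapop_state`.
#' @export
step_year <- function(state, config) {
  stopifnot(inherits(state, "metapop_state"),
            inherits(config, "metapop_config"))
  n <- config$n_patches
  occ0 <- state$patches$occupied
  empty0 <- !occ0

  # (1) extinction
  dies <- occ0 & runif(n) < config$extinction_rate
  survivors <- occ0 & !dies
  state$patches$occupied[dies] <- FALSE
  state$patches$age[dies] <- NA_real_
  state$freq[dies, ] <- NA_real_

  # (2) colonization of patches empty at the start of the year
  colonized <- which(empty0 & runif(n) < config$colonization_rate)
  src <- which(survivors)
  for (i in colonized) {
    p_src <- if (length(src) == 0) state$source_p
             else kernel_mixture(state, config, i, src)
    k <- if (runif(1) < config$single_founder_prob) 1L else 2L
    dosage <- founder_dosage(k, p_src, config$stochastic_migrants)
    state$freq[i, ] <- dosage / (2 * k)
    state$patches$occupied[i] <- TRUE
    state$patches$age[i] <- 0
    state$patches$founders_k[i] <- k
    state$patches$n_foundings[i] <- state$patches$n_foundings[i] + 1L
  }

  # (3) migration into surviving patches: the arrival intensity scales with
  # the kernel-weighted mass of occupied neighbor patches, so isolated ponds
  # receive fewer immigrants (exponentially decaying dispersal)
  if (config$migration_rate > 0 && length(src) > 1) {
    for (i in src) {
      nb <- setdiff(src, i)
      s_i <- sum(exp(-state$dist[i, nb] * config$migration_decay))
      m <- rpois(1, config$migration_rate * s_i)
      if (m == 0) next
      lambda <- min(1, m / config$deme_size)
      if (lambda <= 0) next
      p_mix <- kernel_mixture(state, config, i, nb)
      p_imm <- if (config$stochastic_migrants)
                 rbinom(config$n_loci, 2L * m, p_mix) / (2 * m)
               else p_mix
      state$freq[i, ] <- (1 - lambda) * state$freq[i, ] + lambda * p_imm
    }
  }

  # (4) drift in surviving patches (newly founded demes are clonal expansions)
  if (config$drift && is.finite(config$deme_size)) {
    two_k <- 2L * as.integer(config$deme_size)
    for (i in src) {
      state$freq[i, ] <- rbinom(config$n_loci, two_k, state$freq[i, ]) / two_k
    }
  }

  # (5) ageing
  state$patches$age[survivors] <- state$patches$age[survivors] + 1
  state$year <- state$year + 1L
  state
}

#' Run the metapopulation simulator
#'
#' Initializes a state with [metapop_init()] and advances it `config$years`
#' times with [step_year()].
#'
#' @param config A [metapop_config()].
#' @return The final `metapop_state`.
#' @examples
#' cfg <- metapop_config(n_patches = 40, n_loci = 50, years = 5, seed = 1)
#' simulate_metapop(cfg)
#' @export
simulate_metapop <- function(config) {
  state <- metapop_init(config)
  for (y in seq_len(config$years)) state <- step_year(state, config)
  state
}

#' Founder-effect FST experiment
#'
#' Founds `n_founded` demes from a common source pool, each by `k_founders`
#' diploid colonizers sampled at Hardy-Weinberg proportions, treats each deme
#' as the clonal expansion of its founders (deme frequency = founder allele
#' dosage / 2k), and returns the multi-locus Weir-Cockerham ratio-of-averages
#' FST among the newly founded demes. Under the propagule model with a single
#' diploid founder the expectation is 0.5 (among-deme variance `pq/2` over
#' total `pq`); with `k` founders it is `1/(2k)`.
#'
#' @param config A [metapop_config()]; supplies `n_loci`, the Beta source
#'   distribution, and `deme_size`.
#' @param n_founded Number of demes to found (>= 2).
#' @param k_founders Diploid founders per deme.
#' @param source_freq Optional vector of source allele frequencies (length
#'   `n_loci`); `NULL` draws them from the configured Beta.
#' @return Mean multi-locus FST (a single number).
#' @examples
#' cfg <- metapop_config(n_loci = 500, seed = 1)
#' founder_fst_experiment(cfg, n_founded = 100)
#' @export
founder_fst_experiment <- function(config, n_founded, k_founders = 1,
                                   source_freq = NULL) {
  stopifnot(inherits(config, "metapop_config"))
  if (n_founded < 2) abort("`n_founded` must be >= 2.")
  if (!is.null(config$seed)) set.seed(config$seed)
  p <- if (is.null(source_freq))
         rbeta(config$n_loci, config$source_freq_alpha, config$source_freq_beta)
       else source_freq
  freq <- t(vapply(seq_len(n_founded), function(i) {
    rbinom(length(p), 2L * as.integer(k_founders), p) /
      (2 * k_founders)
  }, numeric(length(p))))
  n_alleles <- matrix(2 * min(config$deme_size, 1e6), nrow = n_founded,
                      ncol = length(p))
  wc_fst_freq(freq, n_alleles)
}
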