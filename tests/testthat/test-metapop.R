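test_that("with no turnover, migration, or drift the state is frozen", {
  cfg <- metapop_config(n_patches = 30, n_loci = 20, extinction_rate = 0,
                        colonization_rate = 0, migration_rate = 0,
                        deme_size = Inf, init_occupancy = 0.5, seed = 1)
  st <- metapop_init(cfg)
  f0 <- st$freq
  a0 <- st$patches$age
  st2 <- step_year(step_year(st, cfg), cfg)
  expect_equal(st2$freq, f0)
  expect_equal(st2$patches$age[st2$patches$occupied],
               a0[st$patches$occupied] + 2)
})

test_that("without colonization occupancy decays to zero", {
  cfg <- metapop_config(n_patches = 40, n_loci = 5, extinction_rate = 0.5,
                        colonization_rate = 0, migration_rate = 0, seed = 2,
                        init_occupancy = 0.5)
  st <- metapop_init(cfg)
  occ <- sum(st$patches$occupied)
  for (y in 1:40) {
    st <- step_year(st, cfg)
    occ_new <- sum(st$patches$occupied)
    expect_lte(occ_new, occ)
    occ <- occ_new
  }
  expect_equal(occ, 0)
})

test_that("default turnover rates keep the system at a positive quasi-equilibrium", {
  # Levins-type persistence: extinction 0.20 / colonization 0.05 sustains
  # occupancy near c/(c+e) = 0.2 of patches
  set.seed(3)
  persisted <- 0
  final_occ <- numeric(50)
  for (r in 1:50) {
    cfg <- metapop_config(n_patches = 300, n_loci = 2, migration_rate = 0)
    st <- metapop_init(cfg)
    for (y in 1:100) st <- step_year(st, cfg)
    final_occ[r] <- mean(st$patches$occupied)
    if (any(st$patches$occupied)) persisted <- persisted + 1
  }
  expect_gte(persisted / 50, 0.9)
  expect_gt(mean(final_occ), 0.1)
  expect_lt(mean(final_occ), 0.3)
})

test_that("colonization falls back to the Beta source when all patches are empty", {
  cfg <- metapop_config(n_patches = 200, n_loci = 10, init_occupancy = 0,
                        colonization_rate = 0.1, seed = 4)
  st <- metapop_init(cfg)
  expect_equal(sum(st$patches$occupied), 0L)
  st <- step_year(st, cfg)
  occ <- which(st$patches$occupied)
  expect_gt(length(occ), 0)
  expect_false(anyNA(st$freq[occ, ]))
  expect_true(all(st$patches$age[occ] == 0))
})

test_that("single-founder demes carry half the source heterozygosity", {
  cfg <- metapop_config(n_patches = 400, n_loci = 400, init_occupancy = 1,
                        seed = 5)
  st <- metapop_init(cfg)
  hs <- 2 * st$source_p * (1 - st$source_p)
  hd <- 2 * st$freq * (1 - st$freq)
  expect_equal(mean(colMeans(hd)) / mean(hs), 0.5, tolerance = 0.03)
})

test_that("founder FST matches the propagule-model expectations", {
  p_half <- rep(0.5, 1000)
  f1 <- founder_fst_experiment(metapop_config(n_loci = 1000, seed = 10),
                               n_founded = 300, source_freq = p_half)
  expect_equal(as.numeric(f1), 0.5, tolerance = 0.02)
  f2 <- founder_fst_experiment(metapop_config(n_loci = 1000, seed = 11),
                               n_founded = 300, k_founders = 2,
                               source_freq = p_half)
  expect_equal(as.numeric(f2), 0.25, tolerance = 0.02)
  # founders = (almost) the whole source population: no bottleneck
  f_all <- founder_fst_experiment(metapop_config(n_loci = 500, seed = 12),
                                  n_founded = 100, k_founders = 500,
                                  source_freq = rep(0.5, 500))
  expect_lt(as.numeric(f_all), 0.01)
  expect_error(founder_fst_experiment(metapop_config(), n_founded = 1),
               ">= 2")
})

test_that("founder FST decreases in founder number as pq/(2k) predicts", {
  fs <- vapply(c(1, 2, 4, 8), function(k) {
    as.numeric(founder_fst_experiment(
      metapop_config(n_loci = 800, seed = 20 + k),
      n_founded = 250, k_founders = k))
  }, numeric(1))
  expect_true(all(diff(fs) < 0))
  expect_equal(fs, 1 / (2 * c(1, 2, 4, 8)), tolerance = 0.08)
})

test_that("a closed, drift-free, deterministic system only mixes frequencies convexly", {
  cfg <- metapop_config(n_patches = 20, n_loci = 30, extinction_rate = 0,
                        colonization_rate = 0, migration_rate = 5,
                        init_occupancy = 1, drift = FALSE,
                        stochastic_migrants = FALSE, seed = 6)
  st <- metapop_init(cfg)
  lo <- apply(st$freq, 2, min)
  hi <- apply(st$freq, 2, max)
  for (y in 1:15) st <- step_year(st, cfg)
  expect_true(all(st$freq >= rep(lo, each = 20) - 1e-12))
  expect_true(all(st$freq <= rep(hi, each = 20) + 1e-12))
})

test_that("identical seeds emit identical tables", {
  cfg <- metapop_config(n_patches = 50, n_loci = 30, years = 5, seed = 7)
  e1 <- emit_poolseq(simulate_metapop(cfg), seed = 8)
  e2 <- emit_poolseq(simulate_metapop(cfg), seed = 8)
  expect_identical(e1$variants, e2$variants)
  expect_identical(e1$covariates, e2$covariates)
})

test_that("young demes are more differentiated than old demes", {
  cfg <- metapop_config(seed = 9)
  st <- simulate_metapop(cfg)
  occ <- which(st$patches$occupied)
  age <- st$patches$age[occ]
  young <- occ[age <= 2]
  old <- occ[age > 5]
  expect_gte(length(young), 5)
  expect_gte(length(old), 5)
  pair_mean_fst <- function(idx) {
    vals <- c()
    for (i in seq_along(idx)) for (j in seq_len(i - 1)) {
      vals <- c(vals, as.numeric(driftmeta:::wc_fst_freq(
        st$freq[c(idx[i], idx[j]), ], 2 * cfg$deme_size)))
    }
    mean(vals)
  }
  expect_gt(pair_mean_fst(young), pair_mean_fst(old))
})

test_that("pool-seq read frequencies converge to pool frequencies at depth", {
  cfg <- metapop_config(n_patches = 40, n_loci = 200, years = 3, seed = 13)
  st <- simulate_metapop(cfg)
  occ <- which(st$patches$occupied)
  mad_at <- function(depth) {
    em <- emit_poolseq(st, poolseq_emission(pool_size = 10000,
                                            depth_mean = depth,
                                            error_rate = 0), seed = 14)
    v <- em$variants
    truth <- st$freq[occ, , drop = FALSE]
    rownames(truth) <- st$patches$patch[occ]
    got <- v$ad_alt / pmax(v$dp, 1)
    want <- truth[cbind(match(v$sample, rownames(truth)),
                        as.integer(v$pos / 100))]
    mean(abs(got - want)[v$dp > 0])
  }
  errs <- c(mad_at(20), mad_at(200), mad_at(2000))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.02)
})

test_that("a single-founder age-0 pond emits read frequencies near {0, 1/2, 1}", {
  cfg <- metapop_config(n_patches = 5, n_loci = 300, init_occupancy = 1,
                        seed = 15)
  st <- metapop_init(cfg) # all demes are age-0 single-founder clones
  em <- emit_poolseq(st, poolseq_emission(pool_size = 1, depth_mean = 500,
                                          error_rate = 0), seed = 16)
  v <- em$variants[em$variants$dp > 100, ]
  p <- v$ad_alt / v$dp
  d <- pmin(abs(p), abs(p - 0.5), abs(p - 1))
  expect_lt(max(d), 0.1)
})

test_that("emitting an empty or inconsistent state fails loudly", {
  cfg <- metapop_config(n_patches = 10, n_loci = 5, init_occupancy = 0,
                        seed = 17)
  st <- metapop_init(cfg)
  expect_error(emit_poolseq(st), "occupied")
  st$patches$occupied[1] <- TRUE
  expect_error(emit_poolseq(st), "consistency")
})
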