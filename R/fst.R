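# Weir-Cockerham method-of-moments FST from per-population allele
# frequencies with (effective) allele sample sizes; ratio of averages over
# loci. p: populations x loci matrix; n: matching matrix (or vector recycled
# per population) of allele counts. Loci need >= 2 populations with data.
wc_fst_freq <- function(p, n, return_components = FALSE) {
  p <- as.matrix(p)
  if (is.vector(n)) n <- matrix(n, nrow = nrow(p), ncol = ncol(p))
  n <- as.matrix(n)
  stopifnot(all(dim(p) == dim(n)))
  ok <- !is.na(p) & !is.na(n) & n > 1
  n[!ok] <- 0
  p[!ok] <- 0
  r <- colSums(ok)
  usable <- r >= 2
  if (!any(usable)) abort("No loci usable for FST.")
  nsum <- colSums(n)
  pbar <- colSums(n * p) / nsum
  msp <- colSums(n * (p - rep(pbar, each = nrow(p)))^2 * ok) / (r - 1)
  msg <- colSums(n * p * (1 - p)) / (nsum - r)
  nc <- (nsum - colSums(n^2) / nsum) / (r - 1)
  a_l <- ifelse(usable, (msp - msg) / nc, NA_real_)
  b_l <- ifelse(usable, msg, NA_real_)
  fst <- sum(a_l[usable]) / sum(a_l[usable] + b_l[usable])
  if (return_components) list(fst = fst, a = a_l, b = b_l,
                              n_loci = sum(usable))
  else structure(fst, n_loci = sum(usable))
}

# Double-binomial effective number of alleles for a pool: h haploid pool
# size, d read depth.
pool_n_eff <- function(h, d) {
  ifelse(d > 0, (h * d) / (h + d - 1), NA_real_)
}

#' Pairwise pool-seq FST between two samples
#'
#' Ratio-of-averages Weir-Cockerham estimator from read counts. Per site the
#' among/within variance components are computed from read frequencies with
#' effective sample size `n_eff = h * D / (h + D - 1)` per pool (`h` = haploid
#' pool size, `D` = allelic depth) — a double-binomial correction for
#' sampling individuals into the pool and reads from the pool. Negative
#' per-site components are kept; the ratio is reported as-is.
#'
#' @param ad_a,ad_b Tibbles/data frames with `ad_ref` and `ad_alt` for the
#'   same sites, one row per site (rows must be aligned).
#' @param pool_size_a,pool_size_b Individuals per pool.
#' @return FST (numeric scalar) with attribute `n_sites`.
#' @export
pairwise_fst <- function(ad_a, ad_b, pool_size_a, pool_size_b) {
  da <- ad_a$ad_ref + ad_a$ad_alt
  db <- ad_b$ad_ref + ad_b$ad_alt
  ok <- !is.na(da) & !is.na(db) & da > 0 & db > 0
  if (!any(ok)) abort("No shared usable sites between the two samples.")
  pa <- ad_a$ad_alt[ok] / da[ok]
  pb <- ad_b$ad_alt[ok] / db[ok]
  na <- pool_n_eff(2 * pool_size_a, da[ok])
  nb <- pool_n_eff(2 * pool_size_b, db[ok])
  fst <- wc_fst_freq(rbind(pa, pb), rbind(na, nb))
  structure(as.numeric(fst), n_sites = sum(ok))
}

#' All-pairs FST matrix from a long variant table
#'
#' Computes [pairwise_fst()] for every sample pair on the intersection of
#' sites that are unmasked (non-missing) in both samples.
#'
#' @param variants Filtered long variant tibble.
#' @param pools Tibble with `sample` and `pool_size`.
#' @return An object of class `fst_matrix`: list with `fst` (symmetric
#'   matrix, zero diagonal), `n_sites` (per-pair shared site counts), and
#'   `samples`.
#' @export
fst_matrix <- function(variants, pools) {
  samples <- sort(unique(variants$sample))
  if (length(samples) < 2) abort("Need >= 2 samples for an FST matrix.")
  psize <- setNames(pools$pool_size, pools$sample)
  if (!all(samples %in% names(psize)))
    abort("`pools` must list every sample in the table.")
  v <- dplyr::filter(variants, !.data$masked)
  key <- paste(v$chrom, v$pos)
  sites <- unique(key)
  row_i <- match(key, sites)
  col_i <- match(v$sample, samples)
  ar <- aa <- matrix(NA_real_, length(sites), length(samples))
  ar[cbind(row_i, col_i)] <- v$ad_ref
  aa[cbind(row_i, col_i)] <- v$ad_alt
  m <- matrix(0, length(samples), length(samples),
              dimnames = list(samples, samples))
  ns <- matrix(NA_integer_, length(samples), length(samples),
               dimnames = list(samples, samples))
  diag(ns) <- 0L
  for (i in seq_along(samples)) {
    for (j in seq_len(i - 1)) {
      shared <- which(!is.na(ar[, i]) & !is.na(ar[, j]))
      res <- tryCatch(
        pairwise_fst(
          tibble::tibble(ad_ref = ar[shared, i], ad_alt = aa[shared, i]),
          tibble::tibble(ad_ref = ar[shared, j], ad_alt = aa[shared, j]),
          psize[[samples[i]]], psize[[samples[j]]]),
        error = function(e) {
          warn(paste0("FST failed for ", samples[i], " vs ", samples[j],
                      ": ", conditionMessage(e)))
          structure(NA_real_, n_sites = 0L)
        })
      m[i, j] <- m[j, i] <- as.numeric(res)
      ns[i, j] <- ns[j, i] <- attr(res, "n_sites")
    }
  }
  structure(list(fst = m, n_sites = ns, samples = samples),
            class = "fst_matrix")
}

#' @export
print.fst_matrix <- function(x, ...) {
  off <- x$fst[lower.tri(x$fst)]
  cat("<fst_matrix>", length(x$samples), "samples; mean pairwise FST",
      format(mean(off, na.rm = TRUE), digits = 3), "\n")
  invisible(x)
}

#' Population-specific differentiation score
#'
#' The per-sample mean of its pairwise FST values — a moment-based proxy for
#' deme-specific differentiation (in place of a full Bayesian F-model fit).
#'
#' @param fst An `fst_matrix` (from [fst_matrix()]) or a square symmetric
#'   matrix.
#' @return A tibble with `sample` and `fst_specific`.
#' @export
population_specific_fst <- function(fst) {
  m <- if (inherits(fst, "fst_matrix")) fst$fst else as.matrix(fst)
  if (nrow(m) < 3) abort("Need >= 3 samples for population-specific FST.")
  diag(m) <- NA
  tibble::tibble(sample = rownames(m),
                 fst_specific = unname(rowMeans(m, na.rm = TRUE)))
}

#' Mantel test of isolation by distance
#'
#' Pearson correlation between pairwise FST and log10 geographic distance,
#' with significance from random row/column permutations of one matrix
#' (via `vegan::mantel`).
#'
#' @param fst An `fst_matrix` or square symmetric matrix.
#' @param dist_m Square matrix of pairwise distances in meters (e.g.,
#'   [pond_distances()]), aligned to the FST matrix.
#' @param n_perm Number of permutations (>= 99).
#' @param log10_dist Log10-transform the distances first (default TRUE).
#' @param seed Optional integer seed for the permutations.
#' @return A tibble with `statistic` (Mantel r), `p_value`, `n_perm`.
#' @export
mantel_ibd <- function(fst, dist_m, n_perm = 999, log10_dist = TRUE,
                       seed = NULL) {
  m <- if (inherits(fst, "fst_matrix")) fst$fst else as.matrix(fst)
  dist_m <- as.matrix(dist_m)
  if (!all(dim(m) == dim(dist_m)))
    abort("FST and distance matrices must have matching dimensions.")
  if (n_perm < 99) abort("`n_perm` must be >= 99.")
  off <- m[lower.tri(m)]
  if (sd(off, na.rm = TRUE) == 0 || all(is.na(off)))
    abort("Constant FST matrix: correlation undefined.")
  d <- dist_m
  if (log10_dist) {
    if (any(d[lower.tri(d)] <= 0))
      abort("Zero or negative pairwise distance: cannot log10-transform.")
    d <- log10(d)
    diag(d) <- 0
  }
  if (!is.null(seed)) set.seed(seed)
  res <- vegan::mantel(stats::as.dist(m), stats::as.dist(d),
                       method = "pearson", permutations = n_perm)
  tibble::tibble(statistic = unname(res$statistic),
                 p_value = res$signif, n_perm = n_perm)
}
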