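#' Polarize a sample's variants against an outgroup
#'
#' Counts, per sample, the synonymous and nonsynonymous polymorphisms (`P_s`,
#' `P_n`) and fixed differences from the outgroup (`D_s`, `D_n`). A site is
#' polymorphic when both alleles have read support after masking; it is a
#' substitution only when the sample is monomorphic *and* its allele differs
#' from the outgroup base — a site never contributes to both P and D. Sites
#' whose outgroup base is missing are excluded and tallied. Only coding
#' classes are counted (nonsense variants count as nonsynonymous).
#'
#' @param variants Filtered long variant tibble with a `class` column (see
#'   [classify_variants()]).
#' @param outgroup Tibble with `chrom`, `pos`, `outgroup_base` giving the
#'   aligned outgroup allele per site. Sites polymorphic in the outgroup are
#'   expected to carry their reference base.
#' @param site_table Per-gene site totals ([cds_site_totals()]) or a one-row
#'   tibble with `s_syn`, `s_nonsyn`.
#' @param mono_threshold Optional major-allele frequency at or above which a
#'   sample is treated as monomorphic (e.g., 0.95). Default `NULL`: strictly
#'   monomorphic after masking.
#' @return A tibble with one row per sample: `sample`, `P_n`, `P_s`, `D_n`,
#'   `D_s`, `s_syn`, `s_nonsyn`, `n_no_outgroup`.
#' @export
polarize <- function(variants, outgroup, site_table, mono_threshold = NULL) {
  if (!"class" %in% names(variants))
    abort("`variants` needs a `class` column; run classify_variants() first.")
  tot <- if (all(c("s_syn", "s_nonsyn") %in% names(site_table)) &&
             nrow(site_table) > 1) site_totals(site_table) else site_table
  v <- variants |>
    dplyr::filter(.data$class %in%
                    c("synonymous", "nonsynonymous", "nonsense")) |>
    dplyr::mutate(cls = ifelse(.data$class == "synonymous", "syn", "nonsyn")) |>
    dplyr::left_join(outgroup, by = c("chrom", "pos"))
  v |>
    dplyr::group_by(.data$sample) |>
    dplyr::group_modify(function(d, key) {
      d <- d[!d$masked & d$dp > 0, , drop = FALSE]
      p_alt <- ifelse(d$dp > 0, d$ad_alt / d$dp, NA_real_)
      if (is.null(mono_threshold)) {
        poly <- d$ad_ref > 0 & d$ad_alt > 0
      } else {
        poly <- pmax(p_alt, 1 - p_alt) < mono_threshold
      }
      mono_allele <- ifelse(p_alt >= 0.5, d$alt, d$ref)
      no_out <- is.na(d$outgroup_base)
      sub <- !poly & !no_out & mono_allele != d$outgroup_base
      countable_excluded <- no_out & !poly
      tibble::tibble(
        P_n = sum(poly & d$cls == "nonsyn"),
        P_s = sum(poly & d$cls == "syn"),
        D_n = sum(sub & d$cls == "nonsyn"),
        D_s = sum(sub & d$cls == "syn"),
        s_syn = tot$s_syn[1],
        s_nonsyn = tot$s_nonsyn[1],
        n_no_outgroup = sum(countable_excluded)
      )
    }) |>
    dplyr::ungroup()
}

#' McDonald-Kreitman estimate of the adaptive substitution fraction
#'
#' `alpha = 1 - (D_s * P_n) / (D_n * P_s)`. May be negative (an excess of
#' segregating weakly deleterious nonsynonymous variants). Undefined when
#' `D_n` or `P_s` is zero; such inputs give `NA` with a warning rather than
#' silent `NaN`.
#'
#' @param counts A tibble with columns `P_n`, `P_s`, `D_n`, `D_s` (one or
#'   more rows), as from [polarize()].
#' @return Numeric vector of alpha values, one per row.
#' @examples
#' mk_alpha(tibble::tibble(P_n = 10, P_s = 10, D_n = 5, D_s = 10)) # -1
#' @export
mk_alpha <- function(counts) {
  bad <- counts$D_n == 0 | counts$P_s == 0
  if (any(bad))
    warn(paste0(sum(bad), " sample(s) with D_n = 0 or P_s = 0: ",
                "alpha undefined (NA)."))
  ifelse(bad, NA_real_,
         1 - (counts$D_s * counts$P_n) / (counts$D_n * counts$P_s))
}

#' Substitutions per site
#'
#' `d_N = D_n / S_nonsyn`, `d_S = D_s / S_syn`.
#'
#' @param counts A tibble with `D_n`, `D_s`, `s_syn`, `s_nonsyn`.
#' @return A tibble with `d_n` and `d_s`, one row per input row.
#' @export
substitution_rates <- function(counts) {
  if (any(counts$s_syn <= 0 | counts$s_nonsyn <= 0))
    abort("Site totals must be positive to compute substitution rates.")
  tibble::tibble(d_n = counts$D_n / counts$s_nonsyn,
                 d_s = counts$D_s / counts$s_syn)
}

#' Rates of adaptive and nonadaptive nonsynonymous substitution
#'
#' `omega_A = alpha * (d_N / d_S)` and `omega_NA = (1 - alpha) * (d_N / d_S)`,
#' so `omega_A + omega_NA = d_N / d_S` exactly. Undefined (NA, warned) when
#' `d_S` is zero or `alpha` is NA.
#'
#' @param alpha Alpha values (from [mk_alpha()]).
#' @param d_n,d_s Substitution rates per site (from [substitution_rates()]).
#' @return A tibble with `omega_a` and `omega_na`.
#' @export
omega_rates <- function(alpha, d_n, d_s) {
  bad <- is.na(alpha) | is.na(d_s) | d_s == 0
  if (any(bad))
    warn(paste0(sum(bad), " input(s) with d_S = 0 or undefined alpha: ",
                "omega undefined (NA)."))
  ratio <- ifelse(bad, NA_real_, d_n / d_s)
  tibble::tibble(omega_a = alpha * ratio, omega_na = (1 - alpha) * ratio)
}

#' Per-sample divergence summary statistics
#'
#' Convenience wrapper: [polarize()], then [mk_alpha()],
#' [substitution_rates()] and [omega_rates()] per sample.
#'
#' @inheritParams polarize
#' @return A tibble with one row per sample holding `P_n`, `P_s`, `D_n`,
#'   `D_s`, `d_n`, `d_s`, `alpha`, `omega_a`, `omega_na`.
#' @export
divergence_stats <- function(variants, outgroup, site_table,
                             mono_threshold = NULL) {
  counts <- polarize(variants, outgroup, site_table, mono_threshold)
  rates <- substitution_rates(counts)
  alpha <- suppressWarnings(mk_alpha(counts))
  om <- suppressWarnings(omega_rates(alpha, rates$d_n, rates$d_s))
  dplyr::bind_cols(counts, rates, tibble::tibble(alpha = alpha), om)
}

#' Read an outgroup allele table
#'
#' A TSV with columns `chrom`, `pos`, `outgroup_base` (1-based positions on
#' the same coordinates as the VCF).
#'
#' @param path Path to the TSV file.
#' @return A tibble.
#' @export
read_outgroup_table <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "outgroup_base")
  if (!all(need %in% names(out)))
    abort("Outgroup table needs columns chrom, pos, outgroup_base.")
  tibble::as_tibble(out)
}
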