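#' Filter a variant table by the study's site and genotype rules
#'
#' Record-level filters keep sites with `QUAL > 30`, `MQ > 40`, `QD > 2.0`,
#' `FS < 60`, and exactly two alleles, both single nucleotides (strict
#' inequalities; a missing INFO field fails its criterion). Per-sample
#' genotype masks: depth `DP < 10`, or minor-allele read depth exactly 1
#' (a depth-aware guard against sequencing errors, more conservative than a
#' minor-allele-frequency cutoff).
#'
#' Removed records are attributed to the first failing rule in the order
#' qual, mq, qd, fs, biallelic-SNV; the per-rule counts therefore sum to the
#' total number of removed records.
#'
#' @param variants Long variant tibble (see [read_variant_vcf()]).
#' @param min_dp Genotype depth threshold (masked if `DP < min_dp`).
#' @return The filtered tibble (failing records dropped, masks set), with a
#'   `filter_report` attribute; retrieve it with [filter_report()].
#' @export
filter_variants <- function(variants, min_dp = 10) {
  v <- variants
  snv <- grepl("^[ACGT]$", v$ref) & grepl("^[ACGT]$", v$alt)
  if ("n_alt" %in% names(v)) snv <- snv & v$n_alt == 1L
  pass_qual <- !is.na(v$qual) & v$qual > 30
  pass_mq <- !is.na(v$mq) & v$mq > 40
  pass_qd <- !is.na(v$qd) & v$qd > 2.0
  pass_fs <- !is.na(v$fs) & v$fs < 60
  first_fail <- dplyr::case_when(
    !pass_qual ~ "qual",
    !pass_mq ~ "mq",
    !pass_qd ~ "qd",
    !pass_fs ~ "fs",
    !snv ~ "biallelic_snv",
    TRUE ~ NA_character_
  )
  keep <- is.na(first_fail)

  # count per unique site, not per sample-row
  site_key <- paste(v$chrom, v$pos)
  site_fail <- tapply(first_fail, site_key, function(x) x[1])
  removed <- table(factor(site_fail[!is.na(site_fail)],
                          levels = c("qual", "mq", "qd", "fs",
                                     "biallelic_snv")))

  out <- v[keep, , drop = FALSE]
  masked0 <- out$masked | is.na(out$dp)
  mask_dp <- !masked0 & out$dp < min_dp
  minor_ad <- pmin(out$ad_ref, out$ad_alt)
  mask_minor <- !masked0 & !mask_dp & !is.na(minor_ad) & minor_ad == 1
  out$masked <- masked0 | mask_dp | mask_minor

  report <- tibble::tibble(
    rule = c(names(removed), "genotype_dp", "genotype_minor_ad"),
    n_removed = c(as.integer(removed), sum(mask_dp), sum(mask_minor)),
    unit = c(rep("site", length(removed)), "genotype", "genotype")
  )
  attr(out, "filter_report") <- report
  out
}

#' Retrieve the filtering report of a filtered variant table
#'
#' @param variants A table returned by [filter_variants()].
#' @return A tibble of per-rule removal counts.
#' @export
filter_report <- function(variants) {
  rep <- attr(variants, "filter_report")
  if (is.null(rep)) abort("No filter report: was this table filtered?")
  rep
}

#' Per-site diversity from pooled allele depths
#'
#' Estimates expected heterozygosity from read counts with the
#' read-sampling correction `(D / (D - 1)) * 2 * p * (1 - p)`, where
#' `p = AD_alt / D` and `D` is the total allelic depth. Sites with `D < 2`
#' are undefined (`NA`).
#'
#' @param ad_ref,ad_alt Reference and alternate read counts (vectors).
#' @return Numeric vector of per-site diversity values.
#' @examples
#' site_pi(5, 5) # (10/9) * 0.5
#' @export
site_pi <- function(ad_ref, ad_alt) {
  d <- ad_ref + ad_alt
  p <- ifelse(d > 0, ad_alt / d, NA_real_)
  ifelse(!is.na(d) & d >= 2, (d / (d - 1)) * 2 * p * (1 - p), NA_real_)
}

#' Region-level diversity statistics per pool sample
#'
#' Sums [site_pi()] over the variant sites of each sample and divides by the
#' assayed site totals. Monomorphic sites contribute zero to the numerators
#' but stay in the denominators; variant sites that are masked or have depth
#' below 2 are skipped and subtracted from the denominators of their class
#' (assayed-site bookkeeping). When the table carries a `class` column and
#' site totals are supplied, class-wise `pi_n` and `pi_s` are reported too
#' (nonsense variants count as nonsynonymous).
#'
#' @param variants Filtered long variant tibble.
#' @param s_syn,s_nonsyn Synonymous/nonsynonymous site totals of the region
#'   (e.g., from [cds_site_totals()] + [site_totals()]); optional.
#' @param total_sites Total assayed sites for overall `pi`; defaults to
#'   `s_syn + s_nonsyn` when those are given.
#' @return A tibble with one row per sample: `sample`, `pi`, `pi_n`, `pi_s`,
#'   `pi_ratio` (`pi_n / pi_s`, `NA` with `pi_ratio_defined = FALSE` when
#'   `pi_s` is 0), `n_variant_sites`, `n_skipped`.
#' @export
region_pi <- function(variants, s_syn = NULL, s_nonsyn = NULL,
                      total_sites = NULL) {
  if (is.null(total_sites)) {
    if (is.null(s_syn) || is.null(s_nonsyn))
      abort("Supply `total_sites`, or both `s_syn` and `s_nonsyn`.")
    total_sites <- s_syn + s_nonsyn
  }
  if (total_sites <= 0) abort("Empty region: no assayed sites.")
  has_class <- "class" %in% names(variants) &&
    !is.null(s_syn) && !is.null(s_nonsyn)
  v <- dplyr::mutate(variants,
                     pi_site = site_pi(.data$ad_ref, .data$ad_alt),
                     usable = !.data$masked & !is.na(.data$pi_site))
  if (has_class) {
    v <- dplyr::mutate(v, cls = dplyr::case_when(
      .data$class %in% c("nonsynonymous", "nonsense") ~ "nonsyn",
      .data$class == "synonymous" ~ "syn",
      TRUE ~ "other"
    ))
  }
  v |>
    dplyr::group_by(.data$sample) |>
    dplyr::group_modify(function(d, key) {
      skipped <- !d$usable
      pi_all <- sum(d$pi_site[d$usable]) /
        max(total_sites - sum(skipped), 1)
      if (has_class) {
        skip_n <- sum(skipped & d$cls == "nonsyn")
        skip_s <- sum(skipped & d$cls == "syn")
        pi_n <- sum(d$pi_site[d$usable & d$cls == "nonsyn"]) /
          max(s_nonsyn - skip_n, 1)
        pi_s <- sum(d$pi_site[d$usable & d$cls == "syn"]) /
          max(s_syn - skip_s, 1)
      } else {
        pi_n <- NA_real_
        pi_s <- NA_real_
      }
      tibble::tibble(
        pi = pi_all, pi_n = pi_n, pi_s = pi_s,
        pi_ratio = ifelse(!is.na(pi_s) & pi_s > 0, pi_n / pi_s, NA_real_),
        pi_ratio_defined = !is.na(pi_s) && pi_s > 0,
        n_variant_sites = sum(d$usable),
        n_skipped = sum(skipped)
      )
    }) |>
    dplyr::ungroup()
}
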