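#' Pool-seq emission model
#'
#' How read-count data are generated from a pond's true allele frequencies:
#' `pool_size` individuals are sampled per pond (allele count
#' `Binomial(2 * pool_size, p)`), per-site read depth is negative-binomial
#' with mean `depth_mean` and dispersion (size) `depth_dispersion`, alternate
#' read counts are `Binomial(depth, pool frequency)`, and each read is
#' miscalled to the other allele with probability `error_rate`.
#'
#' @param pool_size Individuals sampled per pond (default 50).
#' @param depth_mean Mean reads per site (default 30).
#' @param depth_dispersion Negative-binomial size parameter (default 10;
#'   larger is closer to Poisson).
#' @param error_rate Per-read miscall probability (default 0.002).
#' @return An object of class `poolseq_emission`.
#' @export
poolseq_emission <- function(pool_size = 50, depth_mean = 30,
                             depth_dispersion = 10, error_rate = 0.002) {
  if (pool_size < 1) abort("`pool_size` must be >= 1.")
  if (depth_mean <= 0) abort("`depth_mean` must be > 0.")
  if (error_rate < 0 || error_rate > 1)
    abort("`error_rate` must lie in [0, 1].")
  structure(list(pool_size = as.integer(pool_size), depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion,
                 error_rate = error_rate),
            class = "poolseq_emission")
}

#' Emit synthetic pool-seq variant and covariate tables
#'
#' Samples pool-seq read counts for every occupied patch and locus of a
#' metapopulation state and returns a VCF-convention variant table, a pond
#' covariate table, and the generating truth. Only age and isolation carry
#' built-in effects on the genetic data (through founding bottlenecks and
#' distance-decaying gene flow); depth, surface area, and infection status
#' are generated as pure noise covariates.
#'
#' @param state A `metapop_state` with at least one occupied patch.
#' @param emission A [poolseq_emission()].
#' @param seed Optional integer seed.
#' @return A list with elements `variants` (long tibble: `chrom`, `pos`,
#'   `ref`, `alt`, `qual`, `mq`, `qd`, `fs`, `sample`, `ad_ref`, `ad_alt`,
#'   `dp`, `masked`), `covariates` (tibble: `pond`, `lat`, `lon`, `age`,
#'   `depth_m`, `surface_m2`, `infection`), `pools` (tibble: `sample`,
#'   `pool_size`), and `truth` (true frequencies, ages, founder counts).
#' @examples
#' cfg <- metapop_config(n_patches = 30, n_loci = 20, years = 5, seed = 1)
#' sim <- simulate_metapop(cfg)
#' emitted <- emit_poolseq(sim, poolseq_emission(depth_mean = 20), seed = 2)
#' head(emitted$variants)
#' @export
emit_poolseq <- function(state, emission = poolseq_emission(), seed = NULL) {
  stopifnot(inherits(state, "metapop_state"),
            inherits(emission, "poolseq_emission"))
  occ <- which(state$patches$occupied)
  if (length(occ) == 0) abort("No occupied patches to emit.")
  if (anyNA(state$freq[occ, ]))
    abort("Internal consistency error: occupied patch with undefined frequencies.")
  if (!is.null(seed)) set.seed(seed)

  n_loci <- ncol(state$freq)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_loci, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
  pos <- seq_len(n_loci) * 100L

  ponds <- state$patches$patch[occ]
  rows <- purrr::map_dfr(seq_along(occ), function(j) {
    i <- occ[j]
    p <- state$freq[i, ]
    pool_ct <- rbinom(n_loci, 2L * emission$pool_size, p)
    pool_p <- pool_ct / (2 * emission$pool_size)
    dp <- rnbinom(n_loci, size = emission$depth_dispersion,
                  mu = emission$depth_mean)
    ad_alt <- rbinom(n_loci, dp, pool_p)
    if (emission$error_rate > 0) {
      ad_alt <- ad_alt - rbinom(n_loci, ad_alt, emission$error_rate) +
        rbinom(n_loci, dp - ad_alt, emission$error_rate)
    }
    tibble::tibble(
      chrom = "chr1", pos = pos, ref = ref, alt = alt,
      qual = 500, mq = 60, qd = 25, fs = 1,
      sample = ponds[j], ad_ref = dp - ad_alt, ad_alt = ad_alt, dp = dp,
      masked = FALSE
    )
  })

  covariates <- tibble::tibble(
    pond = ponds,
    lat = state$patches$lat[occ],
    lon = state$patches$lon[occ],
    age = state$patches$age[occ],
    depth_m = exp(rnorm(length(occ), log(0.3), 0.4)),
    surface_m2 = exp(rnorm(length(occ), log(6), 0.7)),
    infection = runif(length(occ)) < 0.5
  )

  list(
    variants = rows,
    covariates = covariates,
    pools = tibble::tibble(sample = ponds,
                           pool_size = emission$pool_size),
    truth = list(freq = state$freq[occ, , drop = FALSE],
                 age = state$patches$age[occ],
                 founders_k = state$patches$founders_k[occ],
                 pond = ponds)
  )
}

#' Write a long variant table as a VCF 4.2 file
#'
#' One record per site, FORMAT `AD:DP`, INFO fields `MQ`, `QD`, `FS`.
#'
#' @param variants Long variant tibble as produced by [emit_poolseq()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(variants, path) {
  sites <- dplyr::distinct(variants, .data$chrom, .data$pos, .data$ref,
                           .data$alt, .data$qual, .data$mq, .data$qd,
                           .data$fs)
  sites <- dplyr::arrange(sites, .data$chrom, .data$pos)
  samples <- sort(unique(variants$sample))
  wide <- variants |>
    dplyr::mutate(field = sprintf("%d,%d:%d", .data$ad_ref, .data$ad_alt,
                                  .data$dp)) |>
    dplyr::select("chrom", "pos", "sample", "field") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "field",
                       values_fill = ".:.")
  wide <- dplyr::left_join(sites, wide, by = c("chrom", "pos"))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=driftmeta",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand bias\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- apply(wide, 1, function(r) {
    paste(c(r[["chrom"]], r[["pos"]], ".", r[["ref"]], r[["alt"]],
            r[["qual"]], ".",
            sprintf("MQ=%s;QD=%s;FS=%s", r[["mq"]], r[["qd"]], r[["fs"]]),
            "AD:DP", unlist(r[samples])), collapse = "\t")
  })
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF with per-sample AD/DP into a long variant tibble
#'
#' Parses a VCF 4.2 file (via \pkg{vcfR}) into the long per-sample table the
#' diversity and differentiation estimators consume. `DP` is recomputed as
#' the sum of the allelic depths, since upstream callers may include
#' uninformative reads in `DP` that are absent from `AD`.
#'
#' @param path Path to a VCF file.
#' @return A long tibble with columns `chrom`, `pos`, `ref`, `alt`, `qual`,
#'   `mq`, `qd`, `fs`, `sample`, `ad_ref`, `ad_alt`, `dp`, `masked`.
#' @export
read_variant_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcf@fix, stringsAsFactors = FALSE))
  info_num <- function(field) {
    x <- vcfR::extract.info(vcf, element = field, as.numeric = TRUE)
    if (is.null(x)) rep(NA_real_, nrow(fix)) else x
  }
  ad <- vcfR::extract.gt(vcf, element = "AD")
  n_site <- nrow(ad)
  samples <- colnames(ad)
  site_tbl <- tibble::tibble(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    mq = info_num("MQ"), qd = info_num("QD"), fs = info_num("FS"),
    n_alt = vapply(strsplit(fix$ALT, ","), length, integer(1))
  )
  purrr::map_dfr(samples, function(s) {
    parts <- strsplit(ad[, s], ",", fixed = TRUE)
    bad <- vapply(parts, function(p)
      !(length(p) %in% c(1L, 2L)) || anyNA(suppressWarnings(as.integer(p))),
      logical(1))
    bad[is.na(ad[, s]) | ad[, s] == "."] <- FALSE # missing, not malformed
    if (any(bad)) {
      where <- paste0(site_tbl$chrom[bad], ":", site_tbl$pos[bad],
                      collapse = ", ")
      abort(paste0("Malformed AD for sample ", s, " at ", where))
    }
    ad_ref <- unname(vapply(parts, function(p)
      suppressWarnings(as.integer(p[1])), integer(1)))
    ad_alt <- unname(vapply(parts, function(p)
      if (length(p) >= 2) suppressWarnings(as.integer(p[2])) else NA_integer_,
      integer(1)))
    dplyr::mutate(site_tbl,
                  sample = s, ad_ref = ad_ref, ad_alt = ad_alt,
                  dp = ad_ref + ad_alt,
                  masked = is.na(ad_ref) | is.na(ad_alt))
  }) |>
    dplyr::select("chrom", "pos", "ref", "alt", "qual", "mq", "qd", "fs",
                  "n_alt", "sample", "ad_ref", "ad_alt", "dp", "masked")
}
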