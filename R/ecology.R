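#' Pond volume from surface area and depth
#'
#' Pyramid approximation: `surface_area * depth / 3`.
#'
#' @param surface_area Surface area, m^2 (>= 0).
#' @param depth Depth, m (>= 0).
#' @return Volume in m^3.
#' @examples
#' pond_volume(3, 1) # 1 m^3
#' @export
pond_volume <- function(surface_area, depth) {
  if (any(surface_area < 0, na.rm = TRUE) || any(depth < 0, na.rm = TRUE))
    abort("`surface_area` and `depth` must be non-negative.")
  surface_area * depth / 3
}

#' Isolation as mean distance to the two nearest neighbors (NN2)
#'
#' For each focal pond, the mean of the two smallest haversine distances to
#' the other occupied ponds. Ties contribute both tied values, so the mean
#' is tie-order invariant. A pond is never its own neighbor.
#'
#' @param ponds Tibble with columns `pond`, `lat`, `lon` (occupied ponds).
#' @param focal Optional vector of pond ids to report; default all.
#' @return A tibble with `pond` and `nn2` (meters).
#' @examples
#' p <- tibble::tibble(pond = c("a", "b", "c"),
#'                     lat = c(59.82, 59.821, 59.823), lon = 23.25)
#' nn2_isolation(p)
#' @export
nn2_isolation <- function(ponds, focal = NULL) {
  if (is.null(focal)) focal <- ponds$pond
  d <- pond_distances(ponds$lat, ponds$lon)
  rownames(d) <- colnames(d) <- ponds$pond
  nn2 <- vapply(focal, function(f) {
    others <- setdiff(ponds$pond, f)
    if (length(others) < 2)
      abort(paste0("Pond ", f, " has fewer than 2 neighbors."))
    mean(sort(d[f, others])[1:2])
  }, numeric(1))
  tibble::tibble(pond = focal, nn2 = unname(nn2))
}

#' Subpopulation age from a presence/absence survey series
#'
#' A subpopulation counts as newly established when animals are observed
#' after at least three consecutive visits without them (or at the start of
#' the series). The most recent such founding event at or before
#' `reference_date` defines the age; ponds observed at every visit are
#' right-censored at the span of the survey.
#'
#' @param records Tibble with `pond`, `date` (Date or numeric years), and
#'   `detected` (logical), ordered or orderable by date.
#' @param reference_date The date ages are measured at.
#' @param miss_run Number of consecutive non-detections that defines an
#'   extinction gap (default 3).
#' @return A tibble with `pond`, `age` (years; `NA` if never detected,
#'   flagged by `age_defined`), and `newly_founded` (age <= 2).
#' @export
age_from_survey <- function(records, reference_date, miss_run = 3) {
  to_years <- function(x) {
    if (inherits(x, "Date")) as.numeric(x) / 365.25 else as.numeric(x)
  }
  ref <- to_years(reference_date)
  records |>
    dplyr::group_by(.data$pond) |>
    dplyr::group_modify(function(d, key) {
      d <- d[order(d$date), , drop = FALSE]
      t <- to_years(d$date)
      keep <- t <= ref
      det <- d$detected[keep]
      t <- t[keep]
      if (!any(det))
        return(tibble::tibble(age = NA_real_, age_defined = FALSE,
                              newly_founded = NA))
      founding <- NA_real_
      run <- Inf # series start counts as a gap
      for (i in seq_along(det)) {
        if (det[i]) {
          if (run >= miss_run) founding <- t[i]
          run <- 0
        } else {
          run <- run + 1
        }
      }
      if (is.na(founding)) founding <- t[which(det)[1]]
      age <- ref - founding
      tibble::tibble(age = age, age_defined = TRUE,
                     newly_founded = age <= 2)
    }) |>
    dplyr::ungroup()
}

#' Probability of missing an extant subpopulation over consecutive visits
#'
#' `(1 - p_detect)^n_visits`; with the survey's per-visit detection
#' probability of 0.74 and three visits this is 0.017576, below 2%.
#'
#' @param p_detect Per-visit detection probability.
#' @param n_visits Number of consecutive visits.
#' @return Probability of `n_visits` consecutive misses.
#' @export
detection_miss_probability <- function(p_detect = 0.74, n_visits = 3) {
  (1 - p_detect)^n_visits
}

#' PCA of ecological covariates
#'
#' Selected area/length columns are log10-transformed, all columns are then
#' standardized and principal components of the correlation matrix computed.
#' Constant columns are dropped with a warning. Each loading vector is
#' oriented so its largest-magnitude entry is positive.
#'
#' @param covariates Tibble of pond covariates.
#' @param log10_cols Character vector of columns to log10-transform first.
#' @param id_col Identifier column carried into the scores (default
#'   `"pond"`, ignored if absent).
#' @return An object of class `covariate_pca`: list with `scores` (tibble),
#'   `loadings` (matrix), `variance_fraction` (numeric, sums to 1).
#' @export
covariate_pca <- function(covariates, log10_cols = character(),
                          id_col = "pond") {
  ids <- if (id_col %in% names(covariates)) covariates[[id_col]] else NULL
  num <- dplyr::select(covariates, dplyr::where(is.numeric))
  if (id_col %in% names(num)) num <- dplyr::select(num, -dplyr::all_of(id_col))
  if (ncol(num) < 2) abort("Need >= 2 numeric covariates.")
  if (nrow(num) < 3) abort("Need >= 3 ponds.")
  for (cl in intersect(log10_cols, names(num))) num[[cl]] <- log10(num[[cl]])
  const <- vapply(num, function(x) sd(x, na.rm = TRUE) == 0, logical(1))
  if (any(const)) {
    warn(paste0("Dropping constant column(s): ",
                paste(names(num)[const], collapse = ", ")))
    num <- num[, !const, drop = FALSE]
  }
  fit <- prcomp(num, center = TRUE, scale. = TRUE)
  # sign convention: biggest loading positive
  for (k in seq_len(ncol(fit$rotation))) {
    big <- which.max(abs(fit$rotation[, k]))
    if (fit$rotation[big, k] < 0) {
      fit$rotation[, k] <- -fit$rotation[, k]
      fit$x[, k] <- -fit$x[, k]
    }
  }
  scores <- tibble::as_tibble(fit$x)
  if (!is.null(ids)) scores <- dplyr::bind_cols(tibble::tibble(!!id_col := ids),
                                                scores)
  structure(list(scores = scores, loadings = fit$rotation,
                 variance_fraction = fit$sdev^2 / sum(fit$sdev^2)),
            class = "covariate_pca")
}

#' @export
print.covariate_pca <- function(x, ...) {
  cat("<covariate_pca>", length(x$variance_fraction), "components;",
      "PC1", sprintf("%.1f%%", 100 * x$variance_fraction[1]),
      "PC2", sprintf("%.1f%%", 100 * x$variance_fraction[2]), "\n")
  invisible(x)
}

#' Multiple regression of diversity on ecological covariates
#'
#' Ordinary least squares with marginal (type-II) tests: each term is tested
#' after all others (partial sums of squares, via `car::Anova`). The default
#' predictor set mirrors the study design: log10(age + 1), the two covariate
#' PCs, NN2 isolation, and infection status.
#'
#' @param data Tibble with the response and predictor columns (complete
#'   cases are used).
#' @param response Name of the response column (e.g., `"pi"`).
#' @param predictors Character vector of predictor column names.
#' @return An object of class `diversity_assoc` with [tidy()] and
#'   [glance()] methods.
#' @export
diversity_regression <- function(data, response = "pi",
                                 predictors = c("log_age", "PC1", "PC2",
                                                "nn2", "infection")) {
  missing_cols <- setdiff(c(response, predictors), names(data))
  if (length(missing_cols) > 0)
    abort(paste0("Missing columns: ", paste(missing_cols, collapse = ", ")))
  d <- data[complete.cases(data[, c(response, predictors)]), , drop = FALSE]
  if (nrow(d) < length(predictors) + 2)
    abort("Too few complete cases for the requested model.")
  fml <- stats::reformulate(predictors, response = response)
  fit <- lm(fml, data = d)
  if (any(is.na(coef(fit)))) {
    aliased <- names(coef(fit))[is.na(coef(fit))]
    abort(paste0("Rank-deficient model; aliased terms: ",
                 paste(aliased, collapse = ", ")))
  }
  an <- car::Anova(fit, type = 2)
  structure(list(fit = fit, anova = an, response = response,
                 predictors = predictors, n = nrow(d)),
            class = "diversity_assoc")
}

#' @export
print.diversity_assoc <- function(x, ...) {
  cat("<diversity_assoc>", x$response, "~",
      paste(x$predictors, collapse = " + "), " (n =", x$n, ")\n")
  print(tidy(x))
  invisible(x)
}

#' @rdname diversity_regression
#' @param x A `diversity_assoc` object.
#' @param ... Unused.
#' @return `tidy()`: a tibble with one row per model term: `term`,
#'   `estimate`, `statistic_t` (signed, for 1-df terms), `statistic_F`,
#'   `df`, `p_value`.
#' @method tidy diversity_assoc
#' @export
tidy.diversity_assoc <- function(x, ...) {
  an <- as.data.frame(x$anova)
  terms <- rownames(an)
  keep <- terms != "Residuals"
  est <- coef(x$fit)
  # map each anova term to its coefficient (1-df continuous/binary terms)
  cm <- attr(x$fit$terms, "term.labels")
  assign_idx <- attr(stats::model.matrix(x$fit), "assign")
  coef_for <- vapply(seq_along(cm), function(i) {
    idx <- which(assign_idx == i)
    if (length(idx) == 1) est[idx] else NA_real_
  }, numeric(1))
  names(coef_for) <- cm
  f <- an[keep, "F value"]
  df1 <- an[keep, "Df"]
  estv <- coef_for[terms[keep]]
  tstat <- ifelse(df1 == 1, sign(estv) * sqrt(f), NA_real_)
  tibble::tibble(
    term = terms[keep],
    estimate = unname(estv),
    statistic_t = unname(tstat),
    statistic_F = unname(f),
    df = unname(df1),
    p_value = unname(an[keep, "Pr(>F)"])
  )
}

#' @rdname diversity_regression
#' @return `glance()`: a one-row tibble with `r_squared`,
#'   `adj_r_squared`, `sigma`, `n`.
#' @method glance diversity_assoc
#' @export
glance.diversity_assoc <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(r_squared = s$r.squared, adj_r_squared = s$adj.r.squared,
                 sigma = s$sigma, n = x$n)
}
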