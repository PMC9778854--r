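#' Tidy an FST matrix into long pair form
#'
#' @param x An `fst_matrix`.
#' @param ... Unused.
#' @return A tibble with `sample_a`, `sample_b`, `fst`, `n_sites` for each
#'   unordered pair.
#' @method tidy fst_matrix
#' @export
tidy.fst_matrix <- function(x, ...) {
  idx <- which(lower.tri(x$fst), arr.ind = TRUE)
  tibble::tibble(
    sample_a = x$samples[idx[, 2]],
    sample_b = x$samples[idx[, 1]],
    fst = x$fst[idx],
    n_sites = x$n_sites[idx]
  )
}

#' @rdname tidy.fst_matrix
#' @return `glance()`: one-row tibble with the mean, min and max pairwise
#'   FST and the number of samples.
#' @method glance fst_matrix
#' @export
glance.fst_matrix <- function(x, ...) {
  off <- x$fst[lower.tri(x$fst)]
  tibble::tibble(mean_fst = mean(off, na.rm = TRUE),
                 min_fst = min(off, na.rm = TRUE),
                 max_fst = max(off, na.rm = TRUE),
                 n_samples = length(x$samples))
}

#' @method tidy covariate_pca
#' @export
tidy.covariate_pca <- function(x, ...) {
  lt <- tibble::as_tibble(x$loadings, rownames = "variable")
  tidyr::pivot_longer(lt, -"variable", names_to = "component",
                      values_to = "loading")
}

#' @method glance covariate_pca
#' @export
glance.covariate_pca <- function(x, ...) {
  tibble::tibble(component = paste0("PC", seq_along(x$variance_fraction)),
                 variance_fraction = x$variance_fraction)
}

#' Heatmap of pairwise FST
#'
#' @param object An `fst_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fst_matrix
#' @export
autoplot.fst_matrix <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_a, y = .data$sample_b,
                                     fill = .data$fst)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = expression(F[ST])) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Diversity against subpopulation age
#'
#' Scatter of per-pond diversity against log10(age + 1), point size scaled
#' by isolation (NN2), with a linear fit.
#'
#' @param data Tibble with columns `pi`, `age`, and optionally `nn2`.
#' @return A ggplot object.
#' @export
plot_diversity_age <- function(data) {
  p <- ggplot2::ggplot(data, ggplot2::aes(x = log10(.data$age + 1),
                                          y = .data$pi))
  p <- if ("nn2" %in% names(data))
    p + ggplot2::geom_point(ggplot2::aes(size = .data$nn2), alpha = 0.7)
  else p + ggplot2::geom_point(alpha = 0.7)
  p +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x) +
    ggplot2::labs(x = expression(log[10] * "(age + 1)"),
                  y = expression(pi), size = "NN2 (m)") +
    ggplot2::theme_minimal()
}

#' Nonsynonymous against synonymous diversity
#'
#' Scatter of `pi_n` against `pi_s` with the one-to-one line and a linear
#' fit, the standard view of relaxed versus efficient purifying selection.
#'
#' @param data Tibble with columns `pi_n` and `pi_s` (e.g., replicate means
#'   from [run_equilibrium()] or per-pond values from [region_pi()]).
#' @return A ggplot object.
#' @export
plot_pin_pis <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$pi_s, y = .data$pi_n)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x) +
    ggplot2::labs(x = expression(pi[S]), y = expression(pi[N])) +
    ggplot2::theme_minimal()
}

#' Map of a metapopulation state
#'
#' Patch coordinates colored by occupancy, sized by subpopulation age.
#'
#' @param object A `metapop_state`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot metapop_state
#' @export
autoplot.metapop_state <- function(object, ...) {
  d <- object$patches
  ggplot2::ggplot(d, ggplot2::aes(x = .data$lon, y = .data$lat,
                                  colour = .data$occupied)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$age), alpha = 0.8,
                        na.rm = TRUE) +
    ggplot2::geom_point(data = d[!d$occupied, ], size = 0.8, shape = 4) +
    ggplot2::labs(x = "Longitude", y = "Latitude", size = "Age (y)",
                  colour = "Occupied") +
    ggplot2::theme_minimal()
}
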