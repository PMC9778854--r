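#' Specify a distribution of fitness effects (DFE) for new mutations
#'
#' The DFE applies to nonsynonymous mutations only; synonymous mutations are
#' always neutral. Three kinds are supported: `"fixed_zero"` (every selection
#' coefficient is exactly 0), `"gamma_deleterious"` (coefficients are
#' `-Gamma(shape, scale)` with `scale = |gamma_mean| / gamma_shape`, so draws
#' have mean `gamma_mean < 0`), and `"gamma_plus_beneficial"` (as the gamma,
#' except that with probability `beneficial_fraction` a draw is replaced by a
#' fixed beneficial coefficient `+beneficial_s`).
#'
#' @param kind One of `"fixed_zero"`, `"gamma_deleterious"`,
#'   `"gamma_plus_beneficial"`.
#' @param gamma_mean Mean selection coefficient of the deleterious gamma;
#'   must be negative for the gamma kinds.
#' @param gamma_shape Shape of the gamma; must be positive.
#' @param beneficial_fraction Probability that a nonsynonymous mutation is
#'   beneficial (only used by `"gamma_plus_beneficial"`).
#' @param beneficial_s Selection coefficient of beneficial mutations (>= 0).
#'
#' @return An object of class `dfe_spec`.
#' @examples
#' dfe_spec("gamma_deleterious", gamma_mean = -0.03, gamma_shape = 0.2)
#' @export
dfe_spec <- function(kind = c("fixed_zero", "gamma_deleterious",
                              "gamma_plus_beneficial"),
                     gamma_mean = -0.03, gamma_shape = 0.2,
                     beneficial_fraction = 0.015, beneficial_s = 1e-4) {
  kind <- match.arg(kind)
  if (kind != "fixed_zero") {
    if (!is.numeric(gamma_mean) || gamma_mean >= 0)
      abort("`gamma_mean` must be negative for gamma DFEs.")
    if (!is.numeric(gamma_shape) || gamma_shape <= 0)
      abort("`gamma_shape` must be > 0.")
  }
  if (beneficial_fraction < 0 || beneficial_fraction > 1)
    abort("`beneficial_fraction` must lie in [0, 1].")
  if (beneficial_s < 0)
    abort("`beneficial_s` must be >= 0.")
  structure(
    list(kind = kind, gamma_mean = gamma_mean, gamma_shape = gamma_shape,
         beneficial_fraction = beneficial_fraction,
         beneficial_s = beneficial_s),
    class = "dfe_spec"
  )
}

#' @export
print.dfe_spec <- function(x, ...) {
  cat("<dfe_spec>", x$kind, "\n")
  if (x$kind != "fixed_zero")
    cat("  gamma mean:", x$gamma_mean, " shape:", x$gamma_shape, "\n")
  if (x$kind == "gamma_plus_beneficial")
    cat("  beneficial: fraction", x$beneficial_fraction,
        " s =", x$beneficial_s, "\n")
  invisible(x)
}

#' Draw selection coefficients from a DFE
#'
#' @param dfe A [dfe_spec()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`. Exactly 0 for `"fixed_zero"`.
#' @examples
#' set.seed(1)
#' draw_selection_coefficient(dfe_spec("gamma_deleterious"), 5)
#' @export
draw_selection_coefficient <- function(dfe, n = 1) {
  stopifnot(inherits(dfe, "dfe_spec"))
  if (dfe$kind == "fixed_zero") return(rep(0, n))
  scale <- abs(dfe$gamma_mean) / dfe$gamma_shape
  s <- -rgamma(n, shape = dfe$gamma_shape, scale = scale)
  if (dfe$kind == "gamma_plus_beneficial") {
    hit <- runif(n) < dfe$beneficial_fraction
    s[hit] <- dfe$beneficial_s
  }
  s
}
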