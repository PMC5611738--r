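#' Convert beta values to M values
#'
#' The M value is the logit2 transform `log2(beta / (1 - beta))`, the
#' standard variance-stabilizing scale for statistical modelling of
#' methylation array data. Betas are clipped to `[epsilon, 1 - epsilon]`
#' before the transform so that fully (un)methylated probes map to large
#' finite values rather than infinities.
#'
#' @param beta Numeric vector, matrix or array of methylation proportions
#'   in `[0, 1]`. `NA`s are propagated.
#' @param epsilon Clipping bound applied to beta before the logit
#'   (default `1e-6`).
#' @return Object of the same shape as `beta` on the M scale.
#' @seealso [m_to_beta()] for the inverse transform.
#' @examples
#' beta_to_m(c(0.5, 0.8)) # 0 and 2
#' @export
beta_to_m <- function(beta, epsilon = 1e-6) {
  rng <- range(beta, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1)) {
    stop("beta values must lie in [0, 1]")
  }
  b <- pmin(pmax(beta, epsilon), 1 - epsilon)
  log2(b / (1 - b))
}

#' Convert M values back to beta values
#'
#' Inverse of [beta_to_m()]: `2^m / (2^m + 1)`. Exact inverse of the
#' clipped transform on `[epsilon, 1 - epsilon]`.
#'
#' @param m Numeric vector, matrix or array of M values.
#' @return Methylation proportions in `(0, 1)`, same shape as `m`.
#' @export
m_to_beta <- function(m) {
  1 / (1 + 2^(-m))
}
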