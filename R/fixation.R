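#' Fixation-probability ratio under the Poisson random field model
#'
#' `fixation_ratio()` maps a population-scaled selection coefficient
#' \eqn{\gamma = 2Ns} to the relative fixation rate of a selected mutation
#' versus a neutral one, \eqn{g(\gamma) = \gamma / (1 - e^{-\gamma})}, with
#' the removable singularity \eqn{g(0) = 1}. `invert_fixation_ratio()` is its
#' inverse, computed by monotone root finding. The ratio is the quantity the
#' replacement-by-fixed interaction of the count model acts on: divergence in
#' a selected site class is inflated (or suppressed) by `g(gamma)` relative to
#' the neutral expectation.
#'
#' `g` is strictly increasing and positive, with \eqn{g(\gamma)/g(-\gamma) =
#' e^{\gamma}} exactly.
#'
#' @param gamma numeric vector of selection coefficients (dimensionless).
#' @return numeric vector of fixation-rate ratios, same length as `gamma`.
#' @examples
#' fixation_ratio(0)            # 1
#' fixation_ratio(2)            # 2 / (1 - exp(-2)) ~ 2.313
#' invert_fixation_ratio(1)     # 0
#' @export
fixation_ratio <- function(gamma) {
  if (!is.numeric(gamma) || any(!is.finite(gamma))) {
    stop_input("'gamma' must be finite numeric")
  }
  out <- numeric(length(gamma))
  small <- abs(gamma) < 1e-8
  # series expansion near 0: gamma/(1-exp(-gamma)) = 1 + gamma/2 + gamma^2/12 + ...
  out[small] <- 1 + gamma[small] / 2 + gamma[small]^2 / 12
  g <- gamma[!small]
  out[!small] <- g / (-expm1(-g))
  out
}

#' @param r numeric vector of positive fixation-rate ratios.
#' @rdname fixation_ratio
#' @export
invert_fixation_ratio <- function(r) {
  if (!is.numeric(r) || any(!is.finite(r)) || any(r <= 0)) {
    stop_input("'r' must be positive and finite")
  }
  vapply(r, invert_one_ratio, numeric(1))
}

invert_one_ratio <- function(r) {
  if (abs(r - 1) < 1e-12) return(0)
  # g(x) ~ x for large positive x; g(x) ~ |x| e^{-|x|} for large negative x,
  # so a symmetric bracket grown from the magnitude of log(r) always works.
  hi <- max(4, 2 * abs(log(r)) + r + 4)
  root <- uniroot(function(x) fixation_ratio(x) - r,
                  lower = -hi, upper = hi, tol = 1e-12, extendInt = "upX")
  root$root
}

#' Classify genes by selection regime from point estimates of gamma
#'
#' Genes with \eqn{\gamma > 1} are classed `positive`, \eqn{\gamma < -1}
#' `negative`, and everything in the closed interval \eqn{[-1, 1]}
#' `near_neutral` (boundary values count as near-neutral).
#'
#' @param gamma_hat numeric vector of estimated selection coefficients.
#' @param thresholds length-2 numeric, lower and upper class boundaries.
#' @return character vector in `c("negative", "near_neutral", "positive")`.
#' @examples
#' classify_selection(c(-2, -1, 0.4, 1.5))
#' @export
classify_selection <- function(gamma_hat, thresholds = c(-1, 1)) {
  if (!is.numeric(gamma_hat) || any(!is.finite(gamma_hat))) {
    stop_input("'gamma_hat' must be finite numeric")
  }
  stopifnot(length(thresholds) == 2, thresholds[1] < thresholds[2])
  ifelse(gamma_hat > thresholds[2], "positive",
         ifelse(gamma_hat < thresholds[1], "negative", "near_neutral"))
}
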