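# Discrete power-law tail fitting for network connectedness, in the
# Clauset-Shalizi-Newman style: per-candidate x_min discrete MLE of the
# exponent, model selection by Kolmogorov-Smirnov distance, and a
# semi-parametric bootstrap goodness-of-fit test.

# Hurwitz zeta(alpha, q) = sum_{k>=q} k^-alpha for integer q >= 1, via the
# Riemann zeta minus the finite head. Vectorized over q.
hurwitz_zeta <- function(alpha, q) {
  stopifnot(alpha > 1, all(q >= 1))
  z <- pracma::zeta(alpha)
  qmax <- max(q)
  head <- c(0, cumsum(seq_len(qmax - 1)^(-alpha)))  # head[q] = sum_{k<q} k^-alpha
  z - head[q]
}

#' Sample degrees from a (truncated) discrete power law
#'
#' Draws `n` integers from \eqn{P(k) \propto k^{-\alpha}} on the support
#' `x_min..k_max` by exact enumeration of the probability mass function.
#' This is the generative counterpart of [fit_power_law_tail()]: it produces
#' the heavy-tailed out-degree sequences characteristic of scale-free
#' regulatory networks.
#'
#' @param n number of values to draw (may be 0).
#' @param alpha power-law exponent, must exceed 1.
#' @param x_min smallest attainable degree (integer, >= 1).
#' @param k_max largest attainable degree; the truncation mass above any
#'   practical `k_max` is negligible for the exponents used here.
#' @param seed optional integer; when supplied the draw is reproducible and
#'   the caller's RNG stream is left untouched.
#' @return integer vector of length `n` with values in `[x_min, k_max]`.
#' @examples
#' k <- sample_power_law_degrees(500, alpha = 3, x_min = 1, seed = 1)
#' mean(k)  # close to zeta(2)/zeta(3) ~ 1.368
#' @export
sample_power_law_degrees <- function(n, alpha, x_min = 1L, k_max = 1e6L,
                                     seed = NULL) {
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha) ||
      alpha <= 1) {
    stop_input("'alpha' must be > 1 (the discrete power law is not ",
               "normalizable otherwise)")
  }
  stopifnot(n >= 0, x_min >= 1, k_max >= x_min)
  n <- as.integer(n)
  if (n == 0L) return(integer(0))
  if (k_max - x_min + 1 > 5e7) stop_input("support too large to enumerate")
  support <- seq.int(x_min, k_max)
  if (length(support) == 1L) return(rep(as.integer(support), n))
  pmf <- support^(-alpha)
  with_seed_if(seed, sample(support, n, replace = TRUE, prob = pmf))
}

# Discrete MLE of the exponent for the tail k >= x_min, by golden-section /
# parabolic search of the profile log-likelihood on [1.01, 6].
plfit_alpha <- function(x_tail, x_min, interval = c(1.01, 6)) {
  n <- length(x_tail)
  slx <- sum(log(x_tail))
  nll <- function(a) a * slx + n * log(hurwitz_zeta(a, x_min))
  optimize(nll, interval = interval, tol = 1e-8)$minimum
}

# KS sup-distance between the empirical tail CDF and the fitted discrete
# power-law CDF, evaluated on the tail support.
plfit_ks <- function(x_tail, x_min, alpha) {
  n <- length(x_tail)
  ks <- sort(unique(x_tail))
  emp <- cumsum(tabulate(x_tail - x_min + 1L, nbins = max(ks) - x_min + 1L)) / n
  emp <- emp[ks - x_min + 1L]
  zx <- hurwitz_zeta(alpha, x_min)
  mod <- 1 - hurwitz_zeta(alpha, ks + 1L) / zx
  max(abs(emp - mod))
}

#' Fit a discrete power law to the tail of a degree distribution
#'
#' For each candidate cutoff `x_min` among the unique observed values, the
#' exponent is estimated by discrete maximum likelihood (normalized by the
#' Hurwitz zeta) and the cutoff minimizing the Kolmogorov-Smirnov distance
#' between the empirical and fitted tail CDFs is selected. Pass `x_min` to
#' skip the cutoff search and fit the exponent at a fixed tail start.
#'
#' @param k_values integer vector of degrees (connectedness values).
#' @param x_min optional fixed tail cutoff; default searches all candidates.
#' @param interval search interval for the exponent.
#' @return an object of class `power_law_fit`: a list with `x_min`, `alpha`,
#'   `ks_statistic`, `n_tail`, `n`, and (after [bootstrap_gof()]) `gof_p`.
#' @examples
#' k <- sample_power_law_degrees(2000, alpha = 2.5, x_min = 1, seed = 1)
#' fit_power_law_tail(k)
#' @seealso [bootstrap_gof()] for the goodness-of-fit p-value.
#' @export
fit_power_law_tail <- function(k_values, x_min = NULL, interval = c(1.01, 6)) {
  k_values <- as.integer(k_values)
  if (length(k_values) < 10) stop_input("need at least 10 degree values")
  if (length(unique(k_values)) < 2) stop_input("degenerate input: all values equal")
  if (any(k_values < 1)) stop_input("degrees must be >= 1")

  cands <- if (is.null(x_min)) sort(unique(k_values)) else as.integer(x_min)
  best <- NULL
  for (xm in cands) {
    tail_x <- k_values[k_values >= xm]
    if (length(tail_x) < 2 || length(unique(tail_x)) < 2) {
      if (!is.null(x_min)) stop_input("fewer than 2 distinct tail values at x_min = ", xm)
      next
    }
    a <- plfit_alpha(tail_x, xm, interval)
    ks <- plfit_ks(tail_x, xm, a)
    if (is.null(best) || ks < best$ks_statistic) {
      best <- list(x_min = xm, alpha = a, ks_statistic = ks,
                   n_tail = length(tail_x))
    }
  }
  if (is.null(best)) stop_input("no admissible x_min candidate")
  best$n <- length(k_values)
  best$gof_p <- NA_real_
  best$fixed_x_min <- !is.null(x_min)
  class(best) <- "power_law_fit"
  best
}

#' Semi-parametric bootstrap goodness-of-fit for a power-law tail
#'
#' Each bootstrap replicate keeps the empirical body (values below the fitted
#' `x_min`, resampled with replacement) and draws its tail from the fitted
#' discrete power law; the full fitting procedure (cutoff search included,
#' unless the original fit fixed `x_min`) is re-run on the replicate and its
#' KS distance recorded. The p-value is the fraction of replicate KS
#' distances at least as large as the observed one; small p indicates the
#' power law is a poor description of the tail.
#'
#' @param fit a `power_law_fit` object.
#' @param k_values the degree data the fit was produced from.
#' @param n_boot number of bootstrap replicates (>= 1).
#' @param seed optional integer for reproducibility.
#' @return the `power_law_fit` with `gof_p` filled in and a
#'   `boot_ks` vector of replicate KS distances attached.
#' @export
bootstrap_gof <- function(fit, k_values, n_boot = 200, seed = NULL) {
  stopifnot(inherits(fit, "power_law_fit"))
  if (n_boot < 1) stop_input("'n_boot' must be >= 1")
  k_values <- as.integer(k_values)
  n <- length(k_values)
  body <- k_values[k_values < fit$x_min]
  p_tail <- 1 - length(body) / n
  xm_arg <- if (isTRUE(fit$fixed_x_min)) fit$x_min else NULL
  # the fitted tail law is fixed across replicates: enumerate its pmf once
  # and draw every replicate's tail in one bulk call
  k_hi <- 1e6L
  support <- seq.int(fit$x_min, k_hi)
  pmf <- support^(-fit$alpha)
  boot_ks <- with_seed_if(seed, {
    n_tails <- rbinom(n_boot, n, p_tail)
    all_tail <- sample(support, sum(n_tails), replace = TRUE, prob = pmf)
    splits <- rep.int(seq_len(n_boot), n_tails)
    vapply(seq_len(n_boot), function(b) {
      n_tail <- n_tails[b]
      rep_body <- if (n - n_tail > 0) sample(body, n - n_tail, replace = TRUE) else integer(0)
      rep_tail <- all_tail[splits == b]
      rep_fit <- fit_power_law_tail(c(rep_body, rep_tail), x_min = xm_arg)
      rep_fit$ks_statistic
    }, numeric(1))
  })
  fit$gof_p <- mean(boot_ks >= fit$ks_statistic)
  fit$boot_ks <- boot_ks
  fit$n_boot <- n_boot
  fit
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat("Discrete power-law tail fit\n")
  cat(sprintf("  x_min = %d%s, alpha = %.3f\n", x$x_min,
              if (isTRUE(x$fixed_x_min)) " (fixed)" else "", x$alpha))
  cat(sprintf("  tail n = %d of %d values, KS = %.4f\n",
              x$n_tail, x$n, x$ks_statistic))
  if (!is.na(x$gof_p)) {
    cat(sprintf("  bootstrap GoF p = %.3f (%d replicates)\n", x$gof_p, x$n_boot))
  }
  invisible(x)
}

#' Connectedness-tail presets
#'
#' Named parameter sets for the degree-tail generator. The
#' `"honeybee-trn-tail"` preset reproduces the fitted tail of the honey bee
#' brain TRN connectedness distribution (exponent 3.00 above a cutoff of 42).
#'
#' @param name preset name.
#' @return list with `alpha` and `x_min`.
#' @export
power_law_preset <- function(name = "honeybee-trn-tail") {
  switch(name,
         "honeybee-trn-tail" = list(alpha = 3.00, x_min = 42L),
         stop_input("unknown power-law preset: ", name))
}
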