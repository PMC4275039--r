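# Poisson random-effects estimation of per-gene selection coefficients from
# McDonald-Kreitman count tables. The marginal model is fit by Laplace
# penalized likelihood (lme4); per-gene selection effects are then either the
# conditional modes ("laplace") or, by default, empirical-Bayes posterior
# means under a 3-component normal mixture prior re-fit to the unshrunk
# gene effects ("mixture"). The mixture prior matters: selection-effect
# distributions are spike-and-tail shaped (most genes near neutral, a few
# strongly selected), and a single normal prior inflated by the tails
# under-shrinks the near-neutral majority.

#' Fit the McDonald-Kreitman Poisson random-effects model
#'
#' For gene \eqn{i} and count cell \eqn{c} (silent/selected x
#' polymorphic/fixed) the model is
#' \deqn{\log E[y_{ic}] = \log L_{ic} + \mu + \beta_F I_{fixed}
#'   + (\beta_R + r_i) I_{sel} + (\beta_{RF} + s_i) I_{sel} I_{fixed} + a_i}
#' with independent normal random effects \eqn{a_i, r_i, s_i}. The selected
#' class is replacement sites (`context = "coding"`, columns PR/FR) or
#' upstream regulatory sites (`context = "regulatory"`, columns PC/FC). The
#' gene-level selection effect \eqn{e_i = \beta_{RF} + s_i} is the log
#' fixation-rate ratio that [estimate_gamma()] converts to a
#' population-scaled selection coefficient.
#'
#' @param counts an `mk_counts` data.frame (see [simulate_counts()] /
#'   [tabulate_mk_counts()]), or a path to a TSV written by
#'   [write_mk_counts()].
#' @param context `"coding"` or `"regulatory"`.
#' @param shrink `"mixture"` (default) re-shrinks gene effects under an
#'   EM-fitted 3-component normal mixture prior; `"laplace"` reports the
#'   conditional modes under the fitted normal prior.
#' @param min_genes fits with fewer informative genes trigger a warning.
#' @return an object of class `mk_glmm` with components `fixef` (mu, beta_F,
#'   beta_R, beta_RF), `varcomp` (random-effect sds), `effects` (per-gene
#'   table with modes, conditional variances, the selection effect `e` and
#'   its variance), `mixture` (EM prior fit, when used), `dropped`
#'   (excluded genes with reasons), `converged`, and the underlying lme4
#'   `model`.
#' @examples
#' \donttest{
#' g <- draw_gamma_profile(300, "honeybee-regulatory", seed = 1)
#' counts <- simulate_counts(g, sim_config(), "regulatory", seed = 2)
#' fit <- fit_mk_glmm(counts, context = "regulatory")
#' summary(fit)
#' }
#' @export
fit_mk_glmm <- function(counts, context = c("coding", "regulatory"),
                        shrink = c("mixture", "laplace"),
                        min_genes = 30) {
  context <- match.arg(context)
  shrink <- match.arg(shrink)
  if (is.character(counts)) counts <- read_mk_counts(counts)
  sel <- if (context == "coding") c("PR", "FR") else c("PC", "FC")
  need <- c("gene_id", "PS", "FS", sel, "L_syn",
            if (context == "coding") "L_repl" else "L_reg")
  if (!all(need %in% names(counts))) {
    stop_input("count table lacks columns: ",
               paste(setdiff(need, names(counts)), collapse = ", "))
  }
  d <- counts[, need]
  names(d) <- c("gene_id", "PS", "FS", "Psel", "Fsel", "L_syn", "L_sel")
  if (anyNA(d)) stop_input("missing counts for context '", context, "'")

  drop_silent <- d$PS + d$FS == 0
  dropped <- data.frame(gene_id = d$gene_id[drop_silent],
                        reason = rep("no silent counts (offset undefined)",
                                     sum(drop_silent)),
                        stringsAsFactors = FALSE)
  d <- d[!drop_silent, ]
  n <- nrow(d)
  if (n < 2) stop_input("need at least 2 genes with silent counts")
  if (n < min_genes) {
    warning("only ", n, " informative genes; variance components will be unstable")
  }
  if (all(d$Psel + d$Fsel == 0)) {
    stop_input("all selected-class counts are zero: beta_R unidentifiable")
  }

  long <- data.frame(
    gene = factor(rep(d$gene_id, 4), levels = d$gene_id),
    count = c(d$PS, d$FS, d$Psel, d$Fsel),
    f = rep(c(0, 1, 0, 1), each = n),
    r = rep(c(0, 0, 1, 1), each = n),
    logL = log(c(d$L_syn, d$L_syn, d$L_sel, d$L_sel)))
  long$rf <- long$f * long$r

  model <- suppressMessages(lme4::glmer(
    count ~ f * r + (1 | gene) + (0 + r | gene) + (0 + rf | gene) +
      offset(logL),
    data = long, family = stats::poisson,
    control = lme4::glmerControl(calc.derivs = FALSE,
                                 check.conv.singular = "ignore")))

  fe <- lme4::fixef(model)
  fixef <- c(mu = unname(fe["(Intercept)"]), beta_F = unname(fe["f"]),
             beta_R = unname(fe["r"]), beta_RF = unname(fe["f:r"]))
  se_betaRF <- sqrt(stats::vcov(model)["f:r", "f:r"])
  vc <- as.data.frame(lme4::VarCorr(model))
  varcomp <- c(sd_a = vc$sdcor[vc$grp == "gene" & vc$var1 == "(Intercept)"],
               sd_r = vc$sdcor[vc$grp == "gene.1"],
               sd_s = vc$sdcor[vc$grp == "gene.2"])

  re <- lme4::ranef(model, condVar = TRUE)$gene
  pv <- attr(re, "postVar")
  eff <- data.frame(
    gene_id = rownames(re),
    a_mode = re[["(Intercept)"]], r_mode = re[["r"]], s_mode = re[["rf"]],
    s_condvar = pv$rf[1, 1, ], stringsAsFactors = FALSE)

  msgs <- unlist(model@optinfo$conv$lme4$messages)
  converged <- length(msgs) == 0

  fit <- structure(list(
    context = context, shrink = shrink, fixef = fixef, se_betaRF = se_betaRF,
    varcomp = varcomp, effects = eff, dropped = dropped, n_genes = n,
    converged = converged, messages = msgs, model = model,
    call = match.call()), class = "mk_glmm")

  fit <- add_selection_effects(fit)
  fit
}

# Attach the per-gene selection effect e_i and its variance, applying the
# requested shrinkage scheme.
add_selection_effects <- function(fit) {
  eff <- fit$effects
  beta_RF <- fit$fixef["beta_RF"]
  s2 <- fit$varcomp["sd_s"]^2
  if (fit$shrink == "laplace" || s2 < 1e-6) {
    # conditional modes; with a degenerate variance component every gene
    # collapses onto the fixed effect
    eff$e <- beta_RF + eff$s_mode
    eff$e_var <- eff$s_condvar + fit$se_betaRF^2
    fit$mixture <- NULL
  } else {
    # unshrink the conditional modes to pseudo-MLEs with effective data
    # variances: for a normal-normal pair, mode = z * s2 / (s2 + v) and
    # condvar = (1/v + 1/s2)^-1, which inverts to
    v_data <- 1 / pmax(1 / eff$s_condvar - 1 / s2, 1e-8)
    v_data <- pmin(v_data, 1e6)
    z <- beta_RF + eff$s_mode * (v_data + s2) / s2
    mx <- fit_normal_mixture(z, v_data, k = 3)
    eff$e <- mx$post_mean
    eff$e_var <- mx$post_var + fit$se_betaRF^2
    fit$mixture <- mx[c("weights", "means", "sds", "loglik", "iterations")]
  }
  fit$effects <- eff
  fit
}

# EM fit of z_i ~ N(e_i, v_i), e_i ~ sum_k w_k N(m_k, s2_k), returning the
# posterior mean and variance of each e_i.
fit_normal_mixture <- function(z, v, k = 3, max_iter = 300, tol = 1e-8) {
  m <- as.numeric(quantile(z, seq(0.1, 0.9, length.out = k)))
  s2 <- rep(max(var(z) / k, 1e-3), k)
  w <- rep(1 / k, k)
  n <- length(z)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k),
                   function(j) w[j] * dnorm(z, m[j], sqrt(s2[j] + v)),
                   numeric(n))
    tot <- pmax(rowSums(dens), 1e-300)
    ll <- sum(log(tot))
    r <- dens / tot
    post_v <- vapply(seq_len(k), function(j) 1 / (1 / s2[j] + 1 / v), numeric(n))
    post_m <- vapply(seq_len(k),
                     function(j) post_v[, j] * (m[j] / s2[j] + z / v),
                     numeric(n))
    w <- colMeans(r)
    for (j in seq_len(k)) {
      if (w[j] < 1e-8) next
      m[j] <- sum(r[, j] * post_m[, j]) / sum(r[, j])
      s2[j] <- max(sum(r[, j] * ((post_m[, j] - m[j])^2 + post_v[, j])) /
                     sum(r[, j]), 1e-6)
    }
    if (abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  pm <- rowSums(r * post_m)
  pv <- rowSums(r * (post_v + post_m^2)) - pm^2
  list(post_mean = pm, post_var = pmax(pv, 0), weights = w, means = m,
       sds = sqrt(s2), loglik = ll, iterations = it)
}

#' Per-gene selection coefficients from a fitted count model
#'
#' Converts the gene-level selection effects \eqn{e_i} of a fitted
#' [fit_mk_glmm()] model into population-scaled selection coefficients,
#' \eqn{\hat\gamma_i = g^{-1}(e^{e_i})} with \eqn{g} the fixation-rate
#' ratio, propagates the effect's normal interval through the monotone
#' mapping, and classes each gene with [classify_selection()].
#'
#' @param fit an `mk_glmm` object.
#' @param level interval coverage (default 0.95).
#' @param thresholds class boundaries for [classify_selection()].
#' @return data.frame with gene_id, context, e, gamma_hat, lo, hi,
#'   sel_class.
#' @export
estimate_gamma <- function(fit, level = 0.95, thresholds = c(-1, 1)) {
  stopifnot(inherits(fit, "mk_glmm"))
  eff <- fit$effects
  zq <- qnorm(1 - (1 - level) / 2)
  clamp <- function(e) pmin(pmax(e, -30), 30)
  sdv <- sqrt(eff$e_var)
  out <- data.frame(
    gene_id = eff$gene_id, context = fit$context, e = eff$e,
    gamma_hat = invert_fixation_ratio(exp(clamp(eff$e))),
    lo = invert_fixation_ratio(exp(clamp(eff$e - zq * sdv))),
    hi = invert_fixation_ratio(exp(clamp(eff$e + zq * sdv))),
    stringsAsFactors = FALSE)
  out$sel_class <- classify_selection(out$gamma_hat, thresholds)
  out
}

#' Naive per-gene selection effects from the 2x2 count table
#'
#' The unpooled log odds ratio \eqn{\log[(F_{sel}+0.5)/(P_{sel}+0.5)] -
#' \log[(FS+0.5)/(PS+0.5)]} per gene, with Haldane-Anscombe corrections.
#' Used as the no-shrinkage reference the random-effects estimates are
#' compared against.
#'
#' @inheritParams fit_mk_glmm
#' @return data.frame with gene_id, e_naive, gamma_naive.
#' @export
naive_selection_effect <- function(counts, context = c("coding", "regulatory")) {
  context <- match.arg(context)
  sel <- if (context == "coding") c("PR", "FR") else c("PC", "FC")
  e <- log((counts[[sel[2]]] + 0.5) / (counts[[sel[1]]] + 0.5)) -
    log((counts$FS + 0.5) / (counts$PS + 0.5))
  data.frame(gene_id = counts$gene_id, e_naive = e,
             gamma_naive = invert_fixation_ratio(exp(pmin(pmax(e, -30), 30))),
             stringsAsFactors = FALSE)
}

#' @export
print.mk_glmm <- function(x, ...) {
  cat("McDonald-Kreitman Poisson random-effects fit (", x$context,
      " context)\n", sep = "")
  cat(sprintf("  genes: %d (dropped: %d), shrinkage: %s\n",
              x$n_genes, nrow(x$dropped), x$shrink))
  cat("  fixed effects:\n")
  print(round(x$fixef, 4))
  cat("  random-effect sds:\n")
  print(round(x$varcomp, 4))
  if (!is.null(x$mixture)) {
    cat(sprintf("  mixture prior: weights %s, means %s\n",
                paste(round(x$mixture$weights, 3), collapse = "/"),
                paste(round(x$mixture$means, 2), collapse = "/")))
  }
  if (!x$converged) {
    cat("  WARNING: optimizer reported:\n   ",
        paste(x$messages, collapse = "\n    "), "\n")
  }
  invisible(x)
}

#' @export
coef.mk_glmm <- function(object, ...) object$fixef

#' @export
summary.mk_glmm <- function(object, ...) {
  gam <- estimate_gamma(object)
  structure(list(fit = object, gamma = gam,
                 class_fractions = prop.table(table(gam$sel_class))),
            class = "summary.mk_glmm")
}

#' @export
print.summary.mk_glmm <- function(x, ...) {
  print(x$fit)
  cat(sprintf("mean gamma_hat = %.3f\n", mean(x$gamma$gamma_hat)))
  print(round(x$class_fractions, 3))
  invisible(x)
}

#' @export
predict.mk_glmm <- function(object, newdata = NULL, type = "response", ...) {
  if (is.null(newdata)) return(predict(object$model, type = type))
  predict(object$model, newdata = newdata, type = type, ...)
}

#' @export
residuals.mk_glmm <- function(object, type = "pearson", ...) {
  residuals(object$model, type = type)
}

#' @export
simulate.mk_glmm <- function(object, nsim = 1, seed = NULL, ...) {
  with_seed_if(seed, {
    mu <- predict(object$model, type = "response")
    replicate(nsim, rpois(length(mu), mu), simplify = FALSE)
  })
}

#' @export
plot.mk_glmm <- function(x, breaks = 50, ...) {
  gam <- estimate_gamma(x)
  hist(gam$gamma_hat, breaks = breaks,
       main = paste("Estimated selection coefficients,", x$context),
       xlab = expression(hat(gamma)), ...)
  abline(v = c(-1, 1), lty = 2)
  invisible(gam)
}

#' Write gamma estimates as TSV
#' @param gamma data.frame from [estimate_gamma()].
#' @param path file path.
#' @export
write_gamma_estimates <- function(gamma, path) {
  write.table(gamma, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
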