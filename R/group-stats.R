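# Group comparisons used by the analysis: one-tailed Wilcoxon rank-sum
# contrasts of gamma between hub and non-hub genes, a chi-square enrichment
# of hubs for negatively selected genes, and a two-sided Wilcoxon contrast
# of betweenness between selection classes.

#' Wilcoxon rank-sum test with an exact small-sample backend
#'
#' Midranks are used for ties. The p-value is exact (by enumeration of rank
#' assignments) when both samples have at most 8 untied observations;
#' otherwise the normal approximation with tie and continuity correction is
#' used. The reported statistic is the Mann-Whitney U for the first sample.
#'
#' @param x,y numeric samples.
#' @param alternative `"two_sided"`, `"less"` (x tends below y) or
#'   `"greater"`.
#' @return list with `statistic`, `p_value`, `exact` flag and sample sizes.
#' @examples
#' wilcoxon_rank_sum(1:3, 4:6, alternative = "less")$p_value  # 1/20
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two_sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0) stop_input("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && length(x) <= 8 && length(y) <= 8
  alt <- sub("two_sided", "two.sided", alternative)
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = alt, exact = exact, correct = TRUE))
  p <- wt$p.value
  # degenerate case: every observation tied across both samples
  if (is.nan(p)) p <- 1
  list(statistic = unname(wt$statistic), p_value = p,
       exact = exact, n_x = length(x), n_y = length(y))
}

#' Chi-square test for a 2x2 table
#'
#' One degree of freedom, Yates continuity correction on by default. A zero
#' row or column margin makes the expected counts undefined and is an error.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param correct apply the Yates correction.
#' @return list with `statistic` and `p_value`.
#' @examples
#' chi_square_2x2(matrix(c(20, 5, 5, 20), 2), correct = FALSE)
#' @export
chi_square_2x2 <- function(table, correct = TRUE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop_input("need a 2x2 table")
  if (any(table < 0) || sum(table) == 0) stop_input("counts must be non-negative, total > 0")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop_input("zero margin: expected counts undefined")
  }
  ct <- suppressWarnings(chisq.test(table, correct = correct))
  list(statistic = unname(ct$statistic), p_value = ct$p.value)
}

sem <- function(x) sd(x) / sqrt(length(x))

comparison_row <- function(id, a_label, b_label, a, b, test, alternative,
                           statistic, p) {
  data.frame(comparison_id = id, group_a = a_label, group_b = b_label,
             n_a = length(a), n_b = length(b),
             mean_a = mean(a), mean_b = mean(b),
             sem_a = sem(a), sem_b = sem(b),
             test = test, alternative = alternative,
             statistic = statistic, p_value = p, stringsAsFactors = FALSE)
}

#' Compare selection coefficients of hub versus non-hub genes
#'
#' Produces the four one-tailed Wilcoxon contrasts (TF and target roles, each
#' for coding and regulatory gamma) with the alternative that hub genes have
#' lower gamma (stronger purifying selection), as expected a priori from the
#' pleiotropy of highly connected genes; plus, per role, a chi-square test of
#' whether hubs are enriched for genes under negative selection on their
#' coding sequence.
#'
#' @param gamma data.frame of gamma estimates with columns `gene_id`,
#'   `context` (coding/regulatory) and `gamma_hat` (e.g. from
#'   [estimate_gamma()], both contexts stacked).
#' @param metrics data.frame from [node_metrics()]; `node_id` must match
#'   `gene_id`.
#' @param negative_threshold gamma below which a gene counts as negatively
#'   selected in the enrichment test; the default 0 means "negative gamma",
#'   with the stricter `-1` class boundary available.
#' @return data.frame of comparisons (4 Wilcoxon + 2 chi-square rows).
#' @export
compare_hub_vs_nonhub <- function(gamma, metrics, negative_threshold = 0) {
  stopifnot(all(c("gene_id", "context", "gamma_hat") %in% names(gamma)),
            all(c("node_id", "role", "hub") %in% names(metrics)))
  rows <- list()
  for (role in c("TF", "target")) {
    m <- metrics[metrics$role == role & !is.na(metrics$hub), ]
    for (ctx in c("coding", "regulatory")) {
      gg <- gamma[gamma$context == ctx, ]
      j <- merge(m, gg, by.x = "node_id", by.y = "gene_id")
      hub_g <- j$gamma_hat[j$hub]
      non_g <- j$gamma_hat[!j$hub]
      if (length(hub_g) == 0) stop_input("empty hub class for role ", role)
      w <- wilcoxon_rank_sum(hub_g, non_g, alternative = "less")
      rows[[paste(role, ctx, sep = "-")]] <- comparison_row(
        paste0(role, "-", ctx), "hub", "non-hub", hub_g, non_g,
        "wilcoxon", "less", w$statistic, w$p_value)
    }
    # enrichment of hubs for negatively selected coding sequences
    gg <- gamma[gamma$context == "coding", ]
    j <- merge(m, gg, by.x = "node_id", by.y = "gene_id")
    neg <- j$gamma_hat < negative_threshold
    tab <- table(factor(j$hub, c(TRUE, FALSE)), factor(neg, c(TRUE, FALSE)))
    cs <- chi_square_2x2(tab)
    rows[[paste0(role, "-enrichment")]] <- comparison_row(
      paste0(role, "-coding-negative-enrichment"), "hub", "non-hub",
      j$gamma_hat[j$hub], j$gamma_hat[!j$hub],
      "chi_square", "two_sided", cs$statistic, cs$p_value)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare betweenness between positively and negatively selected genes
#'
#' Two-sided Wilcoxon rank-sum test of rescaled betweenness between genes
#' under substantial positive selection (gamma > 1) and substantial negative
#' selection (gamma < -1) in the given context; near-neutral genes are
#' excluded.
#'
#' @param gamma data.frame with `gene_id`, `context`, `gamma_hat`.
#' @param metrics data.frame from [node_metrics()].
#' @param context `"coding"` or `"regulatory"`.
#' @param thresholds class boundaries, default `c(-1, 1)`.
#' @return one-row comparison data.frame.
#' @export
compare_betweenness_by_selection <- function(gamma, metrics,
                                             context = c("coding", "regulatory"),
                                             thresholds = c(-1, 1)) {
  context <- match.arg(context)
  gg <- gamma[gamma$context == context, ]
  j <- merge(metrics, gg, by.x = "node_id", by.y = "gene_id")
  pos <- j$betweenness[j$gamma_hat > thresholds[2]]
  neg <- j$betweenness[j$gamma_hat < thresholds[1]]
  if (length(pos) == 0) stop_input("no genes in the positive-selection class (", context, ")")
  if (length(neg) == 0) stop_input("no genes in the negative-selection class (", context, ")")
  w <- wilcoxon_rank_sum(pos, neg, alternative = "two_sided")
  comparison_row(paste0("betweenness-", context), "positive", "negative",
                 pos, neg, "wilcoxon", "two_sided", w$statistic, w$p_value)
}
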