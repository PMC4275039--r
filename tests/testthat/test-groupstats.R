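test_that("rank-sum test reproduces textbook cases", {
  # all C(6,3) = 20 assignments, only one as extreme
  expect_equal(wilcoxon_rank_sum(1:3, 4:6, "less")$p_value, 1 / 20)
  expect_true(wilcoxon_rank_sum(1:3, 4:6, "less")$exact)
  # identical samples carry no signal
  p <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3), "two_sided")$p_value
  expect_gte(p, 0.99)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("exact backend equals full enumeration on random untied samples", {
  withr::with_seed(13, {
    for (i in 1:30) {
      nx <- sample(3:8, 1); ny <- sample(3:8, 1)
      vals <- sample(1:100, nx + ny)
      x <- vals[seq_len(nx)]; y <- vals[-seq_len(nx)]
      alt <- sample(c("less", "greater", "two_sided"), 1)
      ours <- wilcoxon_rank_sum(x, y, alt)
      expect_true(ours$exact)
      expect_equal(ours$p_value, wilcox_enum_p(x, y, alt), tolerance = 1e-12)
    }
  })
})

test_that("exact and approximate backends agree closely at n = 8 vs 8", {
  withr::with_seed(14, {
    for (i in 1:20) {
      vals <- sample(1:1000, 16)
      x <- vals[1:8]; y <- vals[9:16]
      pe <- wilcoxon_rank_sum(x, y, "less")$p_value
      pa <- suppressWarnings(
        wilcox.test(x, y, alternative = "less", exact = FALSE,
                    correct = TRUE)$p.value)
      expect_lt(abs(pe - pa), 0.02)
    }
  })
})

test_that("opposite one-tailed p-values cover the distribution", {
  withr::with_seed(15, {
    for (i in 1:20) {
      x <- rnorm(sample(4:12, 1)); y <- rnorm(sample(4:12, 1))
      pl <- wilcoxon_rank_sum(x, y, "less")$p_value
      pg <- wilcoxon_rank_sum(x, y, "greater")$p_value
      expect_gte(pl + pg, 1 - 1e-12)
    }
  })
})

test_that("chi-square matches the hand-computed 2x2 forms", {
  tab <- matrix(c(20, 5, 5, 20), 2)
  expect_equal(chi_square_2x2(tab, correct = FALSE)$statistic, 18,
               tolerance = 1e-12)
  # Yates: n(|ad-bc| - n/2)^2 / (r1 r2 c1 c2)
  expect_equal(chi_square_2x2(tab)$statistic,
               50 * (abs(20 * 20 - 5 * 5) - 25)^2 / (25 * 25 * 25 * 25),
               tolerance = 1e-12)
  flat <- matrix(10, 2, 2)
  res <- chi_square_2x2(flat)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(chi_square_2x2(t(tab), correct = FALSE)$statistic, 18,
               tolerance = 1e-12)
  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2)), "margin")
  expect_error(chi_square_2x2(matrix(1, 3, 3)), "2x2")
})

# small joined dataset with known structure
make_joined <- function(seed = 1, shift = 0) {
  sim <- simulate_trn(sim_config(seed = seed, n_tf = 40, n_target = 120,
                                 degree_alpha = 2.2))
  net <- build_network(sim$edges)
  metrics <- node_metrics(net)
  ids <- metrics$node_id
  withr::with_seed(seed + 1000, {
    gam <- rbind(
      data.frame(gene_id = ids, context = "coding",
                 gamma_hat = rnorm(length(ids), 0, 1)),
      data.frame(gene_id = ids, context = "regulatory",
                 gamma_hat = rnorm(length(ids), -0.4, 1)))
  })
  hubs <- metrics$node_id[!is.na(metrics$hub) & metrics$hub]
  gam$gamma_hat[gam$gene_id %in% hubs] <-
    gam$gamma_hat[gam$gene_id %in% hubs] + shift
  list(gamma = gam, metrics = metrics)
}

test_that("hub comparison emits the contracted shape", {
  d <- make_joined(seed = 2)
  cmp <- compare_hub_vs_nonhub(d$gamma, d$metrics)
  expect_equal(sum(cmp$test == "wilcoxon"), 4)
  expect_equal(sum(cmp$test == "chi_square"), 2)
  expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1))
  expect_true(all(c("n_a", "n_b", "mean_a", "sem_a") %in% names(cmp)))
  expect_true(all(cmp$n_a >= 1 & cmp$n_b >= 1))
})

test_that("a planted hub shift is detected and the null is calibrated", {
  shifted <- compare_hub_vs_nonhub(make_joined(3, shift = -1.5)$gamma,
                                   make_joined(3, shift = -1.5)$metrics)
  row <- shifted[shifted$comparison_id == "TF-coding", ]
  expect_lt(row$p_value, 0.05)
  # null: rejection rate near nominal (seeds whose sparse network yields an
  # empty hub class are skipped; the comparison correctly refuses them)
  rej <- 0; n_ok <- 0
  for (s in 1:40) {
    d <- suppressWarnings(make_joined(seed = 100 + s, shift = 0))
    cmp <- tryCatch(suppressWarnings(compare_hub_vs_nonhub(d$gamma, d$metrics)),
                    error = function(e) NULL)
    if (is.null(cmp)) next
    n_ok <- n_ok + 1
    if (cmp$p_value[cmp$comparison_id == "TF-coding"] < 0.05) rej <- rej + 1
  }
  expect_gte(n_ok, 30)
  expect_lte(rej / n_ok, 0.15)
})

test_that("betweenness-by-selection contrasts behave at their edges", {
  d <- make_joined(seed = 4)
  cmp <- compare_betweenness_by_selection(d$gamma, d$metrics, "coding")
  expect_identical(cmp$test, "wilcoxon")
  expect_identical(cmp$alternative, "two_sided")
  # identical betweenness in both classes carries no signal
  gam <- data.frame(gene_id = paste0("n", 1:10), context = "coding",
                    gamma_hat = c(rep(2, 5), rep(-2, 5)))
  met <- data.frame(node_id = paste0("n", 1:10), role = "target",
                    k = 1, hub = FALSE, betweenness = 0.5, eigenvector = 0)
  p <- compare_betweenness_by_selection(gam, met, "coding")$p_value
  expect_gte(p, 0.99)
  # empty class is an informative error
  gam$gamma_hat <- abs(gam$gamma_hat)
  expect_error(compare_betweenness_by_selection(gam, met, "coding"),
               "negative-selection class")
})
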