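#' Simulate a scale-free transcriptional regulatory network
#'
#' TF out-degrees are drawn from a discrete power law (clipped at the number
#' of available targets) and each TF's targets are sampled uniformly without
#' replacement, so edges are unique and there are no self-loops. The returned
#' truth ledger records the planted degree sequence and hub flags, for use by
#' recovery tests downstream.
#'
#' @param config a [sim_config()] object.
#' @return list with `edges` (data.frame `tf_id`, `target_id`) and `truth`
#'   (list with `tf_degree`, `target_in_degree`, `hub_tf`, `hub_target`,
#'   `seed`).
#' @examples
#' net <- simulate_trn(sim_config(seed = 1, n_tf = 20, n_target = 100))
#' nrow(net$edges) == sum(net$truth$tf_degree)
#' @export
simulate_trn <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_tf < 1 || config$n_target < 1) {
    stop_input("need at least one TF and one target")
  }
  tf_ids <- sprintf("TF%03d", seq_len(config$n_tf))
  tg_ids <- sprintf("TG%04d", seq_len(config$n_target))

  withr::with_seed(config$seed, {
    deg <- sample_power_law_degrees(config$n_tf, config$degree_alpha,
                                    x_min = config$degree_xmin,
                                    k_max = config$n_target)
    targets <- lapply(deg, function(k) sample(tg_ids, k, replace = FALSE))
  })
  edges <- data.frame(
    tf_id = rep(tf_ids, times = deg),
    target_id = unlist(targets),
    stringsAsFactors = FALSE)

  in_deg <- table(factor(edges$target_id, levels = tg_ids))
  in_deg <- setNames(as.integer(in_deg), tg_ids)
  out_deg <- setNames(as.integer(deg), tf_ids)

  safe_hubs <- function(k) {
    if (length(k) < 5) return(setNames(rep(FALSE, length(k)), names(k)))
    suppressWarnings(classify_hubs(k, fraction = config$hub_fraction))
  }
  truth <- list(
    tf_degree = out_deg,
    target_in_degree = in_deg,
    hub_tf = safe_hubs(out_deg),
    hub_target = safe_hubs(in_deg[in_deg > 0]),
    seed = config$seed)
  list(edges = edges, truth = truth)
}
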