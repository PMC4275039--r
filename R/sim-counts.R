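#' Simulate per-gene McDonald-Kreitman count tables
#'
#' The generative inverse of the Poisson random-effects count model. For
#' gene \eqn{i} with diversity \eqn{\theta_i} (log-normal around the
#' configured `theta`), constraint offset \eqn{\rho_i}, divergence scale
#' \eqn{\delta} and true selection coefficient \eqn{\gamma_i}:
#' \deqn{PS_i \sim Poi(\theta_i L_{syn}), \quad
#'       FS_i \sim Poi(\theta_i L_{syn} e^{\delta}),}
#' \deqn{PR_i \sim Poi(\theta_i L e^{\rho_i}), \quad
#'       FR_i \sim Poi(\theta_i L e^{\rho_i} e^{\delta} g(\gamma_i)),}
#' where \eqn{g} is [fixation_ratio()] and \eqn{L} is `L_repl` (coding
#' context) or `L_reg` (regulatory context, in which case the selected pair
#' is reported in the `PC`/`FC` columns).
#'
#' @param true_gamma numeric vector of per-gene selection coefficients, or a
#'   data.frame from [draw_gamma_profile()] (columns `gene_id`,
#'   `gamma_true`).
#' @param config a [sim_config()].
#' @param context `"coding"` or `"regulatory"`.
#' @param seed optional integer for reproducibility.
#' @return an `mk_counts` data.frame (gene_id, PS, PR, FS, FR, PC, FC,
#'   L_syn, L_repl, L_reg) with a `truth` attribute holding the per-gene
#'   `theta_i`, `rho_i` and `gamma_true`.
#' @examples
#' g <- draw_gamma_profile(50, "honeybee-regulatory", seed = 1)
#' counts <- simulate_counts(g, sim_config(), context = "regulatory", seed = 1)
#' head(counts)
#' @export
simulate_counts <- function(true_gamma, config = sim_config(),
                            context = c("coding", "regulatory"),
                            seed = NULL) {
  context <- match.arg(context)
  stopifnot(inherits(config, "sim_config"))
  if (is.data.frame(true_gamma)) {
    gene_id <- true_gamma$gene_id
    gam <- true_gamma$gamma_true
  } else {
    gam <- as.numeric(true_gamma)
    gene_id <- sprintf("gene%05d", seq_along(gam))
  }
  if (any(!is.finite(gam))) stop_input("non-finite true gamma")
  n <- length(gam)
  g_of_gamma <- fixation_ratio(gam)
  if (any(!is.finite(g_of_gamma))) stop_input("fixation ratio overflow")

  L_sel <- if (context == "coding") config$L_repl else config$L_reg
  rho_mean <- if (context == "coding") config$rho_mean_coding else config$rho_mean_regulatory

  with_seed_if(seed, {
    theta_i <- rlnorm(n, log(config$theta), config$theta_sd)
    rho_i <- rnorm(n, rho_mean, config$rho_sd)
    PS <- rpois(n, theta_i * config$L_syn)
    FS <- rpois(n, theta_i * config$L_syn * exp(config$delta))
    Psel <- rpois(n, theta_i * L_sel * exp(rho_i))
    Fsel <- rpois(n, theta_i * L_sel * exp(rho_i + config$delta) * g_of_gamma)
    out <- data.frame(gene_id = gene_id, PS = PS, PR = NA_integer_,
                      FS = FS, FR = NA_integer_, PC = NA_integer_,
                      FC = NA_integer_,
                      L_syn = config$L_syn, L_repl = config$L_repl,
                      L_reg = config$L_reg, stringsAsFactors = FALSE)
    if (context == "coding") {
      out$PR <- Psel; out$FR <- Fsel
    } else {
      out$PC <- Psel; out$FC <- Fsel
    }
    attr(out, "truth") <- data.frame(gene_id = gene_id, theta_i = theta_i,
                                     rho_i = rho_i, gamma_true = gam)
    attr(out, "context") <- context
    class(out) <- c("mk_counts", "data.frame")
    out
  })
}

#' Read and write MK count tables
#'
#' Plain TSV with the stable column order gene_id, PS, PR, FS, FR, PC, FC,
#' L_syn, L_repl, L_reg.
#'
#' @param counts an `mk_counts` data.frame.
#' @param path file path.
#' @return `read_mk_counts` returns an `mk_counts` data.frame.
#' @export
write_mk_counts <- function(counts, path) {
  cols <- c("gene_id", "PS", "PR", "FS", "FR", "PC", "FC",
            "L_syn", "L_repl", "L_reg")
  stopifnot(all(cols %in% names(counts)))
  write.table(counts[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_mk_counts
#' @export
read_mk_counts <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("mk_counts", "data.frame")
  out
}
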