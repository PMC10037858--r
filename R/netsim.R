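#' Simulation configuration for synthetic GRN time-series data
#'
#' Defines a DREAM-style in silico experiment: a random directed network in
#' which only TFs have outgoing edges, and perturbation-response time series
#' integrated from Hill-kinetics ODEs with multiplicative lognormal
#' measurement noise.
#'
#' Defaults emulate the DREAM4 style: ~100-gene networks, samples every
#' 50 minutes (10/20/25/50/100 are the conventional choices) over a
#' 1000-minute horizon, 10 perturbation trajectories, 5% measurement noise.
#' Decay `lambda = 0.02`/min gives a ~50-minute mRNA relaxation time; with
#' maximal transcription `alpha = 1` the unregulated steady state is
#' `alpha/lambda = 50` expression units, and the Hill half-saturation
#' constant defaults to half that level so regulators actually traverse the
#' responsive part of the Hill curve when perturbed.
#'
#' @param n_genes Number of genes.
#' @param n_tfs Number of transcription factors (first `n_tfs` genes).
#' @param mean_out_degree Expected number of targets per TF (Poisson).
#' @param interval_minutes Sampling interval between time points, minutes.
#' @param horizon_minutes Last sampling time, minutes.
#' @param n_trajectories Number of perturbation time series.
#' @param noise_sd Standard deviation of the lognormal measurement noise on
#'   the log scale (fraction-of-signal scale); 0 disables noise.
#' @param hill_coefficient Hill exponent `n`.
#' @param decay_rate First-order decay `lambda`, per minute.
#' @param alpha Maximal transcription rate, units per minute.
#' @param hill_k Hill half-saturation constant; default `0.5 * alpha/decay_rate`.
#' @param seed Integer seed; the network + simulation pair is deterministic
#'   given the seed.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 100, n_tfs = 10, mean_out_degree = 3,
                              interval_minutes = 50, horizon_minutes = 1000,
                              n_trajectories = 10, noise_sd = 0.05,
                              hill_coefficient = 2, decay_rate = 0.02,
                              alpha = 1, hill_k = NULL, seed = 1L) {
  if (n_tfs < 1) grn_abort("n_tfs must be >= 1", "grn_config_error")
  if (n_tfs > n_genes) grn_abort("n_tfs must be <= n_genes", "grn_config_error")
  if (mean_out_degree < 0) grn_abort("mean_out_degree must be >= 0", "grn_config_error")
  if (interval_minutes <= 0 || horizon_minutes < interval_minutes) {
    grn_abort("need horizon_minutes >= interval_minutes > 0", "grn_config_error")
  }
  if (decay_rate <= 0 || alpha <= 0 || hill_coefficient <= 0) {
    grn_abort("rates must be positive", "grn_config_error")
  }
  if (noise_sd < 0) grn_abort("noise_sd must be >= 0", "grn_config_error")
  if (is.null(hill_k)) hill_k <- 0.5 * alpha / decay_rate
  structure(
    list(n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
         mean_out_degree = mean_out_degree, interval_minutes = interval_minutes,
         horizon_minutes = horizon_minutes, n_trajectories = as.integer(n_trajectories),
         noise_sd = noise_sd, hill_coefficient = hill_coefficient,
         decay_rate = decay_rate, alpha = alpha, hill_k = hill_k,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

sim_gene_ids <- function(cfg) sprintf("G%03d", seq_len(cfg$n_genes))

#' Generate a random regulatory network
#'
#' Only TFs have outgoing edges. Each TF's out-degree is Poisson with mean
#' `mean_out_degree` (truncated at `n_genes - 1`); targets are drawn without
#' replacement. Each edge is annotated activator (probability 0.7) or
#' repressor (0.3) with an interaction strength uniform in `[0.5, 2]`.
#'
#' @param cfg A [simulation_config].
#' @return A [regulatory_network] whose `edges` carry `sign` (+1/-1) and
#'   `strength` columns; `regulator_universe` is the full TF set.
#' @export
generate_network <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  genes <- sim_gene_ids(cfg)
  tfs <- genes[seq_len(cfg$n_tfs)]
  edges <- withr::with_seed(cfg$seed, {
    out <- lapply(tfs, function(tf) {
      k <- min(rpois(1, cfg$mean_out_degree), cfg$n_genes - 1L)
      if (k == 0) return(NULL)
      tgt <- sample(setdiff(genes, tf), k)
      data.frame(regulator = tf, target = tgt,
                 sign = ifelse(runif(k) < 0.7, 1, -1),
                 strength = runif(k, 0.5, 2))
    })
    do.call(rbind, out)
  })
  if (is.null(edges)) edges <- data.frame(regulator = character(), target = character(),
                                          sign = numeric(), strength = numeric())
  net <- regulatory_network(edges, regulator_universe = tfs)
  attr(net, "gene_ids") <- genes
  net
}

# Right-hand side builder: dx/dt = alpha * f(x) - lambda * x, with f the
# strength-weighted mean of Hill terms h(x_r) (activators) and 1 - h(x_r)
# (repressors) over a gene's regulators; f = 1 for unregulated genes.
make_rhs <- function(net, cfg, alpha) {
  genes <- attr(net, "gene_ids")
  G <- length(genes)
  Wact <- matrix(0, G, G, dimnames = list(genes, genes))
  Wrep <- matrix(0, G, G, dimnames = list(genes, genes))
  e <- net$edges
  if (nrow(e) > 0) {
    act <- e$sign > 0
    Wact[cbind(match(e$target[act], genes), match(e$regulator[act], genes))] <- e$strength[act]
    Wrep[cbind(match(e$target[!act], genes), match(e$regulator[!act], genes))] <- e$strength[!act]
  }
  wsum <- rowSums(Wact) + rowSums(Wrep)
  regulated <- which(wsum > 0)
  Wact_r <- Wact[regulated, , drop = FALSE]
  Wrep_r <- Wrep[regulated, , drop = FALSE]
  wsum_r <- wsum[regulated]
  Kn <- cfg$hill_k^cfg$hill_coefficient
  n <- cfg$hill_coefficient
  lambda <- cfg$decay_rate
  f <- rep(1, G)
  function(x) {
    xn <- x^n
    h <- xn / (Kn + xn)
    if (length(regulated) > 0) {
      f[regulated] <- (Wact_r %*% h + Wrep_r %*% (1 - h)) / wsum_r
    }
    alpha * f - lambda * x
  }
}

# Fixed-step classical RK4; records the state at the requested sample times,
# which must all be multiples of `step`.
rk4_integrate <- function(rhs, x0, step, sample_times) {
  t_end <- max(sample_times)
  n_steps <- as.integer(round(t_end / step))
  out <- matrix(NA_real_, length(x0), length(sample_times))
  sample_steps <- as.integer(round(sample_times / step))
  hit <- match(0L, sample_steps)
  if (!is.na(hit)) out[, hit] <- x0
  x <- x0
  for (s in seq_len(n_steps)) {
    k1 <- rhs(x)
    k2 <- rhs(x + step / 2 * k1)
    k3 <- rhs(x + step / 2 * k2)
    k4 <- rhs(x + step * k3)
    x <- x + step / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    x[x < 0] <- 0
    hit <- match(s, sample_steps)
    if (!is.na(hit)) out[, hit] <- x
  }
  out
}

#' Simulate perturbation-response expression time series
#'
#' Integrates Hill-kinetics ODEs (`dx_g/dt = alpha_g f_g(x) - lambda x_g`)
#' with a fixed-step RK4 scheme. The system is first relaxed to its
#' unperturbed steady state; each trajectory then applies a knockdown to one
#' randomly chosen TF (its `alpha` scaled by a uniform factor in `[0, 0.2]`)
#' and records samples at `t = 0, interval, 2*interval, ... <= horizon`.
#' Multiplicative lognormal measurement noise with log-scale sd `noise_sd`
#' is applied to every sample.
#'
#' @param net A network from [generate_network()].
#' @param cfg The [simulation_config] used to generate it.
#' @param perturb If `FALSE`, trajectories start at the unperturbed steady
#'   state with no knockdown (useful to verify the integrator conserves a
#'   fixed point). Default `TRUE`.
#' @return An [expression_dataset] with time metadata.
#' @export
simulate_expression <- function(net, cfg, perturb = TRUE) {
  stopifnot(inherits(cfg, "simulation_config"))
  genes <- attr(net, "gene_ids")
  if (is.null(genes)) grn_abort("network lacks gene annotations; use generate_network()",
                                "grn_config_error")
  tfs <- net$regulator_universe
  step <- cfg$interval_minutes / max(20, ceiling(cfg$interval_minutes / 0.5))
  sample_times <- seq(0, cfg$horizon_minutes, by = cfg$interval_minutes)
  alpha0 <- rep(cfg$alpha, length(genes))

  # unperturbed fixed point: relax for ~60 decay time-constants
  rhs0 <- make_rhs(net, cfg, alpha0)
  relax_t <- 60 / cfg$decay_rate
  ss <- rk4_integrate(rhs0, alpha0 / cfg$decay_rate, min(0.5, step), c(0, relax_t))[, 2]

  withr::with_seed(cfg$seed + 1L, {
    # draw all knockdowns up front so the perturbation schedule is the same
    # whether or not measurement noise is later applied
    kd_tfs <- replicate(cfg$n_trajectories, sample(tfs, 1))
    kd_factors <- runif(cfg$n_trajectories, 0, 0.2)
    cols <- list()
    meta <- list()
    for (j in seq_len(cfg$n_trajectories)) {
      alpha_j <- alpha0
      if (perturb) {
        alpha_j[match(kd_tfs[j], genes)] <- alpha_j[match(kd_tfs[j], genes)] * kd_factors[j]
      }
      traj <- rk4_integrate(make_rhs(net, cfg, alpha_j), ss, step, sample_times)
      if (any(!is.finite(traj))) {
        bad <- genes[which(!is.finite(traj), arr.ind = TRUE)[1, 1]]
        grn_abort(sprintf("simulation blow-up (non-finite value) for gene '%s'", bad),
                  "grn_simulation_error")
      }
      if (cfg$noise_sd > 0) {
        traj <- traj * exp(matrix(rnorm(length(traj), 0, cfg$noise_sd), nrow(traj)))
      }
      colnames(traj) <- sprintf("traj%d_t%g", j, sample_times)
      cols[[j]] <- traj
      meta[[j]] <- data.frame(sample_id = colnames(traj),
                              trajectory_id = sprintf("traj%d", j),
                              time_minutes = sample_times)
    }
    values <- do.call(cbind, cols)
    rownames(values) <- genes
    expression_dataset(values, tfs, do.call(rbind, meta))
  })
}
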