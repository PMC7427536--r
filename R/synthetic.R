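# Seeded synthetic-data generators. Every generator returns its ground
# truth alongside the noisy observations, so downstream estimators can be
# benchmarked exactly. Noise structure: multiplicative (CV-based) Gaussian
# noise for concentrations and densities, additive Gaussian noise for Ct
# values - matching how plate readers / HPLC and qPCR instruments err.

#' Generator configuration
#'
#' @param seed Integer seed; fixes all generator output bit-identically.
#' @param noise_cv Coefficient of variation of multiplicative measurement
#'   noise (default 0.02).
#' @param sampling_interval Sampling interval for time series, h.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, noise_cv = 0.02,
                             sampling_interval = 0.25) {
  structure(list(seed = as.integer(seed), noise_cv = noise_cv,
                 sampling_interval = sampling_interval),
            class = "generator_config")
}

#' Synthetic growth curve (lag + exponential + saturation)
#'
#' Logistic growth after a lag phase: OD stays at `od0` until `lag`, then
#' follows a Verhulst trajectory with rate `mu` towards `od_max`.
#' Multiplicative Gaussian noise at `cfg$noise_cv` is applied to the
#' observations; the noiseless truth is attached.
#'
#' @param mu True maximum specific growth rate, 1/h (> 0).
#' @param lag Lag phase, h.
#' @param od0 Inoculation OD.
#' @param od_max Carrying capacity, OD units.
#' @param horizon Duration, h.
#' @param cfg A [generator_config()].
#' @return Data frame with `t`, `od`; attributes `truth` (noiseless curve)
#'   and `params`.
#' @export
gen_growth_curve <- function(mu, lag = 6, od0 = 0.05, od_max = 5,
                             horizon = 24, cfg = generator_config()) {
  if (mu <= 0) stop("mu must be > 0")
  set.seed(cfg$seed)
  t <- seq(0, horizon, by = cfg$sampling_interval)
  te <- pmax(t - lag, 0)
  truth <- od_max * od0 * exp(mu * te) /
    (od_max + od0 * (exp(mu * te) - 1))
  od <- truth * (1 + stats::rnorm(length(t), 0, cfg$noise_cv))
  out <- data.frame(t = t, od = pmax(od, 1e-9))
  attr(out, "truth") <- truth
  attr(out, "params") <- list(mu = mu, lag = lag, od0 = od0,
                              od_max = od_max)
  out
}

#' Synthetic fed-batch fermentation measurements
#'
#' Runs the deterministic simulator ([simulate_fedbatch()]) and overlays
#' per-channel multiplicative measurement noise on X, S, A and P (DO and
#' volumes are returned as logged by the control system, noise-free). The
#' simulator output is retained as the ground truth.
#'
#' @param cfg A [generator_config()].
#' @param sim_config A [fedbatch_config()].
#' @return List with `series` (noisy data frame), `truth`
#'   (`fermentation_sim` object) and `events`.
#' @export
gen_fermentation <- function(cfg = generator_config(),
                             sim_config = fedbatch_config()) {
  sim <- simulate_fedbatch(sim_config)
  set.seed(cfg$seed)
  noisy <- sim$series
  for (col in c("X", "S", "A", "P")) {
    noisy[[col]] <- pmax(
      noisy[[col]] * (1 + stats::rnorm(nrow(noisy), 0, cfg$noise_cv)), 0)
  }
  list(series = noisy, truth = sim, events = sim$events)
}

#' Synthetic qPCR experiment
#'
#' Generates a Ct table for one strain from true expression folds
#' (`ct_gene = ct_ref - log_E(fold) + noise`) plus a seven-point two-fold
#' dilution standard curve per primer with the same amplification
#' efficiency.
#'
#' @param true_folds Named numeric vector, gene -> true fold relative to
#'   the reference gene (> 0).
#' @param efficiency True amplification factor per cycle (2 = perfect
#'   doubling).
#' @param ct_ref_mean Mean Ct of the reference gene.
#' @param sigma_ct Additive Ct noise SD (cycles).
#' @param cfg A [generator_config()].
#' @param strain Strain label.
#' @param reference_gene Reference gene name.
#' @param n_biological Biological replicates (default 2).
#' @param n_technical Technical replicates per biological one (default 3).
#' @return List with `table` (a [qpcr_table()]), `curves` (list of
#'   [standard_curve()] inputs per gene: data frames `log2_dilution`,
#'   `ct`) and `truth`.
#' @export
gen_qpcr <- function(true_folds, efficiency = 2, ct_ref_mean = 20,
                     sigma_ct = 0.1, cfg = generator_config(),
                     strain = "strain1", reference_gene = "rpoB",
                     n_biological = 2, n_technical = 3) {
  if (any(true_folds <= 0)) stop("true folds must be > 0")
  if (efficiency <= 1) stop("efficiency must exceed 1")
  set.seed(cfg$seed)
  genes <- names(true_folds)
  rows <- list()
  for (b in seq_len(n_biological)) {
    ct_ref_b <- ct_ref_mean + stats::rnorm(1, 0, sigma_ct)
    for (k in seq_len(n_technical)) {
      rows[[length(rows) + 1]] <- data.frame(
        gene = reference_gene, strain = strain, replicate = b,
        ct = ct_ref_b + stats::rnorm(1, 0, sigma_ct))
    }
    for (g in genes) {
      # dCt in cycles given the true per-cycle amplification factor
      ct_g <- ct_ref_b - log(true_folds[[g]], base = efficiency)
      for (k in seq_len(n_technical)) {
        rows[[length(rows) + 1]] <- data.frame(
          gene = g, strain = strain, replicate = b,
          ct = ct_g + stats::rnorm(1, 0, sigma_ct))
      }
    }
  }
  tab <- qpcr_table(do.call(rbind, rows), reference_gene = reference_gene)
  # 7-point two-fold dilution series per primer; slope -1/log2(E); each
  # point is the mean of the technical replicates, as read off the plate
  slope_true <- -1 / log2(efficiency)
  dil <- 0:-6
  curves <- lapply(stats::setNames(nm = c(reference_gene, genes)),
                   function(g) {
    ct_pts <- vapply(dil, function(d) {
      mean(ct_ref_mean + slope_true * d +
             stats::rnorm(n_technical, 0, sigma_ct))
    }, numeric(1))
    data.frame(log2_dilution = dil, ct = ct_pts)
  })
  list(table = tab, curves = curves,
       truth = list(folds = true_folds, efficiency = efficiency,
                    sigma_ct = sigma_ct))
}
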