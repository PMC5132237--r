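#' Configuration for the synthetic life-history generator
#'
#' Defaults emulate the structure of curated microfluidics cohorts of
#' wild-type budding yeast: a sigmoidal (discretised log-normal) lifespan
#' distribution with median 16 divisions and a practical range of roughly
#' 6-33; starting cross-sectional areas with median 17.65 um^2; a
#' cell-specific growth rate that is near-constant in time, so post-SEP
#' cycle elongation automatically produces the accelerated per-division
#' enlargement seen late in life; a negative coupling between the
#' per-division size increase (g*tau) and lifespan; and a reporter whose
#' concentration dilutes in rapidly enlarging cells while the total amount
#' rises with age.
#'
#' @param n_cells cohort size.
#' @param start_size_median,start_size_sdlog log-normal starting area
#'   (um^2).
#' @param growth_rate_median,growth_rate_sdlog log-normal per-cell growth
#'   rate g_i (um^2/hour).
#' @param base_cycle_median,base_cycle_sdlog log-normal per-cell base
#'   division duration tau_i (hours).
#' @param cycle_jitter_sdlog multiplicative log-normal jitter applied to
#'   each division's duration before frame snapping.
#' @param frame_min imaging cadence (minutes); division times snap to this
#'   grid.
#' @param lifespan_median,lifespan_sdlog discretised log-normal lifespan
#'   (divisions).
#' @param lifespan_floor minimum divisions per cell, so every cell supports
#'   trajectory fitting.
#' @param lifespan_coupling kappa >= 0: the log-median lifespan decreases
#'   by `kappa * (log(g_i*tau_i) - population log-median)`, so cells that
#'   add more area per division live shorter. Acting through g*tau (not
#'   size itself) keeps the start-size/lifespan correlation near zero.
#' @param sep_fraction fraction of the lifespan at which the SEP occurs.
#' @param post_sep_slowdown multiplicative cycle elongation per post-SEP
#'   division.
#' @param fluor_production baseline reporter concentration (AU).
#' @param fluor_dilution delta >= 0: concentration falls as
#'   `production / (1 + delta * (fold - 1))`; 0 switches dilution off.
#' @param fluor_noise_sd measurement noise on concentration (AU).
#' @param size_noise_sd measurement noise on area (um^2).
#' @param exponential_growth if `TRUE`, area grows exponentially in time
#'   with the same initial slope g_i; default is linear-in-time growth.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cells = 119,
                             start_size_median = 17.65, start_size_sdlog = 0.18,
                             growth_rate_median = 0.6, growth_rate_sdlog = 0.35,
                             base_cycle_median = 1.5, base_cycle_sdlog = 0.2,
                             cycle_jitter_sdlog = 0.15, frame_min = 20,
                             lifespan_median = 16, lifespan_sdlog = 0.3,
                             lifespan_floor = 3,
                             lifespan_coupling = 0.2,
                             sep_fraction = 0.8, post_sep_slowdown = 1.4,
                             fluor_production = 100, fluor_dilution = 0.5,
                             fluor_noise_sd = 5, size_noise_sd = 0.5,
                             exponential_growth = FALSE) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_cells >= 1, cfg$start_size_median > 0,
            cfg$growth_rate_median > 0, cfg$base_cycle_median > 0,
            cfg$lifespan_median > 0, cfg$lifespan_coupling >= 0,
            cfg$fluor_dilution >= 0, cfg$sep_fraction > 0,
            cfg$sep_fraction <= 1, cfg$post_sep_slowdown >= 1,
            cfg$frame_min > 0, cfg$lifespan_floor >= 3)
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a synthetic cohort of cell life histories
#'
#' Draws, per cell: growth rate `g_i`, base cycle `tau_i` and starting area
#' `s_i`; a lifespan `L_i` from a discretised log-normal whose log-median
#' decreases linearly in `kappa * log(g_i*tau_i)`; an SEP at
#' `round(sep_fraction * L_i)`. Division durations equal `tau_i` with
#' multiplicative jitter, snapped to the imaging frame grid, and are
#' multiplied by `post_sep_slowdown` for each division past the SEP age —
#' the recorded SEP age is thus the last normally-paced division, i.e. the
#' elbow of the duration profile, matching the convention of [detect_sep()].
#' Area at age k is `s_i + g_i * t_k` plus noise (growth constant in time),
#' and reporter concentration is `production / (1 + delta*(fold_k - 1))`
#' plus noise. Fully deterministic for a fixed seed.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return a [life_history_dataset()] (source `"synthetic"`) carrying the
#'   per-cell ground truth retrievable with [truth_table()].
#' @export
generate_population <- function(config = synthetic_config(), seed = NULL) {
  if (!inherits(config, "synthetic_config"))
    stop("config must come from synthetic_config()", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_cells
  g <- rlnorm(n, log(config$growth_rate_median), config$growth_rate_sdlog)
  tau <- rlnorm(n, log(config$base_cycle_median), config$base_cycle_sdlog)
  s0 <- rlnorm(n, log(config$start_size_median), config$start_size_sdlog)
  # centre the coupling covariate at the population log-median of g*tau
  z <- log(g * tau) - (log(config$growth_rate_median) +
                       log(config$base_cycle_median))
  L <- round(rlnorm(n, log(config$lifespan_median) -
                       config$lifespan_coupling * z,
                    config$lifespan_sdlog))
  L <- pmax(L, config$lifespan_floor)
  sep <- pmin(pmax(round(config$sep_fraction * L), 2L), L - 1L)

  frame_h <- config$frame_min / 60
  cells <- vector("list", n)
  truth <- data.frame(cell_id = sprintf("synth_%03d", seq_len(n)),
                      growth_rate = g, base_cycle = tau, start_size = s0,
                      rls = as.integer(L), sep_age = as.integer(sep),
                      stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    k <- L[i]
    dur <- tau[i] * rlnorm(k - 1L, 0, config$cycle_jitter_sdlog)
    slow <- pmax(0L, seq_len(k - 1L) - sep[i])
    dur <- dur * config$post_sep_slowdown^slow
    dur <- pmax(round(dur / frame_h), 1) * frame_h   # snap to frame grid
    t <- c(0, cumsum(dur))
    drift <- if (config$exponential_growth)
      s0[i] * expm1((g[i] / s0[i]) * t) else g[i] * t
    s <- pmax(s0[i] + drift + rnorm(k, 0, config$size_noise_sd), 0.5)
    fold <- s / s[1]
    fl <- config$fluor_production / (1 + config$fluor_dilution * (fold - 1)) +
      rnorm(k, 0, config$fluor_noise_sd)
    fl <- pmax(fl, 0)
    cells[[i]] <- cell_life_history(truth$cell_id[i], s, t, avg_fluor = fl,
                                    death_observed = TRUE,
                                    experiment_id = "synthetic")
  }
  ds <- life_history_dataset(cells, name = "synthetic cohort",
                             source = "synthetic")
  attr(ds, "truth") <- truth
  attr(ds, "config") <- config
  ds
}

#' Ground truth of a generated cohort
#'
#' @param dataset a dataset produced by [generate_population()].
#' @return data frame with one row per cell, aligned with the dataset:
#'   `cell_id`, `growth_rate` (um^2/h), `base_cycle` (h), `start_size`
#'   (um^2), `rls`, `sep_age`.
#' @export
truth_table <- function(dataset) {
  truth <- attr(dataset, "truth")
  if (is.null(truth))
    stop("dataset carries no ground truth (not produced by generate_population)",
         call. = FALSE)
  ids <- vapply(dataset$cells, function(c) c$cell_id, character(1))
  if (!identical(truth$cell_id, ids))
    stop("ground-truth ids do not match the dataset", call. = FALSE)
  truth
}
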