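#' Measurement noise model for synthetic fluorescence data
#'
#' Maps simulated molecule counts to background-subtracted nuclear
#' fluorescence the way hourly time-lapse imaging produces it: a
#' per-cell multiplicative gain (lognormal across cells), a per-cell
#' nonzero baseline, and additive Gaussian per-frame measurement noise.
#'
#' @param baseline_mean mean pre-stimulus baseline fluorescence (a.u.).
#' @param baseline_cv cell-to-cell CV of the baseline.
#' @param additive_sd SD of per-frame additive noise (a.u.).
#' @param gain mean counts-to-fluorescence multiplier.
#' @param gain_cv cell-to-cell CV of the gain (lognormal).
#' @return An object of class \code{noise_model}.
#' @export
noise_model <- function(baseline_mean = 20, baseline_cv = 0.2,
                        additive_sd = 1.5, gain = 1, gain_cv = 0.15) {
  vals <- c(baseline_mean = baseline_mean, baseline_cv = baseline_cv,
            additive_sd = additive_sd, gain = gain, gain_cv = gain_cv)
  if (any(!is.finite(vals)) || any(vals < 0)) stop("noise parameters must be nonnegative")
  if (gain <= 0) stop("gain must be > 0")
  structure(as.list(vals), class = "noise_model")
}

#' Noise-free measurement model
#' @return A \code{noise_model} with unit gain and no baseline or noise.
#' @export
no_noise <- function() noise_model(baseline_mean = 0, baseline_cv = 0,
                                   additive_sd = 0, gain = 1, gain_cv = 0)

rlnorm_cv <- function(n, mean, cv) {
  if (mean == 0) return(rep(0, n))
  if (cv == 0) return(rep(mean, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Generate a synthetic single-cell population
#'
#' Simulates \code{n_cells} stochastic single-cell trajectories and
#' converts the protein counts to fluorescence through a [noise_model()]:
#' \code{gain_i * P + baseline_i + N(0, additive_sd)} per frame, sampled
#' hourly with two pre-stimulus frames. The latent count trajectories
#' and per-cell gain/baseline draws are retained in the metadata so
#' every extracted feature can be scored against construction.
#'
#' @param kin,adapt,protocol model and stimulus.
#' @param n_cells number of cells.
#' @param noise a [noise_model()].
#' @param seed master seed (drives both the simulator and the noise).
#' @param horizon duration after onset (h).
#' @return A [trace_matrix()]; \code{metadata$truth} holds the latent
#'   protein counts, gains and baselines.
#' @export
gen_population <- function(kin, adapt = preset_adaptation(), protocol,
                           n_cells, noise = noise_model(), seed = 1,
                           horizon = 31) {
  cfg <- stochastic_config(n_cells = n_cells, seed = seed,
                           horizon = horizon,
                           record_grid = seq(-2, horizon, by = 1))
  ens <- simulate_ensemble(kin, adapt, protocol, cfg)
  P <- ens$counts[, , "P", drop = TRUE]

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer((seed + 77003) %% .Machine$integer.max))
  gains <- rlnorm_cv(n_cells, noise$gain, noise$gain_cv)
  baselines <- rlnorm_cv(n_cells, noise$baseline_mean, noise$baseline_cv)
  eps <- matrix(stats::rnorm(length(P), 0, noise$additive_sd),
                nrow = n_cells)
  values <- P * gains + baselines + eps

  protocol <- parse_protocol(protocol)
  onsets <- protocol$segments$t_start
  trace_matrix(values, ens$time,
               stimulus_onsets = if (length(onsets)) onsets else 0,
               metadata = list(
                 seed = seed, noise = unclass(noise),
                 truth = list(protein = P, gains = gains,
                              baselines = baselines)))
}

#' Generate the full multi-condition synthetic dataset
#'
#' Emulates the study's design matrix for one gene: five constant
#' concentrations (0.1, 1, 3, 10, 20 ng/ml) on the plate platform, four
#' durations (1, 4, 8 h and constant) of 10 ng/ml on the chip platform,
#' and the two-pulse protocol. Plate and chip are given different gains
#' so the plate/chip bridging step is exercised. Mean traces come from
#' the deterministic model (\code{mean_mode = "ode"}, noiseless) or from
#' stochastic ensemble means (\code{mean_mode = "ensemble"}).
#'
#' @param kin,adapt model parameters.
#' @param seed master seed.
#' @param n_cells cells per condition (ensemble mode).
#' @param mean_mode source of the per-condition mean traces.
#' @param plate_gain,chip_gain fluorescence gain per platform.
#' @param mask_plate_12h restrict plate conditions' fit mask to the
#'   first 12 h (the convention for a gene whose late plate signal is
#'   not comparable).
#' @param horizon duration after onset (h).
#' @return List with \code{conditions} (list of [fit_condition()]),
#'   \code{two_pulse} (a \code{fit_condition}), and \code{truth}
#'   (generating parameters and gains).
#' @export
gen_condition_suite <- function(kin, adapt = preset_adaptation(), seed = 1,
                                n_cells = 200,
                                mean_mode = c("ode", "ensemble"),
                                plate_gain = 2, chip_gain = 1,
                                mask_plate_12h = FALSE, horizon = 31) {
  mean_mode <- match.arg(mean_mode)
  times <- seq(-2, horizon, by = 1)
  concs <- c(0.1, 1, 3, 10, 20)
  durs <- c(1, 4, 8)

  specs <- c(
    lapply(concs, function(cc) list(
      label = sprintf("plate_%g", cc), platform = "plate",
      protocol = parse_protocol(sprintf("constant:%g", cc), horizon))),
    lapply(durs, function(d) list(
      label = sprintf("chip_%gh", d), platform = "chip",
      protocol = parse_protocol(sprintf("pulse:0-%g:10", d), horizon))),
    list(list(label = "chip_const", platform = "chip",
              protocol = parse_protocol("constant:10", horizon))))

  mean_of <- function(protocol, idx) {
    if (mean_mode == "ode") {
      integrate_model(kin, adapt, protocol, times)$P
    } else {
      cfg <- stochastic_config(n_cells = n_cells, seed = seed + idx,
                               horizon = horizon, record_grid = times)
      colMeans(simulate_ensemble(kin, adapt, protocol, cfg)$counts[, , "P"])
    }
  }

  conditions <- lapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    gain <- if (sp$platform == "plate") plate_gain else chip_gain
    fit_condition(sp$label, sp$protocol, times,
                  mean_of(sp$protocol, i) * gain,
                  platform = sp$platform,
                  fit_mask = if (mask_plate_12h && sp$platform == "plate")
                    c(min(times), 12) else NULL)
  })

  tp_proto <- two_pulse_protocol(horizon = horizon)
  two_pulse <- fit_condition("chip_twopulse", tp_proto, times,
                             mean_of(tp_proto, length(specs) + 1) * chip_gain,
                             platform = "chip")

  list(conditions = conditions, two_pulse = two_pulse,
       truth = list(kinetics = kin, adaptation = adapt,
                    plate_gain = plate_gain, chip_gain = chip_gain,
                    seed = seed, mean_mode = mean_mode))
}
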