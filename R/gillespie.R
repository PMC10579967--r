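#' Stochastic simulation settings
#'
#' @param n_cells number of independent single-cell replicates.
#' @param seed master seed; per-cell random streams are derived from it
#'   by a counter-based scheme, so ensembles are order-independent and a
#'   given master seed is fully reproducible.
#' @param horizon total simulated duration after stimulus onset (h).
#' @param record_grid recording times (h); default hourly from two
#'   pre-stimulus frames to the horizon, mimicking time-lapse imaging.
#' @param resample_initial logical; draw each cell's integer initial
#'   state from the pre-stimulus stationary distribution (multinomial
#'   chromatin, Poisson molecule counts). If \code{FALSE} all cells
#'   start from the rounded deterministic resting state.
#' @return An object of class \code{stochastic_config}.
#' @export
stochastic_config <- function(n_cells = 1000, seed = 1, horizon = 31,
                              record_grid = NULL, resample_initial = TRUE) {
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (is.null(record_grid)) record_grid <- seq(-2, horizon, by = 1)
  if (max(record_grid) > horizon + 1e-9)
    stop("record_grid must lie within the horizon")
  structure(list(n_cells = as.integer(n_cells), seed = seed,
                 horizon = horizon, record_grid = as.numeric(record_grid),
                 resample_initial = isTRUE(resample_initial)),
            class = "stochastic_config")
}

seed_parts <- function(seed) {
  s <- as.numeric(seed) %% 2^53
  c(lo = s %% 2^32, hi = s %/% 2^32)
}

#' Single-cell direct-Gillespie run
#'
#' Exact direct-method simulation of the chromatin/expression reaction
#' network in integer molecule counts. Reactions: chromatin opening
#' (\code{k1 TF C}), closing (\code{k2 OU}), initiation (\code{k3 TF OU}),
#' de-initiation (\code{k4 OI}); mRNA synthesis/decay (\code{k5 OI},
#' \code{deltaM M}); protein synthesis/decay (\code{k6 M},
#' \code{deltaP P}); plus regulator mRNA/protein synthesis and decay
#' when adaptation is enabled. The TF activity is re-evaluated at every
#' reaction event from the current stimulus level and regulator count,
#' and propensities are refreshed at every stimulus switch time.
#'
#' @param kin a [gene_kinetics()] object.
#' @param adapt an [adaptation_params()] object; \code{reg_thr} is in
#'   molecule units, matching the count-scaled model.
#' @param protocol a \code{stimulus_protocol} or shorthand string.
#' @param seed integer seed for this run's random stream.
#' @param record_grid recording times (h).
#' @param init integer initial state; default the rounded resting state.
#' @return Data frame of integer copy numbers on the recording grid.
#' @export
gillespie_run <- function(kin, adapt = no_adaptation(), protocol, seed,
                          record_grid = seq(-2, 31, by = 1), init = NULL) {
  protocol <- parse_protocol(protocol)
  if (is.null(init)) init <- round(equilibrate(kin, adapt, 0))
  sw <- gillespie_switch_tables(protocol, record_grid)
  sp <- seed_parts(seed)
  m <- .gillespie_core(kinetics_vector(kin), adaptation_vector(adapt),
                       sw$times, sw$ifng, record_grid,
                       as.numeric(init[state_names()]), sp["lo"], sp["hi"],
                       FALSE)
  data.frame(time = record_grid, m, check.names = FALSE)
}

kinetics_vector <- function(kin) {
  unlist(kin[c("k1", "k2", "k3", "k4", "k5", "k6",
               "deltaM", "deltaP", "alpha", "Kd")])
}

adaptation_vector <- function(adapt) {
  c(enabled = as.numeric(adapt$enabled),
    unlist(adapt[c("a_regM", "a_regP", "delta_regM", "delta_regP",
                   "reg_thr", "c1", "c2")]))
}

gillespie_switch_tables <- function(protocol, record_grid) {
  t0 <- min(record_grid)
  t_end <- max(record_grid) + 1e-9
  bounds <- c(protocol_switch_times(protocol, t0, t_end), t_end)
  prev <- c(t0, bounds[-length(bounds)])
  list(times = bounds, ifng = ifng_at(protocol, (prev + bounds) / 2))
}

#' Simulate an ensemble of single cells
#'
#' Runs \code{cfg$n_cells} independent [gillespie_run()] replicates and
#' collects all seven species on the recording grid. Each cell's initial
#' state is drawn from the pre-stimulus stationary distribution
#' (multinomial over chromatin states, Poisson molecule counts) unless
#' \code{cfg$resample_initial} is off.
#'
#' @param kin,adapt,protocol model and stimulus, as in [gillespie_run()].
#' @param cfg a [stochastic_config()].
#' @return An object of class \code{ensemble_sim}: list with \code{time},
#'   \code{counts} (cells x timepoints x species array), \code{protocol},
#'   \code{seed}, and \code{cell_seeds}.
#' @export
simulate_ensemble <- function(kin, adapt = no_adaptation(), protocol,
                              cfg = stochastic_config()) {
  protocol <- parse_protocol(protocol)
  record <- cfg$record_grid
  n <- cfg$n_cells
  eq <- equilibrate(kin, adapt, 0)
  init <- as.numeric(eq[state_names()])

  sw <- gillespie_switch_tables(protocol, record)
  kv <- kinetics_vector(kin); av <- adaptation_vector(adapt)
  sp <- seed_parts(cfg$seed)
  counts <- array(0L, dim = c(n, length(record), 7),
                  dimnames = list(NULL, NULL, state_names()))
  cell_seeds <- matrix(0, nrow = n, ncol = 2)
  for (i in seq_len(n)) {
    cs <- .derive_stream_seed(sp["lo"], sp["hi"], i)
    cell_seeds[i, ] <- cs
    m <- .gillespie_core(kv, av, sw$times, sw$ifng, record, init,
                         cs[1], cs[2], cfg$resample_initial)
    counts[i, , ] <- m
  }
  structure(list(time = record, counts = counts, protocol = protocol,
                 seed = cfg$seed, cell_seeds = cell_seeds),
            class = "ensemble_sim")
}

#' @export
print.ensemble_sim <- function(x, ...) {
  cat(sprintf("<ensemble_sim> %d cells x %d timepoints (master seed %g)\n",
              dim(x$counts)[1], dim(x$counts)[2], x$seed))
  invisible(x)
}

#' Extract one species from an ensemble as a trace matrix
#'
#' @param ens an \code{ensemble_sim}.
#' @param species one of \code{"C","OU","OI","M","P","regM","regP"}.
#' @return A [trace_matrix()] of integer counts.
#' @export
as_trace_matrix <- function(ens, species = "P") {
  onsets <- ens$protocol$segments$t_start
  trace_matrix(ens$counts[, , species, drop = TRUE], ens$time,
               stimulus_onsets = if (length(onsets)) onsets else 0,
               metadata = list(species = species, seed = ens$seed))
}

#' Ensemble summary statistics
#'
#' Per-timepoint mean, SD and SEM across cells for one species.
#'
#' @param ens an \code{ensemble_sim}.
#' @param species species name.
#' @return Data frame with columns \code{time}, \code{mean}, \code{sd},
#'   \code{sem}.
#' @export
ensemble_stats <- function(ens, species = "P") {
  v <- ens$counts[, , species, drop = TRUE]
  n <- nrow(v)
  m <- colMeans(v)
  s <- apply(v, 2, stats::sd)
  data.frame(time = ens$time, mean = m, sd = s, sem = s / sqrt(n))
}

#' Two-pulse stochastic experiment
#'
#' Simulates an ensemble under the repeated-stimulation protocol (two
#' 4-h pulses of 10 ng/ml with a 10-h off period by default) and
#' measures, independently for each pulse, the protein amplitude change
#' in the window from pulse onset to 9 h after the pulse end, then
#' classifies each cell as responding to the first, second, both or
#' neither pulse.
#'
#' @param kin,adapt model parameters.
#' @param cfg a [stochastic_config()].
#' @param protocol the two-pulse protocol; default [two_pulse_protocol()].
#' @param threshold responder amplitude threshold (molecules); default
#'   from [responder_threshold()] on the pre-stimulus frames.
#' @return List with the \code{ensemble_sim}, the protein
#'   \code{trace_matrix}, per-cell \code{amplitudes} (cells x 2),
#'   \code{classes}, the 2x2 \code{contingency} table, and the
#'   conditional response probabilities \code{p_resp2_given_resp1} and
#'   \code{p_resp2_given_nonresp1}.
#' @export
two_pulse_experiment <- function(kin, adapt, cfg = stochastic_config(),
                                 protocol = two_pulse_protocol(),
                                 threshold = NULL) {
  ens <- simulate_ensemble(kin, adapt, protocol, cfg)
  tm <- as_trace_matrix(ens, "P")
  seg <- protocol$segments
  amp <- sapply(seq_len(nrow(seg)), function(p)
    apply(tm$values, 1, function(tr)
      pulse_amplitude_window(tr, tm$time, pulse_onset = seg$t_start[p],
                             pulse_end = seg$t_end[p], mode = "simulation")))
  if (is.null(threshold))
    threshold <- responder_threshold(tm)
  cls <- classify_responders(amp, threshold)
  c(list(ensemble = ens, traces = tm, amplitudes = amp,
         threshold = threshold), cls)
}
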