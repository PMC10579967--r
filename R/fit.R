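#' Rescale a mean trace to a fixed peak value
#'
#' Pre-fitting normalization: fluorescence units differ between
#' reporters, so each gene's mean expression data are rescaled so the
#' mean trace peaks at a common target (default 40, the model's protein
#' normalization scale).
#'
#' @param trace numeric mean trace with a strictly positive maximum.
#' @param target peak value after rescaling.
#' @return List with \code{trace} (rescaled) and \code{factor}
#'   (\code{target / max(trace)}).
#' @export
rescale_to_peak <- function(trace, target = 40) {
  m <- max(trace)
  if (!is.finite(m) || m <= 0) stop("trace maximum must be > 0")
  f <- target / m
  list(trace = trace * f, factor = f)
}

#' Plate-to-chip fluorescence scaling factor
#'
#' Plate and microfluidic-chip images have different fluorescence
#' amplitudes. The two platforms are bridged through the matched
#' condition (10 ng/ml constant stimulus run on both): the factor is the
#' plate maximum divided by the chip maximum, and all chip traces of
#' that gene are multiplied by it.
#'
#' @param plate_max maximum mean fluorescence of the 10 ng/ml plate
#'   condition.
#' @param chip_max maximum mean fluorescence of the 10 ng/ml constant
#'   chip condition.
#' @return Multiplier to apply to chip traces.
#' @export
chip_scale_factor <- function(plate_max, chip_max) {
  if (!is.finite(plate_max) || !is.finite(chip_max) ||
      plate_max <= 0 || chip_max <= 0)
    stop("both maxima must be > 0")
  plate_max / chip_max
}

#' Reference plate-to-chip scaling factors
#'
#' The published factors for the three reporter lines, kept as reference
#' constants for working with the original data conventions (they are a
#' property of that imaging setup, not recomputable from simulations).
#'
#' @return Named numeric vector for IRF1, CXCL10 and CXCL9.
#' @export
reference_scale_factors <- function() {
  c(IRF1 = 1.7757, CXCL10 = 3.1105, CXCL9 = 3.3009)
}

#' A single fitting condition
#'
#' One stimulation condition's population-mean trace together with its
#' protocol, platform of origin and an optional fit mask restricting
#' which times enter the loss (e.g. only the first 12 h of plate data
#' for a gene whose late plate signal is unreliable).
#'
#' @param label condition name.
#' @param protocol \code{stimulus_protocol} or shorthand string.
#' @param time observation times (h).
#' @param value mean trace values.
#' @param platform \code{"plate"} or \code{"chip"}.
#' @param fit_mask \code{NULL} (use all points) or numeric
#'   \code{c(from, to)} interval in hours; points outside contribute
#'   nothing to the loss.
#' @return An object of class \code{fit_condition}.
#' @export
fit_condition <- function(label, protocol, time, value,
                          platform = c("plate", "chip"), fit_mask = NULL) {
  platform <- match.arg(platform)
  protocol <- parse_protocol(protocol)
  if (length(time) != length(value)) stop("time/value length mismatch")
  if (!is.null(fit_mask)) {
    if (length(fit_mask) != 2 || fit_mask[2] < fit_mask[1])
      stop("fit_mask must be a c(from, to) interval")
    if (fit_mask[2] < min(time) || fit_mask[1] > max(time))
      stop("fit_mask lies outside the observed time range")
  }
  structure(list(label = label, protocol = protocol, time = as.numeric(time),
                 value = as.numeric(value), platform = platform,
                 fit_mask = fit_mask),
            class = "fit_condition")
}

mask_weights <- function(cond) {
  if (is.null(cond$fit_mask)) return(rep(1, length(cond$time)))
  as.numeric(cond$time >= cond$fit_mask[1] & cond$time <= cond$fit_mask[2])
}

#' Normalize a multi-condition dataset for fitting
#'
#' Applies the two pre-fitting data transformations: (1) chip traces are
#' multiplied by the plate/chip scaling factor computed from the matched
#' 10 ng/ml conditions; (2) all traces are rescaled together so the
#' gene's overall mean-expression peak equals \code{target}.
#'
#' @param conditions list of [fit_condition()] objects.
#' @param plate_ref,chip_ref labels of the matched plate and chip
#'   conditions (both 10 ng/ml); if either is absent no chip scaling is
#'   applied.
#' @param target common peak after rescaling.
#' @return List with \code{conditions} (transformed), \code{chip_factor}
#'   and \code{rescale_factor}.
#' @export
prepare_dataset <- function(conditions, plate_ref = NULL, chip_ref = NULL,
                            target = 40) {
  labels <- vapply(conditions, `[[`, character(1), "label")
  chip_factor <- 1
  if (!is.null(plate_ref) && !is.null(chip_ref) &&
      plate_ref %in% labels && chip_ref %in% labels) {
    pm <- max(conditions[[match(plate_ref, labels)]]$value)
    cm <- max(conditions[[match(chip_ref, labels)]]$value)
    chip_factor <- chip_scale_factor(pm, cm)
    conditions <- lapply(conditions, function(cond) {
      if (cond$platform == "chip") cond$value <- cond$value * chip_factor
      cond
    })
  }
  overall_max <- max(vapply(conditions, function(cond) max(cond$value),
                            numeric(1)))
  rf <- rescale_to_peak(c(overall_max), target)$factor
  conditions <- lapply(conditions, function(cond) {
    cond$value <- cond$value * rf
    cond
  })
  list(conditions = conditions, chip_factor = chip_factor,
       rescale_factor = rf)
}

#' Sum-of-squares loss of the model against a dataset
#'
#' Unweighted sum over conditions and mask-included timepoints of the
#' squared difference between the model protein trajectory and the mean
#' trace. Integration failures yield a large finite penalty so a running
#' optimizer survives pathological parameter proposals.
#'
#' @param kin,adapt model parameters.
#' @param conditions list of [fit_condition()] (already normalized).
#' @param rtol,atol solver tolerances used inside the loss.
#' @return Scalar loss (>= 0).
#' @export
model_loss <- function(kin, adapt, conditions, rtol = 1e-6, atol = 1e-8) {
  tryCatch({
    init <- equilibrate(kin, adapt, 0)
    total <- 0
    for (cond in conditions) {
      sol <- integrate_model(kin, adapt, cond$protocol, cond$time,
                             init = init, rtol = rtol, atol = atol)
      w <- mask_weights(cond)
      total <- total + sum(w * (sol$P - cond$value)^2)
    }
    total
  }, error = function(e) 1e10)
}

#' Fit the model to multi-condition mean traces
#'
#' Bounded derivative-free simplex search (Nelder-Mead through a
#' sine-transform reparameterization of box constraints, the classic
#' \code{fminsearchbnd} construction) over a chosen subset of the
#' kinetic parameters, in log10 space, with optional seeded multi-start
#' around a log-uniform sample of the box.
#'
#' @param conditions list of normalized [fit_condition()] objects.
#' @param kin_init starting [gene_kinetics()]; also supplies the fixed
#'   values of parameters not in \code{free}.
#' @param adapt [adaptation_params()] (held fixed).
#' @param free character vector of parameter names to optimize.
#' @param lower,upper named bounds for the free parameters (defaults:
#'   rates in \code{[1e-4, 1e3]} per hour).
#' @param n_starts number of starts (the first is \code{kin_init}).
#' @param maxit Nelder-Mead iteration cap per start.
#' @param seed seed for the multi-start sample.
#' @return An object of class \code{fit_result}: list with
#'   \code{kinetics}, \code{adaptation}, \code{loss}, \code{n_evals},
#'   \code{converged}, \code{bounds}, \code{starts}.
#' @export
fit_kinetics <- function(conditions, kin_init, adapt = no_adaptation(),
                         free = c("k1", "k2", "k3", "k4", "k5", "k6",
                                  "deltaM", "deltaP"),
                         lower = NULL, upper = NULL,
                         n_starts = 1, maxit = 600, seed = 1) {
  def_lo <- stats::setNames(rep(1e-4, length(free)), free)
  def_hi <- stats::setNames(rep(1e3, length(free)), free)
  if (!is.null(lower)) def_lo[names(lower)] <- lower
  if (!is.null(upper)) def_hi[names(upper)] <- upper
  lo <- log10(def_lo); hi <- log10(def_hi)

  to_kin <- function(logp) {
    k <- kin_init
    for (nm in free) k[[nm]] <- 10^logp[[nm]]
    class(k) <- "gene_kinetics"
    k
  }
  # fminsearchbnd-style transform: y unbounded <-> x in [lo, hi]
  from_y <- function(y) lo + (hi - lo) * (sin(y) + 1) / 2
  to_y <- function(x) asin(pmin(1, pmax(-1, 2 * (x - lo) / (hi - lo) - 1)))

  n_evals <- 0L
  obj <- function(y) {
    n_evals <<- n_evals + 1L
    logp <- stats::setNames(from_y(y), free)
    model_loss(to_kin(logp), adapt, conditions)
  }

  start0 <- log10(pmin(def_hi, pmax(def_lo,
    vapply(free, function(nm) kin_init[[nm]], numeric(1)))))
  starts <- list(start0)
  if (n_starts > 1) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(as.integer(seed))
    for (i in seq_len(n_starts - 1))
      starts[[i + 1]] <- stats::setNames(stats::runif(length(free), lo, hi),
                                         free)
  }

  best <- NULL
  for (st in starts) {
    res <- stats::optim(to_y(st), obj, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-10))
    if (is.null(best) || res$value < best$value) best <- res
  }
  logp <- stats::setNames(from_y(best$par), free)
  structure(list(kinetics = to_kin(logp),
                 adaptation = adapt,
                 loss = best$value,
                 n_evals = n_evals,
                 converged = best$convergence == 0,
                 bounds = list(lower = def_lo, upper = def_hi),
                 starts = starts),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> loss = %.6g (%d evaluations, %s)\n", x$loss,
              x$n_evals, if (x$converged) "converged" else "iteration cap"))
  print(x$kinetics)
  invisible(x)
}
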