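#' Maximum induction amplitude of a single-cell trace
#'
#' Maximum over the first 24 h after stimulus addition minus the mean of
#' the first two pre-stimulus frames (taken as basal expression plus
#' noise, unaffected by the stimulus). The value is not clamped: a flat
#' noisy trace can give a small negative amplitude.
#'
#' @param trace numeric vector of one cell's values.
#' @param time matching time grid (h).
#' @param onset stimulus onset (h).
#' @param window length of the post-onset search window (h).
#' @return Amplitude in trace units; warns if the window is truncated.
#' @export
max_amplitude <- function(trace, time, onset = 0, window = 24) {
  pre <- which(time < onset)
  if (length(pre) < 2) stop("need at least 2 pre-onset frames")
  base <- mean(trace[pre[1:2]])
  post <- time > onset & time <= onset + window
  if (max(time) < onset + window - 1e-9)
    warning("post-onset coverage shorter than the ", window, " h window")
  if (!any(post)) stop("no post-onset frames in the window")
  max(trace[post]) - base
}

#' Lag time to expression onset
#'
#' First post-stimulus time at which the trace reaches 1.5 times its
#' baseline, where the baseline is the mean of the two frames before
#' stimulus addition and the frame right at addition. Reported relative
#' to the onset; \code{NA} when the threshold is never reached.
#'
#' @inheritParams max_amplitude
#' @param factor threshold multiple of baseline (default 1.5). The
#'   comparison is inclusive (reaching the level counts).
#' @return Lag (h) or \code{NA_real_} if not detected.
#' @export
lag_time <- function(trace, time, onset = 0, factor = 1.5) {
  pre <- which(time < onset)
  if (length(pre) < 2) stop("need at least 2 pre-onset frames")
  i_on <- which(time >= onset)[1]
  if (is.na(i_on)) stop("no frame at or after the onset")
  base <- mean(c(trace[pre[1:2]], trace[i_on]))
  if (!is.finite(base) || base <= 0)
    stop("baseline must be positive for the ratio threshold")
  post <- which(time > onset)
  hit <- post[trace[post] >= factor * base]
  if (!length(hit)) return(NA_real_)
  time[hit[1]] - onset
}

#' Width at half-maximum amplitude
#'
#' Duration of the contiguous interval around the peak during which the
#' trace stays at or above baseline plus half the peak-minus-baseline
#' amplitude, with linear interpolation at the two crossings. If the
#' trace never descends again within the window the width is
#' right-censored at the window end (attribute \code{censored}).
#' Intended for genes whose reporter tracks endogenous decay.
#'
#' @inheritParams max_amplitude
#' @return Width (h), with logical attribute \code{censored}.
#' @export
half_max_width <- function(trace, time, onset = 0, window = 24) {
  pre <- which(time < onset)
  if (length(pre) < 2) stop("need at least 2 pre-onset frames")
  base <- mean(trace[pre[1:2]])
  win <- which(time > onset & time <= onset + window)
  if (!length(win)) stop("no frames in the post-onset window")
  ipk <- win[which.max(trace[win])]
  half <- base + 0.5 * (trace[ipk] - base)
  if (trace[ipk] <= base) stop("trace has no peak above baseline")

  cross_left <- function() {
    i <- ipk
    while (i > 1 && trace[i - 1] >= half) i <- i - 1
    if (i == 1 || trace[i - 1] >= half) return(time[i])
    # interpolate between i-1 (below) and i (above)
    t1 <- time[i - 1]; t2 <- time[i]
    t1 + (half - trace[i - 1]) / (trace[i] - trace[i - 1]) * (t2 - t1)
  }
  cross_right <- function() {
    n <- length(trace); last <- max(win)
    i <- ipk
    while (i < last && trace[i + 1] >= half) i <- i + 1
    if (i == last) return(structure(time[i], censored = TRUE))
    t1 <- time[i]; t2 <- time[i + 1]
    t1 + (half - trace[i]) / (trace[i + 1] - trace[i]) * (t2 - t1)
  }
  tl <- cross_left()
  tr <- cross_right()
  structure(as.numeric(tr) - as.numeric(tl),
            censored = isTRUE(attr(tr, "censored")))
}

#' Tanh fit of the initial induction rise
#'
#' Fits \code{y = tanh(a x + b) c + d} by nonlinear least squares to the
#' first \code{window} hours after stimulus addition (x measured from
#' the onset) and reports the derived kinetic features: slope
#' \code{a * c} and pulse amplitude \code{2 * c}.
#'
#' @inheritParams max_amplitude
#' @param window fit window after onset (h), default 13.
#' @return Named list \code{a, b, c, d, slope, pulse_amplitude,
#'   residual, converged}. Non-convergence returns \code{NA} features
#'   with \code{converged = FALSE}.
#' @export
tanh_fit <- function(trace, time, onset = 0, window = 13) {
  sel <- time >= onset & time <= onset + window
  x <- time[sel] - onset
  y <- trace[sel]
  if (length(x) < 5) stop("need at least 5 points in the fit window")
  rng <- max(y) - min(y)
  if (rng < .Machine$double.eps^0.5 * max(1, abs(mean(y)))) {
    # flat trace: no rise to fit, amplitude and slope are zero
    return(list(a = 0, b = 0, c = 0, d = mean(y), slope = 0,
                pulse_amplitude = 0, residual = 0, converged = TRUE))
  }
  starts <- list(
    list(a = 0.4, b = -2, c = max(rng / 2, 1e-6), d = min(y) + rng / 2),
    list(a = 0.15, b = -1, c = max(rng / 2, 1e-6), d = mean(y)),
    list(a = 1, b = -4, c = max(rng, 1e-6) , d = min(y)))
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ tanh(a * x + b) * c + d,
                        start = st,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      p <- as.list(stats::coef(fit))
      return(list(a = p$a, b = p$b, c = p$c, d = p$d,
                  slope = p$a * p$c, pulse_amplitude = 2 * p$c,
                  residual = sqrt(mean(stats::resid(fit)^2)),
                  converged = TRUE))
    }
  }
  list(a = NA_real_, b = NA_real_, c = NA_real_, d = NA_real_,
       slope = NA_real_, pulse_amplitude = NA_real_,
       residual = NA_real_, converged = FALSE)
}

#' Coefficient of variation across cells at each timepoint
#'
#' CV = sample SD divided by mean of the values of all cells at each
#' timepoint. Timepoints with (near-)zero mean are returned as \code{NA}.
#'
#' @param tm a [trace_matrix()] (or plain cells x timepoints matrix).
#' @return Data frame with columns \code{time} and \code{cv}.
#' @export
cv_over_time <- function(tm) {
  v <- if (inherits(tm, "trace_matrix")) tm$values else as.matrix(tm)
  time <- if (inherits(tm, "trace_matrix")) tm$time else seq_len(ncol(v))
  if (nrow(v) < 2) stop("need at least 2 cells")
  m <- colMeans(v)
  s <- apply(v, 2, stats::sd)
  cv <- ifelse(abs(m) < .Machine$double.eps^0.5, NA_real_, s / m)
  data.frame(time = time, cv = cv)
}

#' Coefficient of variation of a per-cell feature
#' @param x numeric vector of one feature across cells.
#' @return SD(x)/mean(x) (sample SD); \code{NA} for zero mean.
#' @export
feature_cv <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  if (abs(m) < .Machine$double.eps^0.5) return(NA_real_)
  stats::sd(x) / m
}

#' Per-pulse amplitude in an independent measurement window
#'
#' Maximum within the pulse window minus the value at pulse onset, so
#' each pulse of a repeated-stimulation experiment is measured for
#' itself and earlier pulses do not contribute. Two window conventions
#' are supported: \code{"experimental"} (onset to 13 h after onset:
#' 4 h of stimulus plus 9 h off) and \code{"simulation"} (onset to 9 h
#' after the pulse end).
#'
#' @param trace,time one cell's trace and time grid.
#' @param pulse_onset pulse onset time (h).
#' @param pulse_end pulse end time (h); needed for the simulation window.
#' @param mode window convention.
#' @return Amplitude (>= 0 by construction: the onset point is in the
#'   window). Attribute \code{truncated} flags a window extending past
#'   the data.
#' @export
pulse_amplitude_window <- function(trace, time, pulse_onset,
                                   pulse_end = pulse_onset + 4,
                                   mode = c("experimental", "simulation")) {
  mode <- match.arg(mode)
  w_end <- if (mode == "experimental") pulse_onset + 13 else pulse_end + 9
  truncated <- w_end > max(time) + 1e-9
  sel <- time >= pulse_onset & time <= w_end
  if (!any(sel)) stop("pulse window contains no frames")
  i_on <- which(sel)[1]
  structure(max(trace[sel]) - trace[i_on], truncated = truncated)
}

#' Amplitude threshold separating responders from nonresponders
#'
#' Default detection criterion: three sample SDs of the pre-stimulus
#' frames. Uses each cell's own pre-stimulus SD when informative, and
#' falls back to the SD pooled over all cells' pre-stimulus frames when
#' the per-cell estimate is degenerate (fewer than 3 frames or zero
#' spread, as for low-count data). A floor of one count/fluorescence
#' unit keeps the threshold strictly positive for all-quiet baselines.
#'
#' @param tm a [trace_matrix()].
#' @param k multiple of the baseline SD (default 3).
#' @return Scalar threshold in trace units.
#' @export
responder_threshold <- function(tm, k = 3) {
  onset <- min(tm$stimulus_onsets)
  pre <- tm$time < onset
  if (!any(pre)) stop("no pre-stimulus frames")
  percell <- apply(tm$values[, pre, drop = FALSE], 1, stats::sd)
  pooled <- stats::sd(as.vector(tm$values[, pre, drop = FALSE]))
  s <- if (sum(pre) >= 3 && stats::median(percell) > 0)
    stats::median(percell) else pooled
  k * max(s, 1 / k, na.rm = TRUE)
}

#' Classify cells by pulse response
#'
#' Given per-cell amplitudes for two stimulation pulses, labels each
#' cell as responding to the first (+/-), second (-/+), both (+/+) or
#' neither (-/-) pulse, and summarizes the population: the 2x2
#' contingency table and the conditional probabilities of responding to
#' the second pulse given the first-pulse status.
#'
#' @param amplitudes cells x 2 matrix of per-pulse amplitudes.
#' @param threshold strictly positive amplitude threshold; a cell
#'   responds to a pulse when its amplitude exceeds the threshold.
#' @return List with \code{classes} (factor), \code{contingency},
#'   \code{p_resp2_given_resp1}, \code{p_resp2_given_nonresp1}.
#' @export
classify_responders <- function(amplitudes, threshold) {
  amplitudes <- as.matrix(amplitudes)
  if (ncol(amplitudes) != 2) stop("expected two pulse amplitudes per cell")
  if (!is.finite(threshold) || threshold <= 0)
    stop("threshold must be > 0")
  r1 <- amplitudes[, 1] > threshold
  r2 <- amplitudes[, 2] > threshold
  lab <- paste0(ifelse(r1, "+", "-"), "/", ifelse(r2, "+", "-"))
  classes <- factor(lab, levels = c("+/+", "+/-", "-/+", "-/-"))
  contingency <- table(pulse1 = factor(r1, c(TRUE, FALSE)),
                       pulse2 = factor(r2, c(TRUE, FALSE)))
  list(classes = classes,
       contingency = contingency,
       p_resp2_given_resp1 = if (any(r1)) mean(r2[r1]) else NA_real_,
       p_resp2_given_nonresp1 = if (any(!r1)) mean(r2[!r1]) else NA_real_)
}

#' Pearson correlation between two per-cell features
#'
#' @param featA,featB numeric vectors (paired per cell). Pairs with a
#'   missing value in either feature are dropped.
#' @return List with \code{r} and \code{n} (pairs used); \code{r} is
#'   \code{NA} when either feature has zero variance.
#' @export
feature_correlation <- function(featA, featB) {
  ok <- is.finite(featA) & is.finite(featB)
  n <- sum(ok)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(featA[ok]) == 0 || stats::sd(featB[ok]) == 0)
    return(list(r = NA_real_, n = n))
  list(r = stats::cor(featA[ok], featB[ok]), n = n)
}

#' Extract the standard per-cell feature table
#'
#' Applies the single-trace statistics to every row of a trace matrix:
#' baseline, maximum amplitude, lag time, half-max width (optional) and
#' the tanh induction fit (optional, for slope and pulse amplitude).
#'
#' @param tm a [trace_matrix()].
#' @param onset stimulus onset (h); default the first recorded onset.
#' @param width include the half-max width (IRF1-style reporters only).
#' @param tanh_features include the tanh fit slope/pulse amplitude.
#' @return Data frame, one row per cell.
#' @export
extract_features <- function(tm, onset = NULL, width = FALSE,
                             tanh_features = FALSE) {
  if (is.null(onset)) onset <- min(tm$stimulus_onsets)
  v <- tm$values; time <- tm$time
  pre <- which(time < onset)
  out <- data.frame(
    cell = seq_len(nrow(v)),
    baseline = apply(v[, pre[1:2], drop = FALSE], 1, mean),
    max_amplitude = apply(v, 1, max_amplitude, time = time, onset = onset),
    lag_time = vapply(seq_len(nrow(v)), function(i)
      tryCatch(lag_time(v[i, ], time, onset),
               error = function(e) NA_real_), numeric(1)))
  if (width) {
    out$width <- vapply(seq_len(nrow(v)), function(i) {
      w <- tryCatch(half_max_width(v[i, ], time, onset),
                    error = function(e) NA_real_)
      as.numeric(w)
    }, numeric(1))
  }
  if (tanh_features) {
    tf <- lapply(seq_len(nrow(v)), function(i)
      tanh_fit(v[i, ], time, onset))
    out$slope <- vapply(tf, `[[`, numeric(1), "slope")
    out$pulse_amplitude <- vapply(tf, `[[`, numeric(1), "pulse_amplitude")
  }
  out
}
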