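#' Piecewise-constant IFNg stimulation protocol
#'
#' A protocol is an ordered set of non-overlapping segments
#' \code{(t_start, t_end, ifng)} on the experiment time axis (hours;
#' time zero is stimulus onset). The IFNg concentration at any time is
#' the segment value, or 0 outside all segments, so constant, single
#' pulse, repeated pulse and concentration-series designs are all the
#' same object.
#'
#' @param segments data frame with columns \code{t_start}, \code{t_end}
#'   (h) and \code{ifng} (ng/ml); may have zero rows (no stimulus).
#' @param t0 stimulus onset time defining experiment time zero (h).
#' @param horizon total simulated duration after time zero (h).
#' @return An object of class \code{stimulus_protocol}.
#' @examples
#' stimulus_protocol(data.frame(t_start = 0, t_end = 4, ifng = 10), horizon = 31)
#' parse_protocol("twopulse:0-4,14-18:10")
#' @export
stimulus_protocol <- function(segments, t0 = 0, horizon = 31) {
  segments <- as.data.frame(segments)
  if (nrow(segments) == 0)
    segments <- data.frame(t_start = numeric(0), t_end = numeric(0),
                           ifng = numeric(0))
  stopifnot(all(c("t_start", "t_end", "ifng") %in% names(segments)))
  segments <- segments[order(segments$t_start), , drop = FALSE]
  rownames(segments) <- NULL
  if (any(segments$ifng < 0)) stop("ifng must be >= 0")
  if (any(segments$t_end <= segments$t_start))
    stop("each segment needs t_end > t_start")
  if (nrow(segments) > 1 &&
      any(segments$t_start[-1] < segments$t_end[-nrow(segments)] - 1e-12))
    stop("segments must not overlap")
  if (any(segments$t_end > horizon + 1e-9))
    stop("segments must lie within the horizon")
  structure(list(segments = segments, t0 = t0, horizon = horizon),
            class = "stimulus_protocol")
}

#' Parse a protocol shorthand string
#'
#' Understood forms: \code{"constant:10"} (10 ng/ml from time zero to
#' the horizon), \code{"pulse:0-4:10"} (one pulse), and
#' \code{"twopulse:0-4,14-18:10"} (any comma-separated list of windows
#' at one concentration).
#'
#' @param spec shorthand string, or an existing \code{stimulus_protocol}
#'   (returned unchanged).
#' @param horizon total duration (h).
#' @return A \code{stimulus_protocol}.
#' @export
parse_protocol <- function(spec, horizon = 31) {
  if (inherits(spec, "stimulus_protocol")) return(spec)
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  kind <- parts[1]
  if (kind == "constant") {
    conc <- as.numeric(parts[2])
    return(stimulus_protocol(data.frame(t_start = 0, t_end = horizon,
                                        ifng = conc), horizon = horizon))
  }
  if (kind %in% c("pulse", "twopulse")) {
    wins <- strsplit(parts[2], ",", fixed = TRUE)[[1]]
    conc <- as.numeric(parts[3])
    seg <- do.call(rbind, lapply(wins, function(w) {
      ab <- as.numeric(strsplit(w, "-", fixed = TRUE)[[1]])
      data.frame(t_start = ab[1], t_end = ab[2], ifng = conc)
    }))
    return(stimulus_protocol(seg, horizon = horizon))
  }
  stop("unrecognized protocol shorthand: ", spec)
}

#' IFNg concentration at given times
#'
#' @param protocol a \code{stimulus_protocol}.
#' @param t numeric vector of times (h). Segment start times are
#'   inclusive, end times exclusive.
#' @return ng/ml at each time (0 outside all segments).
#' @export
ifng_at <- function(protocol, t) {
  seg <- protocol$segments
  out <- numeric(length(t))
  for (i in seq_len(nrow(seg))) {
    inside <- t >= seg$t_start[i] & t < seg$t_end[i]
    out[inside] <- seg$ifng[i]
  }
  out
}

#' Times at which the stimulus concentration switches
#'
#' @param protocol a \code{stimulus_protocol}.
#' @param from,to clip the switch list to this observation window (h).
#' @return Sorted vector of switch times strictly inside \code{(from, to)}.
#' @export
protocol_switch_times <- function(protocol, from = -Inf, to = Inf) {
  s <- sort(unique(c(protocol$segments$t_start, protocol$segments$t_end)))
  s[s > from + 1e-12 & s < to - 1e-12]
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf("<stimulus_protocol> horizon %g h, %d segment(s)\n",
              x$horizon, nrow(x$segments)))
  for (i in seq_len(nrow(x$segments)))
    cat(sprintf("  [%g, %g) h : %g ng/ml\n", x$segments$t_start[i],
                x$segments$t_end[i], x$segments$ifng[i]))
  invisible(x)
}

#' Two-pulse stimulation protocol
#'
#' The repeated-stimulation design: two pulses of equal concentration and
#' duration separated by an off interval long enough for the upstream
#' signal to recover from adaptation. Defaults: two 4-h pulses of
#' 10 ng/ml with a 10-h off period.
#'
#' @param conc pulse concentration (ng/ml).
#' @param pulse_len pulse duration (h).
#' @param gap off interval between pulses (h).
#' @param horizon total duration (h).
#' @return A \code{stimulus_protocol}.
#' @export
two_pulse_protocol <- function(conc = 10, pulse_len = 4, gap = 10,
                               horizon = 31) {
  stimulus_protocol(data.frame(
    t_start = c(0, pulse_len + gap),
    t_end = c(pulse_len, 2 * pulse_len + gap),
    ifng = conc), horizon = horizon)
}
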