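#' Integrate the deterministic model over a stimulation protocol
#'
#' Solves the seven-species ODE system with \code{deSolve::lsoda},
#' restarting the solver at every protocol switch time so the
#' piecewise-constant stimulus is handled exactly. Times may extend
#' before stimulus onset (pre-stimulus frames); the initial condition
#' defaults to the resting steady state at zero IFNg.
#'
#' @param kin a [gene_kinetics()] object.
#' @param adapt an [adaptation_params()] object.
#' @param protocol a \code{stimulus_protocol} or shorthand string
#'   understood by [parse_protocol()].
#' @param times sorted output time grid (h).
#' @param init initial state (named vector); default [equilibrate()] at
#'   basal stimulus.
#' @param rtol,atol solver tolerances.
#' @return A data frame with columns \code{time}, \code{C}, \code{OU},
#'   \code{OI}, \code{M}, \code{P}, \code{regM}, \code{regP}.
#' @examples
#' kin <- preset_kinetics("IRF1")
#' sol <- integrate_model(kin, preset_adaptation(), "constant:10", 0:31)
#' @export
integrate_model <- function(kin, adapt = no_adaptation(), protocol,
                            times, init = NULL,
                            rtol = 1e-8, atol = 1e-10) {
  protocol <- parse_protocol(protocol)
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  if (is.null(init)) init <- equilibrate(kin, adapt, 0)
  init <- init[state_names()]

  t0 <- times[1]; t_end <- times[length(times)]
  breaks <- unique(c(t0, protocol_switch_times(protocol, t0, t_end), t_end))
  out <- matrix(NA_real_, nrow = length(times), ncol = 7,
                dimnames = list(NULL, state_names()))
  cur <- as.numeric(init); names(cur) <- state_names()
  if (t0 %in% times) out[match(t0, times), ] <- cur

  for (i in seq_len(length(breaks) - 1L)) {
    a <- breaks[i]; b <- breaks[i + 1L]
    conc <- ifng_at(protocol, (a + b) / 2)
    seg_times <- times[times > a + 1e-12 & times <= b + 1e-12]
    tt <- unique(c(a, seg_times, b))
    rhs <- function(t, y, parms) {
      list(ode_rhs(t, y, kin, adapt, ifng = conc))
    }
    sol <- deSolve::lsoda(cur, tt, rhs, parms = NULL,
                          rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0)
      stop(sprintf("integration failed on segment [%g, %g] h", a, b))
    keep <- match(seg_times, sol[, "time"])
    out[match(seg_times, times), ] <- as.matrix(sol[keep, -1, drop = FALSE])
    cur <- sol[nrow(sol), -1]
  }
  # clip tiny negative solver excursions
  out[out < 0 & out > -1e-9] <- 0
  data.frame(time = times, out, check.names = FALSE)
}
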