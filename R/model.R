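#' Transcription-factor activity for a given stimulus and regulator level
#'
#' The TF (activated STAT1) activity is a saturating function of the
#' IFNg concentration, \code{tanh(alpha * (ifng + Kd))}. With the
#' negative-feedback adaptation enabled, the activity is divided by
#' \code{1 + (regP / reg_thr)^c1}, so accumulating regulator protein
#' suppresses the TF toward a sub-maximal plateau.
#'
#' @param ifng IFNg concentration (ng/ml), scalar or vector.
#' @param kin a [gene_kinetics()] object (supplies \code{alpha}, \code{Kd}).
#' @param adapt an [adaptation_params()] object.
#' @param regP regulator protein level (molecules); ignored when
#'   adaptation is disabled.
#' @return Dimensionless TF activity in \code{[0, 1)}; nondecreasing in
#'   \code{ifng}, nonincreasing in \code{regP}.
#' @export
tf_level <- function(ifng, kin, adapt = no_adaptation(), regP = 0) {
  if (any(ifng < 0)) stop("ifng must be >= 0")
  if (any(regP < 0)) stop("regP must be >= 0")
  base <- tanh(kin$alpha * (ifng + kin$Kd))
  if (!adapt$enabled) return(base)
  base / (1 + (regP / adapt$reg_thr)^adapt$c1)
}

#' Time derivative of the model state
#'
#' The deterministic model: chromatin cycles closed -> open-uninitiated
#' -> open-initiated with TF-dependent forward rates, only the initiated
#' state transcribes, and mRNA/protein turn over linearly. With
#' adaptation, the TF additionally induces a regulator mRNA through a
#' Hill function of TF and the regulator protein feeds back on the TF
#' activity. The three chromatin derivatives sum to zero, conserving
#' \code{C + OU + OI = n_loci}.
#'
#' @param t time (h).
#' @param state named state vector as from [model_state()].
#' @param kin a [gene_kinetics()] object.
#' @param adapt an [adaptation_params()] object.
#' @param protocol a \code{stimulus_protocol}; alternatively pass a fixed
#'   concentration via \code{ifng}.
#' @param ifng optional fixed IFNg concentration overriding the protocol.
#' @return Named derivative vector (same layout as the state).
#' @export
ode_rhs <- function(t, state, kin, adapt = no_adaptation(),
                    protocol = NULL, ifng = NULL) {
  if (is.null(ifng)) ifng <- ifng_at(protocol, t)
  tf <- tf_level(ifng, kin, adapt, state[["regP"]])
  C <- state[["C"]]; OU <- state[["OU"]]; OI <- state[["OI"]]
  M <- state[["M"]]; P <- state[["P"]]
  open_ <- kin$k1 * tf * C
  close_ <- kin$k2 * OU
  init_ <- kin$k3 * tf * OU
  deinit <- kin$k4 * OI
  d <- c(C = close_ - open_,
         OU = open_ - close_ - init_ + deinit,
         OI = init_ - deinit,
         M = kin$k5 * OI - kin$deltaM * M,
         P = kin$k6 * M - kin$deltaP * P,
         regM = 0, regP = 0)
  if (adapt$enabled) {
    hill <- tf^adapt$c2 / (1 + tf^adapt$c2)
    d[["regM"]] <- adapt$a_regM * hill - adapt$delta_regM * state[["regM"]]
    d[["regP"]] <- adapt$a_regP * state[["regM"]] -
      adapt$delta_regP * state[["regP"]]
  }
  d
}

#' Stationary chromatin-state occupancies at fixed TF activity
#'
#' Closed form for the steady state of the three-state chain at constant
#' TF: \code{OU/C = k1 tf / k2} and \code{OI/OU = k3 tf / k4}, normalized
#' to \code{n_loci}. Serves as the analytic anchor for the ODE and
#' Gillespie implementations.
#'
#' @param kin a [gene_kinetics()] object.
#' @param tf dimensionless TF activity (>= 0).
#' @return Named vector \code{(C, OU, OI)} summing to \code{n_loci}; the
#'   degenerate all-absorbing case (\code{tf = 0} with \code{k2 = k4 = 0})
#'   returns all-closed with attribute \code{degenerate = TRUE}.
#' @export
steady_state_chromatin <- function(kin, tf) {
  if (tf < 0) stop("tf must be >= 0")
  n <- kin$n_loci
  if (tf == 0) {
    out <- c(C = n, OU = 0, OI = 0)
    if (kin$k2 == 0 && kin$k4 == 0) attr(out, "degenerate") <- TRUE
    return(out)
  }
  # guard zero backward rates (absorbing downstream states)
  if (kin$k4 == 0 && kin$k3 > 0) return(c(C = 0, OU = 0, OI = n))
  if (kin$k2 == 0) {
    rOU <- 1; rOI <- if (kin$k4 > 0) kin$k3 * tf / kin$k4 else 0
    tot <- rOU + rOI
    return(c(C = 0, OU = n * rOU / tot, OI = n * rOI / tot))
  }
  rC <- 1
  rOU <- kin$k1 * tf / kin$k2
  rOI <- rOU * kin$k3 * tf / kin$k4
  tot <- rC + rOU + rOI
  c(C = n * rC / tot, OU = n * rOU / tot, OI = n * rOI / tot)
}

#' Pre-stimulus steady state of the full model
#'
#' Returns the resting state under a constant basal IFNg concentration
#' (normally 0; the TF input still has a small basal activity
#' \code{tanh(alpha * Kd)}). With adaptation enabled the TF and the
#' regulator protein are mutually dependent, so the TF is found as the
#' fixed point of the scalar self-consistency equation before reading off
#' the chromatin, mRNA and protein steady states.
#'
#' @param kin a [gene_kinetics()] object.
#' @param adapt an [adaptation_params()] object.
#' @param ifng_basal constant basal IFNg concentration (ng/ml).
#' @param tol residual tolerance on the ODE right-hand side at the
#'   returned state.
#' @return A named state vector (see [model_state()]) with attribute
#'   \code{tf} holding the self-consistent TF activity.
#' @export
equilibrate <- function(kin, adapt = no_adaptation(), ifng_basal = 0,
                        tol = 1e-8) {
  tf0 <- tanh(kin$alpha * (ifng_basal + kin$Kd))
  if (!adapt$enabled || tf0 == 0) {
    tf <- tf0
    regM <- 0; regP <- 0
  } else {
    regP_of <- function(tf) {
      hill <- tf^adapt$c2 / (1 + tf^adapt$c2)
      regM <- adapt$a_regM * hill / adapt$delta_regM
      adapt$a_regP * regM / adapt$delta_regP
    }
    g <- function(tf) tf * (1 + (regP_of(tf) / adapt$reg_thr)^adapt$c1) - tf0
    tf <- stats::uniroot(g, c(0, tf0), tol = 1e-14)$root
    hill <- tf^adapt$c2 / (1 + tf^adapt$c2)
    regM <- adapt$a_regM * hill / adapt$delta_regM
    regP <- adapt$a_regP * regM / adapt$delta_regP
  }
  chrom <- steady_state_chromatin(kin, tf)
  M <- if (kin$deltaM > 0) kin$k5 * chrom[["OI"]] / kin$deltaM else 0
  P <- if (kin$deltaP > 0) kin$k6 * M / kin$deltaP else 0
  st <- model_state(chrom[["C"]], chrom[["OU"]], chrom[["OI"]],
                    M = M, P = P, regM = regM, regP = regP)
  resid <- ode_rhs(0, st, kin, adapt, ifng = ifng_basal)
  if (max(abs(resid)) > tol * max(1, max(abs(st))))
    stop("equilibrate: residual ", max(abs(resid)), " exceeds tolerance")
  attr(st, "tf") <- tf
  st
}
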