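#' Per-gene kinetic parameters of the chromatin/expression model
#'
#' Bundles the rate constants of the three-state chromatin cycle
#' (closed -> open-uninitiated -> open-initiated), mRNA and protein
#' turnover, and the saturating transcription-factor (TF) input.
#' Only the open-initiated state transcribes; opening and initiation
#' are proportional to TF activity while closing and de-initiation are
#' constant. All rates are per hour.
#'
#' @param k1 chromatin opening rate per unit TF activity (1/h).
#' @param k2 chromatin closing rate (1/h).
#' @param k3 transcription initiation rate per unit TF activity (1/h).
#' @param k4 de-initiation rate (1/h).
#' @param k5 mRNA synthesis rate per initiated locus (molecules/h).
#' @param k6 translation rate per mRNA (molecules/h).
#' @param deltaM mRNA degradation rate (1/h).
#' @param deltaP protein degradation rate (1/h).
#' @param alpha TF input steepness (per ng/ml).
#' @param Kd TF input offset (ng/ml); gives a small basal TF activity
#'   \code{tanh(alpha * Kd)} at zero stimulus.
#' @param n_loci number of chromatin copies of the gene (default 2,
#'   one per allele).
#'
#' @return An object of class \code{gene_kinetics}.
#' @seealso [adaptation_params()], [tf_level()], [ode_rhs()]
#' @export
gene_kinetics <- function(k1, k2, k3, k4, k5, k6, deltaM, deltaP,
                          alpha, Kd, n_loci = 2L) {
  rates <- c(k1 = k1, k2 = k2, k3 = k3, k4 = k4, k5 = k5, k6 = k6,
             deltaM = deltaM, deltaP = deltaP, alpha = alpha, Kd = Kd)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all kinetic parameters must be finite and nonnegative")
  n_loci <- as.integer(n_loci)
  if (is.na(n_loci) || n_loci < 1L)
    stop("n_loci must be an integer >= 1")
  structure(c(as.list(rates), list(n_loci = n_loci)),
            class = "gene_kinetics")
}

#' Negative-feedback adaptation parameters
#'
#' Parameters of the transcriptional negative feedback that suppresses
#' the TF under sustained stimulation: the TF induces a regulator mRNA
#' (regM), whose protein product (regP) divides the TF activity by
#' \code{1 + (regP/reg_thr)^c1}. With \code{enabled = FALSE} the TF
#' input reduces exactly to the adaptation-free form and the regulator
#' species stay at zero.
#'
#' @param a_regM maximal regulator mRNA synthesis rate (molecules/h).
#' @param a_regP regulator translation rate per regM (molecules/h).
#' @param delta_regM regulator mRNA degradation rate (1/h).
#' @param delta_regP regulator protein degradation rate (1/h).
#' @param reg_thr regulator protein half-suppression scale (molecules).
#' @param c1 suppression Hill exponent (dimensionless).
#' @param c2 regulator-production Hill exponent (dimensionless);
#'   sub-unity values give a shallow, graded induction of the regulator.
#' @param enabled logical; \code{FALSE} disables the feedback entirely.
#'
#' @return An object of class \code{adaptation_params}.
#' @export
adaptation_params <- function(a_regM = 0, a_regP = 0, delta_regM = 1,
                              delta_regP = 1, reg_thr = 1, c1 = 1,
                              c2 = 1, enabled = TRUE) {
  vals <- c(a_regM = a_regM, a_regP = a_regP, delta_regM = delta_regM,
            delta_regP = delta_regP, reg_thr = reg_thr, c1 = c1, c2 = c2)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all adaptation parameters must be finite and nonnegative")
  if (isTRUE(enabled)) {
    if (reg_thr <= 0) stop("reg_thr must be strictly positive when enabled")
    if (c1 <= 0 || c2 <= 0) stop("c1 and c2 must be strictly positive when enabled")
    if (delta_regM <= 0 || delta_regP <= 0)
      stop("regulator degradation rates must be strictly positive when enabled")
  }
  structure(c(as.list(vals), list(enabled = isTRUE(enabled))),
            class = "adaptation_params")
}

#' Disabled adaptation (open-loop TF input)
#' @return An \code{adaptation_params} object with the feedback off.
#' @export
no_adaptation <- function() adaptation_params(enabled = FALSE)

#' @export
print.gene_kinetics <- function(x, ...) {
  cat("<gene_kinetics>\n")
  cat(sprintf("  chromatin: k1=%g k2=%g k3=%g k4=%g (1/h), n_loci=%d\n",
              x$k1, x$k2, x$k3, x$k4, x$n_loci))
  cat(sprintf("  expression: k5=%g k6=%g deltaM=%g deltaP=%g\n",
              x$k5, x$k6, x$deltaM, x$deltaP))
  cat(sprintf("  TF input: alpha=%g per ng/ml, Kd=%g ng/ml\n", x$alpha, x$Kd))
  invisible(x)
}

#' @export
print.adaptation_params <- function(x, ...) {
  cat("<adaptation_params>", if (x$enabled) "enabled" else "disabled", "\n")
  if (x$enabled)
    cat(sprintf("  a_regM=%g a_regP=%g delta_regM=%g delta_regP=%g reg_thr=%g c1=%g c2=%g\n",
                x$a_regM, x$a_regP, x$delta_regM, x$delta_regP,
                x$reg_thr, x$c1, x$c2))
  invisible(x)
}

state_names <- function() c("C", "OU", "OI", "M", "P", "regM", "regP")

#' Assemble a model state vector
#'
#' The model state holds the three chromatin-state occupancies (in locus
#' units, summing to \code{n_loci}), mRNA, protein, and the two
#' adaptation-regulator species.
#'
#' @param C,OU,OI closed / open-uninitiated / open-initiated loci.
#' @param M,P mRNA and protein.
#' @param regM,regP regulator mRNA and protein.
#' @return Named numeric vector of length 7.
#' @export
model_state <- function(C, OU, OI, M = 0, P = 0, regM = 0, regP = 0) {
  y <- c(C = C, OU = OU, OI = OI, M = M, P = P, regM = regM, regP = regP)
  if (any(!is.finite(y)) || any(y < -1e-12))
    stop("state components must be finite and nonnegative")
  y
}

#' Serialize parameters to a YAML configuration file
#'
#' Writes (or reads back) kinetic, adaptation, and protocol settings as a
#' plain hierarchical config with keys named exactly as the constructor
#' arguments, so a model setup travels as a small text file.
#'
#' @param kin a \code{gene_kinetics} object.
#' @param adapt an \code{adaptation_params} object.
#' @param protocol a \code{stimulus_protocol} object (optional).
#' @param path file to write.
#' @return \code{write_model_config} returns \code{path} invisibly;
#'   \code{read_model_config} returns a list with elements
#'   \code{kinetics}, \code{adaptation}, and possibly \code{protocol}.
#' @export
write_model_config <- function(kin, adapt, protocol = NULL, path) {
  cfg <- list(kinetics = unclass(kin), adaptation = unclass(adapt))
  if (!is.null(protocol)) {
    cfg$protocol <- list(
      segments = lapply(seq_len(nrow(protocol$segments)), function(i)
        as.list(protocol$segments[i, ])),
      t0 = protocol$t0, horizon = protocol$horizon)
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- list(
    kinetics = do.call(gene_kinetics, cfg$kinetics),
    adaptation = do.call(adaptation_params, cfg$adaptation))
  if (!is.null(cfg$protocol)) {
    seg <- do.call(rbind, lapply(cfg$protocol$segments, as.data.frame))
    out$protocol <- stimulus_protocol(seg, t0 = cfg$protocol$t0,
                                      horizon = cfg$protocol$horizon)
  }
  out
}
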