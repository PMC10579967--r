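# Independent numerical oracles used across the suite. These re-derive the
# model from the printed reaction scheme with their own code paths so they
# stay independent of the package implementation they check.

# Hand-coded right-hand side (term by term, no package calls).
oracle_rhs <- function(y, p, ifng) {
  tf <- tanh(p$alpha * (ifng + p$Kd))
  if (isTRUE(p$adapt_on))
    tf <- tf / (1 + (y[7] / p$reg_thr)^p$c1)
  h <- if (isTRUE(p$adapt_on)) tf^p$c2 / (1 + tf^p$c2) else 0
  c(p$k2 * y[2] - p$k1 * tf * y[1],
    p$k1 * tf * y[1] - p$k2 * y[2] - p$k3 * tf * y[2] + p$k4 * y[3],
    p$k3 * tf * y[2] - p$k4 * y[3],
    p$k5 * y[3] - p$deltaM * y[4],
    p$k6 * y[4] - p$deltaP * y[5],
    if (isTRUE(p$adapt_on)) p$a_regM * h - p$delta_regM * y[6] else 0,
    if (isTRUE(p$adapt_on)) p$a_regP * y[6] - p$delta_regP * y[7] else 0)
}

# Fixed-step classical RK4, integrated piecewise between stimulus switches so
# the discontinuous input is handled exactly.
rk4_oracle <- function(kin, adapt, protocol, times, y0, h = 1e-3) {
  p <- c(unclass(kin), unclass(adapt)[setdiff(names(adapt), "enabled")])
  p$adapt_on <- adapt$enabled
  protocol <- parse_protocol(protocol)
  t0 <- times[1]; t_end <- times[length(times)]
  breaks <- unique(c(t0, protocol_switch_times(protocol, t0, t_end), t_end))
  out <- matrix(NA_real_, length(times), 7)
  y <- as.numeric(y0)
  if (t0 %in% times) out[match(t0, times), ] <- y
  for (s in seq_len(length(breaks) - 1L)) {
    a <- breaks[s]; b <- breaks[s + 1L]
    ifng <- ifng_at(protocol, (a + b) / 2)
    grid <- times[times > a + 1e-12 & times <= b + 1e-12]
    targets <- unique(c(grid, b))
    t <- a
    for (tg in targets) {
      nstep <- max(1L, ceiling((tg - t) / h - 1e-9))
      hh <- (tg - t) / nstep
      for (i in seq_len(nstep)) {
        k1v <- oracle_rhs(y, p, ifng)
        k2v <- oracle_rhs(y + hh / 2 * k1v, p, ifng)
        k3v <- oracle_rhs(y + hh / 2 * k2v, p, ifng)
        k4v <- oracle_rhs(y + hh * k3v, p, ifng)
        y <- y + hh / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
      }
      t <- tg
      if (tg %in% grid) out[match(tg, times), ] <- y
    }
  }
  colnames(out) <- c("C", "OU", "OI", "M", "P", "regM", "regP")
  out
}

# Small kinetics used when the test only needs a well-behaved parameter set.
toy_kinetics <- function(...) {
  args <- list(k1 = 2, k2 = 1, k3 = 3, k4 = 0.5, k5 = 4, k6 = 1.5,
               deltaM = 1, deltaP = 0.2, alpha = 0.5, Kd = 0.1)
  mod <- list(...)
  args[names(mod)] <- mod
  do.call(gene_kinetics, args)
}

toy_adaptation <- function(...) {
  args <- list(a_regM = 10, a_regP = 2, delta_regM = 0.5,
               delta_regP = 0.25, reg_thr = 50, c1 = 2, c2 = 0.5,
               enabled = TRUE)
  mod <- list(...)
  args[names(mod)] <- mod
  do.call(adaptation_params, args)
}
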