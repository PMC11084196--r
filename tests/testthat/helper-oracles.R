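# Independent oracles and small fixture builders used across the suite.

# Exhaustive DTW: minimum cost over every monotone alignment path from
# (1,1) to (n,m) with steps diagonal/right/down, each adding |x - y|.
# Independent of the package's dynamic program; only viable for short
# series.
brute_force_dtw <- function(s1, s2) {
  n <- length(s1)
  m <- length(s2)
  best <- Inf
  recurse <- function(i, j, acc) {
    acc <- acc + abs(s1[i] - s2[j])
    if (i == n && j == m) {
      best <<- min(best, acc)
      return(invisible(NULL))
    }
    if (i < n) recurse(i + 1L, j, acc)
    if (j < m) recurse(i, j + 1L, acc)
    if (i < n && j < m) recurse(i + 1L, j + 1L, acc)
    invisible(NULL)
  }
  recurse(1L, 1L, 0)
  best
}

# Numerical integration of the two-site binding ODE
#   dR_i/dt = ka_i * C(t) * (Rmax_i - R_i) - kd_i * R_i,
# with C(t) = conc during association and 0 afterwards, integrated phase
# by phase at tight tolerance. Independent route to the closed forms.
ode_sensorgram <- function(kp, rmax1, rmax2, conc, times, t_assoc) {
  deriv <- function(t, state, parms) {
    C <- parms$C
    list(c(
      parms$ka1 * C * (parms$rmax1 - state[1]) - parms$kd1 * state[1],
      parms$ka2 * C * (parms$rmax2 - state[2]) - parms$kd2 * state[2]
    ))
  }
  parms <- list(ka1 = kp$ka1, kd1 = kp$kd1, ka2 = kp$ka2, kd2 = kp$kd2,
                rmax1 = rmax1, rmax2 = rmax2)
  t_a <- times[times <= t_assoc]
  t_d <- times[times > t_assoc]
  parms$C <- conc
  out_a <- deSolve::lsoda(c(0, 0), t_a, deriv, parms,
                          rtol = 1e-11, atol = 1e-11)
  state <- out_a[nrow(out_a), 2:3]
  resp <- rowSums(out_a[, 2:3, drop = FALSE])
  if (length(t_d)) {
    parms$C <- 0
    out_d <- deSolve::lsoda(state, c(max(t_a), t_d), deriv, parms,
                            rtol = 1e-11, atol = 1e-11)
    resp <- c(resp, rowSums(out_d[-1L, 2:3, drop = FALSE]))
  }
  unname(resp)
}

# Table of per-condition two-site parameters used throughout (units:
# ka 1/M/s, kd 1/s, KD M). The KD columns are the independently reported
# averages of per-concentration ratios, not kd/ka of these rows.
kinetics_reference <- list(
  baseline_dmso = list(ka1 = 2.7e2, kd1 = 0.216e-4, KD1 = 0.64e-7,
                       ka2 = 8.9e2, kd2 = 26e-4, KD2 = 5.0e-6),
  baseline_ethanol = list(KD1 = 1.2e-7, KD2 = 3.2e-6),
  prednisone = list(ka1 = 2.73e2, kd1 = 0.11e-4, KD1 = 0.38e-7,
                    ka2 = 36e2, kd2 = 13.6e-4, KD2 = 0.38e-6),
  levothyroxine = list(KD1 = 1.90e-7, KD2 = 0.41e-6),
  mefenamic = list(KD1 = 3.6e-7, KD2 = 13e-6)
)

# kinetic_params carrying the reported averaged-KD columns verbatim.
reported_kp <- function(row) {
  kp <- kinetic_params(1, row$KD1, 1, row$KD2, relabel = FALSE)
  kp
}

toy_sites <- function() {
  list(
    A = binding_site("A", c(1, 2)),
    B = binding_site("B", c(2, 3))
  )
}
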