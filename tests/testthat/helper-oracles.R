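# Independent oracles, coded separately from the package internals.

# Brute-force winding number of Delta over the boundary of the half-disk
# {Re >= x0, |lambda| <= R}, with fixed dense sampling (no adaptivity).
oracle_count_unstable <- function(a1, a2, a3, x0 = 1e-8, npts = 2e5) {
  R <- (abs(a1) + abs(a2)) / (1 - abs(a3)) + 1
  yy <- sqrt(R^2 - x0^2)
  seg <- complex(real = x0, imaginary = seq(yy, -yy, length.out = npts))
  phi <- acos(x0 / R)
  arc <- R * exp(1i * seq(-phi, phi, length.out = npts))
  pts <- c(seg, arc[-1])
  v <- pts - a1 - (a2 + a3 * pts) * exp(-pts)
  dp <- Arg(v[-1] / v[-length(v)])
  stopifnot(max(abs(dp)) < pi / 2)   # oracle resolution guard
  w <- sum(dp) / (2 * pi)
  stopifnot(abs(w - round(w)) < 0.1)
  as.integer(round(w))
}

# Real and imaginary parts of the characteristic equation at
# lambda = mu + i*omega, written directly from the two real equations
# G1 = G2 = 0 (so that Re Delta = -G1, Im Delta = -G2).
oracle_G1 <- function(a1, a2, a3, mu, omega) {
  -mu + a1 + (a2 + a3 * mu) * cos(omega) * exp(-mu) +
    a3 * omega * sin(omega) * exp(-mu)
}

oracle_G2 <- function(a1, a2, a3, mu, omega) {
  -omega - (a2 + a3 * mu) * sin(omega) * exp(-mu) +
    a3 * omega * cos(omega) * exp(-mu)
}

# Plain scalar bisection, used to cross-check the package's curve inversions.
oracle_bisect <- function(f, lo, hi, iter = 200) {
  flo <- f(lo)
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (sign(f(mid)) == sign(flo)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Unstable-root total with conjugate pairs counted twice, from a find_roots
# table restricted to Re > margin.
pair_count <- function(roots, margin = 1e-8) {
  keep <- roots$re > margin
  as.integer(sum(roots$multiplicity[keep] * ifelse(roots$im[keep] > 1e-12, 2, 1)))
}

# Fig 4a-style fixture on the theta = 0.3 slice: Hill exponent n sets the
# local steepness G'(Ebar) = n * G(Ebar) at Ebar = 0.5.
fig4_slice_fixture <- function(hill_n, theta = 0.3) {
  make_fixture("fig4", theta = theta, hill_n = hill_n)
}

# Measured dominant mode for a fixture: baseline-corrected centre and a
# window cut before nonlinear saturation.
measure_fixture_mode <- function(model, amp, t_end, t_min, N = 256) {
  ss <- solve_steady_state(model)
  base <- integrate_model(model, history_steady_state(ss), 5, N = N)
  Qc <- tail(base$Q, 1)
  tr <- integrate_model(model, history_steady_state(ss, amp), t_end, N = N)
  # for a growing mode, stop before nonlinear saturation takes over
  t_max <- Inf
  growing <- abs(tr$Q[length(tr$Q)] - Qc) > 2 * amp * ss$Qbar
  if (growing) {
    sat <- tr$t[abs(tr$Q - Qc) > 0.05 * ss$Qbar][1]
    if (!is.na(sat)) t_max <- sat
  }
  c(measure_dominant_mode(tr, Qc, t_min, t_max), list(ss = ss))
}
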