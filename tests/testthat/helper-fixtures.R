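# Shared fixtures and independent oracles.

# A small, fast parameter set with moderate rates (not the packaged fixture).
toy_params <- function() {
  rid_params(
    absorption_efficiency = 0.9, delay_time = 0.5,
    l_5_4 = 5, l_6_5 = 2, l_7_5 = 0.5, l_8_5 = 0.8,
    l_5_6 = 0.05, l_5_7 = 0.25, l_0_6 = 0.01,
    dietary_intake = 1.5, dose = 2
  )
}

# A second distinct set for parameterised round trips.
slow_store_params <- function() {
  rid_params(
    absorption_efficiency = 0.75, delay_time = 0.3,
    l_5_4 = 12, l_6_5 = 5, l_7_5 = 1.2, l_8_5 = 1.5,
    l_5_6 = 0.01, l_5_7 = 0.6, l_0_6 = 0.002,
    dietary_intake = 2, dose = 1
  )
}

# Independent steady-state oracle: assemble the 4-compartment flux-balance
# system and solve it with generic dense linear algebra.
steady_state_oracle <- function(p) {
  absorbed <- p$absorption_efficiency * p$dietary_intake
  M <- rbind(
    c(p$l_5_4, 0, 0, 0),                                           # chylomicron
    c(-p$l_5_4, p$l_6_5 + p$l_7_5 + p$l_8_5, -p$l_5_6, -p$l_5_7),  # plasma
    c(0, -p$l_6_5, p$l_5_6 + p$l_0_6, 0),                          # large store
    c(0, -p$l_7_5, 0, p$l_5_7)                                     # small store
  )
  b <- c(absorbed, 0, 0, 0)
  m <- solve(M, b)
  list(m_4 = m[1], m_5 = m[2], m_6 = m[3], m_7 = m[4], tbs = m[3] + m[4])
}

# Closed-form matrix-exponential solution for delay-free parameter sets:
# states (c4, c5, c6, c7, out8, out6), dose fraction E entering c4 at t = 0.
expm_oracle <- function(p, times) {
  stopifnot(p$delay_time == 0)
  A <- rbind(
    c(-p$l_5_4, 0, 0, 0, 0, 0),
    c(p$l_5_4, -(p$l_6_5 + p$l_7_5 + p$l_8_5), p$l_5_6, p$l_5_7, 0, 0),
    c(0, p$l_6_5, -(p$l_5_6 + p$l_0_6), 0, 0, 0),
    c(0, p$l_7_5, 0, -p$l_5_7, 0, 0),
    c(0, p$l_8_5, 0, 0, 0, 0),
    c(0, 0, p$l_0_6, 0, 0, 0)
  )
  y0 <- c(p$absorption_efficiency, 0, 0, 0, 0, 0)
  t(vapply(times, function(t) as.numeric(Matrix::expm(A * t) %*% y0),
           numeric(6)))
}

# Conservation defect of a trajectory: worst deviation of the compartment
# fractions plus cumulative outputs from the absorbed fraction.
conservation_defect <- function(traj, params) {
  tot <- traj$f_delay + traj$f_4 + traj$f_5 + traj$f_6 + traj$f_7 +
    traj$f_out_8 + traj$f_out_6
  max(abs(tot - params$absorption_efficiency))
}
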