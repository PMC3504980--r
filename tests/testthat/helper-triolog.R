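# Shared fixtures for the triolog test suite.

# study conditions used throughout: RAF 0.3 at both loci, HWE, baseline 0.1
p_true <- c(0.49, 0.42, 0.09)
p_false1 <- c(0.81, 0.18, 0.01)
p_false2 <- c(0.25, 0.50, 0.25)

# a generic, asymmetric codominant risk set exercising every parameter
fixture_risk <- function() {
  risk_model(S = c(1.2, 1.7), R = c(0.8, 1.4),
             theta = matrix(c(1.3, 2.0, 0.7, 1.1), 2, 2, byrow = TRUE),
             phi = matrix(c(1.5, 0.9, 2.2, 1.2), 2, 2, byrow = TRUE),
             tau = c(1.4, 0.6))
}

fixture_pop <- function() {
  pop_params(p = c(0.5, 0.3, 0.2), mu = c(0.1, 0.2, 0.15, 0.25, 0.2, 0.1))
}

# Independent oracle for the theoretical trio-type table: every cell written
# out literally, exactly as the published table reads, for the fixture
# parameter values above.  S1/S2 etc. are scalars here, never indexed code.
fixture_table_oracle <- function() {
  S1 <- 1.2; S2 <- 1.7; R1 <- 0.8; R2 <- 1.4
  t11 <- 1.3; t12 <- 2.0; t21 <- 0.7; t22 <- 1.1   # theta_ik
  f11 <- 1.5; f12 <- 0.9; f21 <- 2.2; f22 <- 1.2   # phi_jk
  u1 <- 1.4; u2 <- 0.6                             # tau_k
  m1 <- 0.1; m2 <- 0.2; m3 <- 0.15; m4 <- 0.25; m5 <- 0.2; m6 <- 0.1
  p0 <- 0.5; p1 <- 0.3; p2 <- 0.2
  k0 <- c(p0*S2*R2*m1, p0*S2*R2*m2, p0*S2*R1*m2, p0*S1*R2*m2, p0*S1*R1*m2,
          p0*S2*R1*m3, p0*R1*m3, p0*S1*R2*m4, 2*p0*S1*R1*m4, p0*S1*m4,
          p0*S1*R1*m5, p0*S1*m5, p0*R1*m5, p0*m5, p0*m6)
  k1 <- c(p1*t21*f21*S2*R2*m1*u1, p1*t21*f21*S2*R2*m2*u1,
          p1*t21*f11*S2*R1*m2*u1, p1*t11*f21*S1*R2*m2*u1,
          p1*t11*f11*S1*R1*m2*u1, p1*t21*f11*S2*R1*m3*u1,
          p1*f11*R1*m3*u1, p1*t11*f21*S1*R2*m4*u1,
          2*p1*t11*f11*S1*R1*m4*u1, p1*t11*S1*m4*u1,
          p1*t11*f11*S1*R1*m5*u1, p1*t11*S1*m5*u1,
          p1*f11*R1*m5*u1, p1*m5*u1, p1*m6*u1)
  k2 <- c(p2*t22*f22*S2*R2*m1*u2, p2*t22*f22*S2*R2*m2*u2,
          p2*t22*f12*S2*R1*m2*u2, p2*t12*f22*S1*R2*m2*u2,
          p2*t12*f12*S1*R1*m2*u2, p2*t22*f12*S2*R1*m3*u2,
          p2*f12*R1*m3*u2, p2*t12*f22*S1*R2*m4*u2,
          2*p2*t12*f12*S1*R1*m4*u2, p2*t12*S1*m4*u2,
          p2*t12*f12*S1*R1*m5*u2, p2*t12*S1*m5*u2,
          p2*f12*R1*m5*u2, p2*m5*u2, p2*m6*u2)
  c(k0, k1, k2)
}

# log-risk coefficient vector matching the codominant eq1 design columns
fixture_beta <- function(risk, pop) {
  stats::setNames(
    c(log(pop$mu),
      log(risk$S), log(risk$R), log(risk$tau),
      log(c(risk$theta[1, 1], risk$theta[1, 2],
            risk$theta[2, 1], risk$theta[2, 2])),
      log(c(risk$phi[1, 1], risk$phi[1, 2],
            risk$phi[2, 1], risk$phi[2, 2]))),
    c(paste0("mu", 1:6), "S1", "S2", "R1", "R2", "delta1", "delta2",
      paste0("theta", c(11, 12, 21, 22)), paste0("phi", c(11, 12, 21, 22))))
}

expect_rejection_near <- function(observed_frac, expected_pct, n_reps) {
  p0 <- expected_pct / 100
  se <- sqrt(p0 * (1 - p0) / n_reps)
  expect_lt(abs(observed_frac - p0), 3 * se,
            label = sprintf("|%.3f - %.3f| (3 MC SE = %.3f)",
                            observed_frac, p0, 3 * se))
}
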