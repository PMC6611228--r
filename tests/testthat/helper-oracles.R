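# Independent numerical oracles used across tests. These deliberately go
# through generic quadrature / simulation, never through the closed forms
# they are checking.

# Cumulated dose by adaptive quadrature of A0 e^{-lambda t} S(t), with S
# linearly interpolated in time and converted cGy/d -> Gy/h.
quad_dose <- function(A0, s_initial, s_final, T, T_phys = 64.1) {
  lam <- log(2) / T_phys
  s_gy_h <- function(t) {
    (s_initial + (s_final - s_initial) * t / T) * 0.01 / 24
  }
  stats::integrate(function(t) A0 * exp(-lam * t) * s_gy_h(t),
                   0, T, rel.tol = 1e-11, abs.tol = 0)$value
}

# Lea-Catcheside factor by double numerical quadrature of its defining
# integral for dose rate proportional to exp(-lambda t).
quad_g <- function(T_rep, T_phys, T) {
  lam <- log(2) / T_phys
  mu <- log(2) / T_rep
  D <- stats::integrate(function(t) exp(-lam * t), 0, T,
                        rel.tol = 1e-12)$value
  inner <- function(t) {
    stats::integrate(function(s) exp(-lam * s) * exp(-mu * (t - s)),
                     0, t, rel.tol = 1e-12)$value
  }
  num <- stats::integrate(function(tv) {
    exp(-lam * tv) * vapply(tv, inner, numeric(1))
  }, 0, T, rel.tol = 1e-10)$value
  2 * num / D^2
}

# Exact (noise-free) clonogenic records generated straight from the LQ
# survival law, bypassing simulate_clonogenic().
exact_records <- function(alpha, beta, doses = c(0, 1, 2, 4, 6, 8, 10),
                          sets = c("R1", "R2"), wells = 2L,
                          plated = 1000, pe = 0.6) {
  rec <- expand.grid(well = seq_len(wells), dose_Gy = doses,
                     replicate_set = sets, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  rec$plated <- plated
  rec$colonies <- plated * pe * exp(-(alpha * rec$dose_Gy +
                                        beta * rec$dose_Gy^2))
  rec
}
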