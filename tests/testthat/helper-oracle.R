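# Independent numerical oracle for the incomplete-repair factor:
# normalised double integral of exp(-mu|u - v|) over [0, T]^2, evaluated by
# nested adaptive quadrature (no use of the closed form).
f_oracle <- function(mu, T_h) {
  if (T_h == 0) return(1)
  inner <- function(v) {
    vapply(v, function(vv) {
      # split at the |u - v| kink so the quadrature sees smooth integrands
      stats::integrate(function(u) exp(-mu * (vv - u)), 0, vv,
                       rel.tol = 1e-9)$value +
        stats::integrate(function(u) exp(-mu * (u - vv)), vv, T_h,
                         rel.tol = 1e-9)$value
    }, numeric(1L))
  }
  stats::integrate(inner, 0, T_h, rel.tol = 1e-8,
                   subdivisions = 400L)$value / T_h^2
}

# independent session BED from first principles (scalar, readable form)
bed_session_oracle <- function(D, n, T_min, t_min, kin) {
  d <- D / n
  k <- kin$alpha_beta
  comp <- function(mu) {
    D * (1 + ((D - d) / k) * f_oracle(mu, T_min / 60) +
           (d / k) * f_oracle(mu, t_min / 60))
  }
  kin$x_fast * comp(kin$mu_fast) + (1 - kin$x_fast) * comp(kin$mu_slow)
}

avm_kin <- pathology_kinetics("avm")

# small AVM-style fraction table used by several IO tests
make_fx_table <- function() {
  data.frame(
    patient_id = c("p1", "p2", "p2", "p2"),
    fraction_index = c(1L, 1L, 2L, 3L),
    dose_gy = c(20, 8, 8, 8),
    n_iso = c(10L, 7L, 7L, 7L),
    duration_min = c(37.5, 25.5, 25.5, 25.5),
    beam_on_per_iso_min = c(3, 2.5, 2.5, 2.5),
    stringsAsFactors = FALSE)
}
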