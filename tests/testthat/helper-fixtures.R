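# Shared fixtures: the default labelled buffer and small builders.

default_buffer <- function() carbon_pool(7.58, 10)

# substrate 13C atom percent used throughout
A_SUB <- 1.075

# minimal well-formed measurement table (n rows, one microcosm)
make_measurements <- function(days = c(0, 30, 60),
                              deltas = rep(8938.2, length(days)),
                              id = "live_1", treatment = "live") {
  data.frame(day = days, microcosm_id = id, treatment = treatment,
             delta13c_permil = deltas, sulfate_mM = NA_real_,
             cells_per_ml = NA_real_)
}

# independent evaluation of the delta -> atom fraction relation as a
# nested reciprocal (the printed form), delta as a plain fraction
oracle_atom_fraction <- function(delta_frac, r = 0.0111802) {
  1 / (1 + 1 / ((delta_frac + 1) * r))
}

# brute-force inversion of the forward mixing model by 1-D root search
oracle_invert_mix <- function(measured_atom_pct, buffer, substrate_atom_pct,
                              upper = 1e6) {
  f <- function(p) forward_mix(buffer, p, substrate_atom_pct) - measured_atom_pct
  stats::uniroot(f, c(0, upper), tol = 1e-12)$root
}
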