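# Numeric-integration oracle for the one-compartment model:
#   dC/dt = rate(t)/V - (CL/V) * C,  C(0) = 0
# kept independent of the package's closed forms.

ode_conc <- function(cl, v, rate_fn, times, hmax = 0.05) {
  f <- function(t, y, parms) list(rate_fn(t) / v - (cl / v) * y)
  grid <- sort(unique(c(0, times)))
  out <- deSolve::lsoda(c(C = 0), times = grid, func = f,
                        rtol = 1e-10, atol = 1e-12, hmax = hmax,
                        maxsteps = 1e6)
  out[match(times, out[, "time"]), "C"]
}

ode_constant_infusion <- function(rate_mg_h, cl, v, times) {
  ode_conc(cl, v, function(t) rate_mg_h, times, hmax = 0.25)
}

ode_single_infusion <- function(dose_mg, tinf_h, cl, v, times) {
  ode_conc(cl, v, function(t) if (t >= 0 && t < tinf_h) dose_mg / tinf_h else 0,
           times)
}

# superposition of n_doses repeated infusions, every tau hours from t = 0
ode_repeated_infusions <- function(dose_mg, tinf_h, tau_h, n_doses, cl, v,
                                   times) {
  rate <- function(t) {
    if (t < 0 || t >= n_doses * tau_h) return(0)
    if (t %% tau_h < tinf_h) dose_mg / tinf_h else 0
  }
  ode_conc(cl, v, rate, times)
}

expect_rel_equal <- function(actual, expected, rel_tol) {
  expect_true(all(abs(actual - expected) <= rel_tol * pmax(abs(expected), 1e-12)),
              label = sprintf("max rel err %.3g <= %g",
                              max(abs(actual - expected) /
                                    pmax(abs(expected), 1e-12)), rel_tol))
}
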