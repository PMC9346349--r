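# Independent numerical oracles used across the suite. These deliberately do
# not share code paths with the package internals they check.

# Gompertz growth as a numerically integrated ODE, dV/dt = R * log(Vmax/V) * V,
# evaluated at `times` starting from V0.
ode_gompertz <- function(times, V0, Vmax, R) {
  rhs <- function(t, y, parms) list(R * log(Vmax / y) * y)
  out <- deSolve::lsoda(y = c(V = V0), times = times, func = rhs,
                        parms = NULL, rtol = 1e-10, atol = 1e-14)
  out[, "V"]
}

# Inverse of the tumour growth curve by plain bisection on the closed form.
bisect_onset <- function(V, params, tol = 1e-10) {
  lo <- 0
  hi <- 1
  while (tumour_volume(hi, params) < V) hi <- hi * 2
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (tumour_volume(mid, params) < V) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Closed-form solution of the serum compartment under a constant input I:
# C(t) = C_inf + (C0 - C_inf) exp(-gamma t), C_inf = I / (gamma V_p).
analytic_constant_serum <- function(t, K, U, params, Q0 = 0) {
  input <- K * U + params$C_H * params$gamma * params$V_p
  c_inf <- input / (params$gamma * params$V_p)
  c_inf + (Q0 / params$V_p - c_inf) * exp(-params$gamma * t)
}

# Parameters with necrosis switched off (onset volume at the plateau is never
# reached): the serum compartment should sit at its healthy steady state.
no_necrosis_params <- function() {
  p <- default_parameters()
  p$Vn0 <- p$V_Tmax
  p$Vk0 <- p$V_Tmax
  p
}
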