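# Healthy-tissue input K_H*U_H is identifiable only as a product; it is
# rederived from the steady-state relation C_H = K_H*U_H / (gamma * V_p).
.healthy_input <- function(params) params$C_H * params$gamma * params$V_p

#' Blood-brain-barrier transfer fraction
#'
#' The fraction of tumour-released biomarker that reaches the blood. Zero
#' (`K_min`) while the barrier is intact, then a Hill function of absolute
#' model time once the tumour passes the transfer onset volume `Vk0`:
#' `K_T(t) = K_min + (K_max - K_min) * t^h / (K_half^h + t^h)` for
#' `t >= Tk0`. The Hill clock is the time since the single-cell origin, which
#' places the half-saturation time `K_half` on the same axis as the onset
#' time `Tk0`.
#'
#' @param t Time(s) in days, `>= 0`.
#' @param params A `gfap_params` object.
#' @return Transfer fraction(s) in `[K_min, K_max]`.
#' @examples
#' p <- default_parameters()
#' transfer_fraction(p$K_half, p)  # half-saturation: K_max/2 = 0.25
#' @export
transfer_fraction <- function(t, params) {
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  Tk0 <- onset_time(params$Vk0, params, sentinel = TRUE)
  hill <- t^params$h / (params$K_half^params$h + t^params$h)
  ifelse(t < Tk0, params$K_min,
         params$K_min + (params$K_max - params$K_min) * hill)
}

#' Necrosis-driven biomarker production rate
#'
#' Mass of biomarker released per day, `U_T(t) = Q_N * dN_N/dt`. With
#' Gompertzian necrotic growth the derivative is available in closed form:
#' `U_T(t) = Q_N * R_N * log(N_nmax / N_N(t)) * N_N(t)` for `t >= Tn0`, where
#' `N_N = V_N * delta_N` and `N_nmax = V_Nmax * delta_N`; zero before onset.
#' Production vanishes again as the necrotic core reaches its plateau.
#'
#' @inheritParams transfer_fraction
#' @return Production rate(s) in ng/day.
#' @examples
#' p <- default_parameters()
#' production_rate(onset_time(p$Vn0, p), p)  # switch-on at necrosis onset
#' @export
production_rate <- function(t, params) {
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  Tn0 <- onset_time(params$Vn0, params, sentinel = TRUE)
  nn <- cells_from_volume(necrotic_volume(t, params, cap = FALSE),
                          params$delta_N)
  nmax <- params$V_Nmax * params$delta_N
  ifelse(t < Tn0 | nn <= 0, 0,
         params$Q_N * params$R_N * log(nmax / pmax(nn, 1e-300)) * nn)
}

# Right-hand side of the serum mass balance dQp/dt = K_T*U_T + K_H*U_H - gamma*Qp
.serum_rhs <- function(params) {
  uh <- .healthy_input(params)
  function(t, y, parms) {
    list(transfer_fraction(t, params) * production_rate(t, params) +
           uh - params$gamma * y)
  }
}

#' Simulate the serum biomarker trajectory
#'
#' Integrates the one-compartment serum mass balance
#' `dQp/dt = K_T(t) U_T(t) + K_H U_H - gamma Qp` from the healthy steady
#' state `Qp(0) = C_H * V_p`. Before necrosis onset the tumour input is
#' identically zero and the compartment stays at its analytic steady state;
#' numerical integration (adaptive `lsoda`, relative tolerance `1e-8`) starts
#' at the onset switch point.
#'
#' @param params A `gfap_params` object.
#' @param t_end Simulation horizon in days.
#' @param dt Output grid spacing in days.
#' @param rtol,atol Integrator tolerances.
#' @return A data frame of class `gfap_serum` with columns `time_days`,
#'   `Q_p_ng`, `C_ng_per_ml`, `U_T_ng_per_day`, `K_T`, `V_T_ml`, `V_N_ml`.
#' @examples
#' tr <- solve_serum(default_parameters(), t_end = 600)
#' max(tr$C_ng_per_ml)
#' @export
solve_serum <- function(params, t_end = 2000, dt = 0.5,
                        rtol = 1e-8, atol = 1e-8) {
  params <- validate_parameters(params)
  if (t_end <= 0) stop("t_end must be positive", call. = FALSE)
  times <- seq(0, t_end, by = dt)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  Tn0 <- onset_time(params$Vn0, params, sentinel = TRUE)
  q0 <- params$C_H * params$V_p

  qp <- rep(q0, length(times))
  if (is.finite(Tn0) && Tn0 < t_end) {
    post <- times > Tn0
    sub <- c(Tn0, times[post])
    sol <- deSolve::lsoda(y = c(Q = q0), times = sub, func = .serum_rhs(params),
                          parms = NULL, rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0)
      stop("serum ODE integration failed (istate ",
           attr(sol, "istate")[1], ") for the supplied parameters",
           call. = FALSE)
    qp[post] <- sol[-1, "Q"]
  }
  out <- data.frame(
    time_days      = times,
    Q_p_ng         = qp,
    C_ng_per_ml    = qp / params$V_p,
    U_T_ng_per_day = production_rate(times, params),
    K_T            = transfer_fraction(times, params),
    V_T_ml         = tumour_volume(times, params),
    V_N_ml         = necrotic_volume(times, params)
  )
  attr(out, "Tn0") <- Tn0
  attr(out, "params") <- params
  class(out) <- c("gfap_serum", "data.frame")
  out
}

#' Serum trajectory under a constant tumour input
#'
#' Integrates the serum compartment with the tumour input held at the
#' constant value `K * U` (no growth dynamics), starting from `Q_p(0) = Q0`.
#' The linear ODE has the closed-form solution
#' `C(t) = C_inf + (Q0/V_p - C_inf) * exp(-gamma t)` with
#' `C_inf = (K U + K_H U_H) / (gamma V_p)`, which this numerical route is
#' tested against.
#'
#' @param K Constant transfer fraction.
#' @param U Constant production rate (ng/day).
#' @param params A `gfap_params` object.
#' @param t_end Horizon (days).
#' @param Q0 Initial blood mass (ng); default 0.
#' @param dt Output spacing (days).
#' @return A data frame with columns `time_days`, `C_ng_per_ml`.
#' @examples
#' tr <- solve_serum_constant(0.4, 500, default_parameters(), t_end = 20)
#' @export
solve_serum_constant <- function(K, U, params, t_end = 50, Q0 = 0, dt = 0.1) {
  params <- validate_parameters(params)
  times <- seq(0, t_end, by = dt)
  rhs <- function(t, y, parms)
    list(K * U + .healthy_input(params) - params$gamma * y)
  sol <- deSolve::lsoda(y = c(Q = Q0), times = times, func = rhs,
                        parms = NULL, rtol = 1e-10, atol = 1e-10)
  data.frame(time_days = times, C_ng_per_ml = sol[, "Q"] / params$V_p)
}

#' Healthy baseline serum concentration
#'
#' The steady state of the serum compartment with zero tumour input,
#' `C_H = K_H U_H / gamma` (per unit distribution volume). By construction
#' the healthy input is rederived from `C_H`, so this returns `C_H` itself
#' and equals the long-time limit of [solve_serum()] without necrosis.
#'
#' @param params A `gfap_params` object.
#' @return Baseline concentration in ng/ml.
#' @examples
#' healthy_baseline(default_parameters())  # 0.012
#' @export
healthy_baseline <- function(params) {
  .healthy_input(params) / (params$gamma * params$V_p)
}
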