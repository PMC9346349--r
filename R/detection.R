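#' Detection time and volume at a serum threshold
#'
#' Locates the first upward crossing of the simulated serum concentration
#' through a diagnostic cut-off and converts the crossing time to a tumour
#' volume via the closed-form growth curve. The crossing is found during
#' integration by the root-finding integrator [deSolve::lsodar()] (event
#' location on `C(t) - threshold`), so no post-hoc grid interpolation is
#' involved; the reported `C(t_d)` matches the threshold to integrator
#' tolerance.
#'
#' @param params A `gfap_params` object.
#' @param threshold Serum cut-off in ng/ml; must exceed the patient's healthy
#'   baseline `C_H`.
#' @param t_end Simulation horizon in days.
#' @param rtol,atol Integrator tolerances.
#' @return An object of class `gfap_detection`: a list with `threshold`,
#'   `crossed` (logical), `t_d` (days, `NA` if not crossed) and `V_d` (ml,
#'   `NA` if not crossed).
#' @examples
#' detect(default_parameters(), 0.12)  # the average tumour: V_d = 26 ml
#' @export
detect <- function(params, threshold, t_end = 3000,
                   rtol = 1e-10, atol = 1e-10) {
  params <- validate_parameters(params)
  base <- healthy_baseline(params)
  if (threshold <= base)
    stop("threshold (", threshold, " ng/ml) is at or below the healthy ",
         "baseline C_H (", base, " ng/ml): already above baseline, ",
         "threshold not meaningful for this patient", call. = FALSE)

  Tn0 <- onset_time(params$Vn0, params, sentinel = TRUE)
  res <- list(threshold = threshold, crossed = FALSE,
              t_d = NA_real_, V_d = NA_real_)
  class(res) <- "gfap_detection"
  if (!is.finite(Tn0) || Tn0 >= t_end) return(res)

  q0 <- params$C_H * params$V_p
  rootfun <- function(t, y, parms) y / params$V_p - threshold
  sol <- deSolve::lsodar(y = c(Q = q0), times = c(Tn0, t_end),
                         func = .serum_rhs(params), parms = NULL,
                         rootfunc = rootfun, rtol = rtol, atol = atol)
  troot <- attr(sol, "troot")
  if (is.null(troot) || length(troot) == 0) return(res)

  res$crossed <- TRUE
  res$t_d <- troot[1]
  res$V_d <- tumour_volume(troot[1], params)
  res
}

#' @export
print.gfap_detection <- function(x, ...) {
  if (x$crossed) {
    cat(sprintf(
      "Serum threshold %g ng/ml first crossed at t_d = %.4g days (V_d = %.4g ml)\n",
      x$threshold, x$t_d, x$V_d))
  } else {
    cat(sprintf("Serum threshold %g ng/ml not crossed within the horizon\n",
                x$threshold))
  }
  invisible(x)
}

#' Difference between two detection volumes
#'
#' `delta V_d = |V_d2 - V_d1|`, the change in detection volume between two
#' parameter scenarios.
#'
#' @param result_a,result_b `gfap_detection` objects with `crossed = TRUE`.
#' @return Absolute volume difference in ml.
#' @examples
#' p <- default_parameters()
#' a <- detect(p, 0.12)
#' delta_detection_volume(a, a)  # 0
#' @export
delta_detection_volume <- function(result_a, result_b) {
  if (!isTRUE(result_a$crossed) || !isTRUE(result_b$crossed))
    stop("both scenarios must have crossed their threshold", call. = FALSE)
  abs(result_b$V_d - result_a$V_d)
}

#' Convert an observed serum concentration to a tumour volume
#'
#' Inverts the simulated concentration-volume relationship on its rising limb:
#' the returned volume is the tumour volume at the first time the
#' concentration reaches `C_obs`. Late in growth the curve can flatten and
#' fall (necrosis slows at its plateau), so concentrations above the curve
#' maximum, or at or below the healthy baseline, are reported as outside the
#' invertible range.
#'
#' @param C_obs Observed serum concentration (ng/ml).
#' @param params A `gfap_params` object.
#' @param t_end Simulation horizon in days.
#' @return Tumour volume in ml.
#' @examples
#' p <- default_parameters()
#' volume_from_concentration(0.12, p)  # == detect(p, 0.12)$V_d
#' @export
volume_from_concentration <- function(C_obs, params, t_end = 3000) {
  params <- validate_parameters(params)
  base <- healthy_baseline(params)
  if (C_obs <= base)
    stop("C_obs is at or below the healthy baseline: no tumour information",
         call. = FALSE)
  res <- detect(params, C_obs, t_end = t_end)
  if (!res$crossed)
    stop("C_obs is above the maximum of the simulated concentration curve: ",
         "outside invertible range", call. = FALSE)
  res$V_d
}

#' Steady-state detection boundary in the (K_T, U_T) plane
#'
#' For a constant transfer fraction `K` and constant production rate `U`, the
#' serum compartment settles at `C = C_H + K U / (gamma V_p)`. The minimal
#' production rate whose steady state reaches a threshold is therefore the
#' hyperbola `U*(K) = (threshold - C_H) * gamma * V_p / K`: combinations
#' above the curve are detectable, combinations below are not. Each `U*` is
#' also expressed as the equivalent cell death rate and volumetric death
#' rate.
#'
#' @param K_grid Transfer fractions in `(0, 1]`.
#' @param threshold Serum cut-off (ng/ml), above `C_H`.
#' @param params A `gfap_params` object.
#' @return A data frame with columns `K`, `U_star_ng_per_day`,
#'   `cells_per_day`, `ml_per_day`.
#' @examples
#' detection_boundary(c(0.1, 0.2, 0.4), 0.12, default_parameters())
#' @export
detection_boundary <- function(K_grid, threshold, params) {
  params <- validate_parameters(params)
  if (any(K_grid <= 0) || any(K_grid > 1))
    stop("K values must lie in (0, 1]", call. = FALSE)
  if (threshold <= healthy_baseline(params))
    stop("threshold must exceed the healthy baseline C_H", call. = FALSE)
  u_star <- (threshold - params$C_H) * params$gamma * params$V_p / K_grid
  eq <- cell_rate_equivalent(u_star, params)
  data.frame(K = K_grid, U_star_ng_per_day = u_star,
             cells_per_day = eq$cells_per_day, ml_per_day = eq$ml_per_day)
}

#' Cell and volumetric death-rate equivalents of a production rate
#'
#' Converts a biomarker production rate into the number of cells dying per
#' day (`U / Q_N`) and the corresponding necrotic volume turnover
#' (`U / (Q_N * delta_N)`).
#'
#' @param U Production rate(s) in ng/day, `>= 0`.
#' @param params A `gfap_params` object.
#' @return A data frame with columns `cells_per_day` and `ml_per_day`.
#' @examples
#' cell_rate_equivalent(2000, default_parameters())
#' @export
cell_rate_equivalent <- function(U, params) {
  if (any(U < 0)) stop("U must be non-negative", call. = FALSE)
  data.frame(cells_per_day = U / params$Q_N,
             ml_per_day = U / (params$Q_N * params$delta_N))
}
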