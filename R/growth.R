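#' Gompertzian tumour volume
#'
#' Closed-form Gompertz growth from a single-cell initial volume:
#' `V_T(t) = V_Tmax * exp(log(V_T0/V_Tmax) * exp(-R_T * t))`. The curve is
#' strictly increasing, equals `V_T0` at `t = 0` and approaches the plateau
#' `V_Tmax` as `t -> Inf`.
#'
#' @param t Time(s) since the single-cell origin (days), `>= 0`.
#' @param params A `gfap_params` object.
#' @return Tumour volume(s) in ml.
#' @examples
#' tumour_volume(0, default_parameters())      # one cell
#' tumour_volume(1500, default_parameters())   # near the 158 ml plateau
#' @export
tumour_volume <- function(t, params) {
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  params$V_Tmax * exp(log(params$V_T0 / params$V_Tmax) * exp(-params$R_T * t))
}

#' Time at which the tumour reaches a given volume
#'
#' Analytic inverse of [tumour_volume()]:
#' `t = -log(log(V/V_Tmax) / log(V_T0/V_Tmax)) / R_T`. Used to derive the
#' necrosis onset time `Tn0 = onset_time(Vn0)` and the transfer onset time
#' `Tk0 = onset_time(Vk0)`.
#'
#' Volumes at or above the plateau are unreachable in finite time; `Inf` is
#' returned for the documented no-necrosis sentinel (`V >= V_Tmax`) when
#' `sentinel = TRUE`, otherwise an error is raised.
#'
#' @param V Tumour volume(s) in ml, in `[V_T0, V_Tmax)`.
#' @param params A `gfap_params` object.
#' @param sentinel Return `Inf` instead of erroring for `V >= V_Tmax`.
#' @return Time(s) in days.
#' @examples
#' p <- default_parameters()
#' onset_time(p$Vn0, p)                     # necrosis onset, ~173 days
#' tumour_volume(onset_time(26, p), p)      # round trip: 26 ml
#' @export
onset_time <- function(V, params, sentinel = FALSE) {
  if (any(V < params$V_T0))
    stop("V below the initial (single-cell) volume", call. = FALSE)
  above <- V >= params$V_Tmax
  if (any(above) && !sentinel)
    stop("V at or above the plateau V_Tmax is never reached", call. = FALSE)
  out <- rep(Inf, length(V))
  v <- V[!above]
  out[!above] <- -log(log(v / params$V_Tmax) /
                        log(params$V_T0 / params$V_Tmax)) / params$R_T
  out
}

#' Necrotic core volume
#'
#' Zero before the necrosis onset time `Tn0` (when the tumour reaches `Vn0`),
#' then Gompertzian growth from a single necrotic cell on the shifted clock
#' `t - Tn0`:
#' `V_N(t) = V_Nmax * exp(log(V_N0/V_Nmax) * exp(-R_N * (t - Tn0)))`.
#' The volume is capped at the concurrent tumour volume so that the necrotic
#' core can never exceed the tumour that contains it, even for edge parameter
#' combinations produced by sweeps.
#'
#' @inheritParams tumour_volume
#' @param cap Cap `V_N` at `V_T` (default `TRUE`).
#' @return Necrotic volume(s) in ml.
#' @examples
#' p <- default_parameters()
#' necrotic_volume(onset_time(p$Vn0, p), p)  # one necrotic cell at onset
#' @export
necrotic_volume <- function(t, params, cap = TRUE) {
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  Tn0 <- onset_time(params$Vn0, params, sentinel = TRUE)
  vn <- ifelse(t < Tn0, 0,
               params$V_Nmax * exp(log(params$V_N0 / params$V_Nmax) *
                                     exp(-params$R_N * (t - Tn0))))
  if (cap) vn <- pmin(vn, tumour_volume(t, params))
  vn
}

#' Convert a volume (or volumetric rate) to cells
#'
#' @param V Volume in ml (or ml/day), `>= 0`.
#' @param density Cell density in cells/ml.
#' @return Cell count (or cells/day).
#' @examples
#' cells_from_volume(1, default_parameters()$delta_N)  # 4.8e7 cells
#' @export
cells_from_volume <- function(V, density) {
  if (any(V < 0) || any(density < 0))
    stop("volume and density must be non-negative", call. = FALSE)
  V * density
}

#' Tumour and necrosis growth trajectories
#'
#' Evaluates the closed-form growth laws on a time grid and attaches the
#' derived onset times. Downstream analyses use the closed forms directly;
#' the grid is for inspection and export.
#'
#' @param params A `gfap_params` object.
#' @param times Strictly increasing time grid in days (default: daily over
#'   `[0, 2000]`).
#' @return A data frame of class `gfap_growth` with columns `time_days`,
#'   `V_T_ml`, `V_N_ml`, `N_N_cells`, and attributes `Tn0`, `Tk0`.
#' @examples
#' g <- growth_curve(default_parameters())
#' attr(g, "Tn0")
#' @export
growth_curve <- function(params, times = seq(0, 2000, by = 1)) {
  params <- validate_parameters(params)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing",
                                  call. = FALSE)
  vt <- tumour_volume(times, params)
  vn <- necrotic_volume(times, params)
  out <- data.frame(time_days = times, V_T_ml = vt, V_N_ml = vn,
                    N_N_cells = cells_from_volume(vn, params$delta_N))
  attr(out, "Tn0") <- onset_time(params$Vn0, params, sentinel = TRUE)
  attr(out, "Tk0") <- onset_time(params$Vk0, params, sentinel = TRUE)
  class(out) <- c("gfap_growth", "data.frame")
  out
}
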