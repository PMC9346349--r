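# Blood/serum distribution volume (ml). Fixed once by calibrating the
# all-average forward simulation so that the serum concentration first crosses
# 0.12 ng/ml at a tumour volume of 26 ml (see calibrate_distribution_volume);
# treated as a constant everywhere else.
.VP_CALIBRATED <- 1488.8906

#' Default model parameters for an average glioblastoma
#'
#' Returns the full parameter set of the serum GFAP kinetics model at its
#' population-average values: Gompertzian tumour and necrotic growth, the
#' necrosis-driven GFAP production term, the Hill-type blood-brain-barrier
#' transfer fraction, and the one-compartment serum elimination model.
#'
#' Initial volumes are those of a single cell, `V_T0 = 1/delta_T` and
#' `V_N0 = 1/delta_N`, so that both growth laws start from one viable
#' (respectively necrotic) cell. The blood distribution volume `V_p` is not
#' directly measurable from the published averages; its default is fixed once
#' by calibration (see [calibrate_distribution_volume()]) and then held
#' constant across all analyses.
#'
#' @return An object of class `gfap_params`: a named list with elements
#'   \describe{
#'     \item{R_T, R_N}{initial tumour / necrotic Gompertz growth rates (1/day)}
#'     \item{V_Tmax, V_Nmax}{tumour / necrotic plateau volumes (ml)}
#'     \item{V_T0, V_N0}{initial tumour / necrotic volumes (ml; one cell)}
#'     \item{Vn0, Vk0}{tumour volumes at necrosis onset and at transfer-fraction
#'       onset (ml)}
#'     \item{h}{Hill coefficient of the transfer fraction (dimensionless)}
#'     \item{K_min, K_max}{minimum / maximum transfer fraction in \[0, 1\]}
#'     \item{K_half}{half-saturation time of the transfer fraction (days)}
#'     \item{gamma}{first-order elimination rate of GFAP from blood (1/day)}
#'     \item{C_H}{healthy baseline serum GFAP concentration (ng/ml)}
#'     \item{Q_N}{GFAP mass released per dying cell (ng/cell)}
#'     \item{delta_T, delta_N}{viable / necrotic cell densities (cells/ml)}
#'     \item{V_p}{blood distribution volume (ml)}
#'   }
#' @seealso [validate_parameters()], [load_parameters()], [parameter_ranges()]
#' @examples
#' p <- default_parameters()
#' p$gamma      # 0.7 per day
#' p$Q_N        # 3.1e-4 ng per cell
#' @export
default_parameters <- function() {
  delta_T <- 5.714e7
  delta_N <- 4.8e7
  p <- list(
    R_T     = 0.008,
    R_N     = 0.009,
    V_Tmax  = 158,
    V_Nmax  = 150,
    V_T0    = 1 / delta_T,
    V_N0    = 1 / delta_N,
    Vn0     = 0.5,
    Vk0     = 0.5,
    h       = 7,
    K_min   = 0,
    K_max   = 0.5,
    K_half  = 225,
    gamma   = 0.7,
    C_H     = 0.012,
    Q_N     = 3.1e-4,
    delta_T = delta_T,
    delta_N = delta_N,
    V_p     = .VP_CALIBRATED
  )
  structure(p, class = "gfap_params")
}

#' Published ranges for every ranged model parameter
#'
#' Inclusive `[low, high]` intervals around the population averages, used by
#' the sensitivity sweeps and the virtual-cohort sampler. Parameters without a
#' reported range (densities, initial volumes, `K_min`, `V_p`) are fixed at
#' their defaults.
#'
#' @return A data frame with columns `parameter`, `low`, `average`, `high`.
#' @examples
#' parameter_ranges()
#' @export
parameter_ranges <- function() {
  data.frame(
    parameter = c("R_T", "R_N", "V_Tmax", "V_Nmax", "Vn0", "Vk0", "h",
                  "K_max", "K_half", "gamma", "C_H", "Q_N"),
    low     = c(0.004, 0.005,  72,  70, 0.1, 0.1, 3, 0.3, 100, 0.5, 0,    1.3e-4),
    average = c(0.008, 0.009, 158, 150, 0.5, 0.5, 7, 0.5, 225, 0.7, 0.012, 3.1e-4),
    high    = c(0.01,  0.01,  164, 159, 20,  20,  9, 0.8, 300, 1,   0.11, 5.7e-4),
    stringsAsFactors = FALSE
  )
}

.PARAM_NAMES <- c("R_T", "R_N", "V_Tmax", "V_Nmax", "V_T0", "V_N0", "Vn0",
                  "Vk0", "h", "K_min", "K_max", "K_half", "gamma", "C_H",
                  "Q_N", "delta_T", "delta_N", "V_p")

#' Validate a model parameter set
#'
#' Checks the structural invariants of the kinetics model: positivity of
#' rates, volumes, densities and the distribution volume; `C_H >= 0`;
#' `0 <= K_min <= K_max <= 1`; necrotic containment `V_Nmax < V_Tmax`; and
#' reachability of the onset volumes (`Vn0`, `Vk0` below `V_Tmax`, with
#' `Vn0 >= V_Tmax` permitted as the explicit no-necrosis sentinel).
#'
#' In `strict` mode the half-saturation assumption `K_half > Tk0` (the
#' transfer fraction must still be rising when the barrier first opens) is
#' also enforced, and the sentinel is rejected. The non-strict default leaves
#' that assumption unchecked because late-onset scenarios of practical
#' interest (onset volumes of 20-50 ml) violate it.
#'
#' @param params A `gfap_params` object or plain named list.
#' @param strict Logical; additionally require `K_half > Tk0` and a reachable
#'   necrosis onset (used by [sample_cohort()]).
#' @return `params` (classed) invisibly unchanged if valid; otherwise an error
#'   naming the first violated invariant.
#' @examples
#' validate_parameters(default_parameters())
#' @export
validate_parameters <- function(params, strict = FALSE) {
  p <- unclass(params)
  miss <- setdiff(.PARAM_NAMES, names(p))
  if (length(miss) > 0)
    stop("missing parameter(s): ", paste(miss, collapse = ", "), call. = FALSE)
  num <- vapply(p[.PARAM_NAMES], function(x)
    is.numeric(x) && length(x) == 1 && is.finite(x) || identical(x, Inf),
    logical(1))
  if (!all(num))
    stop("non-numeric parameter: ", .PARAM_NAMES[!num][1], call. = FALSE)

  pos <- c("R_T", "R_N", "V_Tmax", "V_Nmax", "V_T0", "V_N0", "Vn0", "Vk0",
           "h", "K_half", "gamma", "Q_N", "delta_T", "delta_N", "V_p")
  for (nm in pos)
    if (p[[nm]] <= 0) stop(nm, " must be strictly positive", call. = FALSE)
  if (p$C_H < 0) stop("C_H must be non-negative", call. = FALSE)
  if (p$K_min < 0 || p$K_min > 1) stop("K_min out of [0,1]", call. = FALSE)
  if (p$K_max < 0 || p$K_max > 1) stop("K_max out of [0,1]", call. = FALSE)
  if (p$K_min > p$K_max) stop("K_min > K_max", call. = FALSE)
  if (p$V_Nmax >= p$V_Tmax) stop("V_Nmax >= V_Tmax", call. = FALSE)
  if (p$V_T0 >= p$V_Tmax) stop("V_T0 >= V_Tmax", call. = FALSE)
  if (p$V_N0 >= p$V_Nmax) stop("V_N0 >= V_Nmax", call. = FALSE)

  if (strict) {
    if (p$Vn0 >= p$V_Tmax) stop("Vn0 >= V_Tmax (necrosis onset unreachable)",
                                call. = FALSE)
    if (p$Vk0 >= p$V_Tmax) stop("Vk0 >= V_Tmax (transfer onset unreachable)",
                                call. = FALSE)
    tk0 <- onset_time(p$Vk0, structure(p, class = "gfap_params"))
    if (p$K_half <= tk0)
      stop("K_half <= Tk0 (transfer fraction must still be rising at onset)",
           call. = FALSE)
  }
  invisible(structure(p, class = "gfap_params"))
}

#' Load a parameter set from a JSON configuration
#'
#' Reads a flat JSON object mapping parameter names to numbers, overlays it on
#' the defaults, and validates the result. Unknown keys and non-numeric values
#' are rejected so that typos cannot silently fall back to defaults.
#'
#' @param config Path to a JSON file, a JSON string, or a named list/vector of
#'   numeric overrides.
#' @param strict Passed to [validate_parameters()].
#' @return A validated `gfap_params` object.
#' @examples
#' load_parameters(list(R_N = 0.013))
#' @export
load_parameters <- function(config = NULL, strict = FALSE) {
  p <- unclass(default_parameters())
  if (!is.null(config)) {
    if (is.character(config) && length(config) == 1)
      config <- jsonlite::fromJSON(config)
    config <- as.list(config)
    if (length(config) > 0) {
      if (is.null(names(config)) || any(!nzchar(names(config))))
        stop("parameter config must be a named mapping", call. = FALSE)
      unknown <- setdiff(names(config), .PARAM_NAMES)
      if (length(unknown) > 0)
        stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
             call. = FALSE)
      for (nm in names(config)) {
        v <- config[[nm]]
        if (!is.numeric(v) || length(v) != 1)
          stop("parameter ", nm, " must be a single number", call. = FALSE)
        p[[nm]] <- as.numeric(v)
      }
    }
  }
  validate_parameters(p, strict = strict)
}

#' Serialize a parameter set to JSON
#'
#' @param params A `gfap_params` object.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @examples
#' json <- write_parameters(default_parameters())
#' identical(unclass(load_parameters(json)), unclass(default_parameters()))
#' @export
write_parameters <- function(params, path = NULL) {
  params <- validate_parameters(params)
  json <- jsonlite::toJSON(unclass(params), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' Calibrate the blood distribution volume
#'
#' Every serum concentration in the model scales with `1/V_p`, so a single
#' headline observation identifies the distribution volume: here, that the
#' all-average tumour first crosses `threshold` at `target_volume`. The root
#' of `V_d(V_p) - target_volume` is located by [stats::uniroot()]; detection
#' volume is monotone increasing in `V_p` (more dilution, later crossing).
#'
#' The package default `V_p` was produced by this function at its own default
#' arguments and is frozen as a constant; rerunning it is only needed to
#' re-derive or audit that constant.
#'
#' @param target_volume Tumour volume (ml) at which the threshold should first
#'   be crossed.
#' @param threshold Serum cut-off (ng/ml).
#' @param interval Search interval for `V_p` (ml).
#' @param tol Root tolerance (ml).
#' @return The calibrated distribution volume (ml).
#' @examples
#' \donttest{
#' vp <- calibrate_distribution_volume()
#' abs(vp - default_parameters()$V_p) < 0.01
#' }
#' @export
calibrate_distribution_volume <- function(target_volume = 26,
                                          threshold = 0.12,
                                          interval = c(200, 6000),
                                          tol = 1e-5) {
  f <- function(vp) {
    p <- default_parameters()
    p$V_p <- vp
    res <- detect(p, threshold)
    if (!res$crossed) return(1e6)
    res$V_d - target_volume
  }
  stats::uniroot(f, interval = interval, tol = tol)$root
}

#' @export
print.gfap_params <- function(x, ...) {
  cat("Serum biomarker kinetics model parameters\n")
  cat(sprintf("  tumour:    R_T = %g /day, V_Tmax = %g ml, V_T0 = %.3g ml\n",
              x$R_T, x$V_Tmax, x$V_T0))
  cat(sprintf("  necrosis:  R_N = %g /day, V_Nmax = %g ml, onset Vn0 = %g ml\n",
              x$R_N, x$V_Nmax, x$Vn0))
  cat(sprintf("  transfer:  K in [%g, %g], K_half = %g d, h = %g, onset Vk0 = %g ml\n",
              x$K_min, x$K_max, x$K_half, x$h, x$Vk0))
  cat(sprintf("  serum:     gamma = %g /day, C_H = %g ng/ml, V_p = %.4g ml\n",
              x$gamma, x$C_H, x$V_p))
  cat(sprintf("  cells:     Q_N = %.3g ng/cell, delta_T = %.4g, delta_N = %.4g cells/ml\n",
              x$Q_N, x$delta_T, x$delta_N))
  invisible(x)
}
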