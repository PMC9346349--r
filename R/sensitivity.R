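# Evaluate detection volume for a list of parameter sets; shared by all sweeps.
.sweep_eval <- function(param_list, threshold, t_end = 3000) {
  vd <- rep(NA_real_, length(param_list))
  status <- rep("crossed", length(param_list))
  for (i in seq_along(param_list)) {
    res <- detect(param_list[[i]], threshold, t_end = t_end)
    if (res$crossed) vd[i] <- res$V_d else status[i] <- "not_crossed"
  }
  list(V_d = vd, status = status)
}

.sweep_result <- function(grid, vd, status, swept, threshold) {
  out <- cbind(grid, V_d_ml = vd, status = status)
  crossed <- is.finite(vd)
  attr(out, "swept") <- swept
  attr(out, "threshold") <- threshold
  attr(out, "summary") <- list(
    n = nrow(out),
    n_crossed = sum(crossed),
    min_V_d = if (any(crossed)) min(vd[crossed]) else NA_real_,
    max_V_d = if (any(crossed)) max(vd[crossed]) else NA_real_,
    delta_V_d = if (any(crossed)) max(vd[crossed]) - min(vd[crossed])
                else NA_real_
  )
  class(out) <- c("gfap_sweep", "data.frame")
  out
}

#' @export
print.gfap_sweep <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("Detection-volume sweep over %s at threshold %g ng/ml\n",
              paste(attr(x, "swept"), collapse = " x "),
              attr(x, "threshold")))
  cat(sprintf("  %d grid points, %d crossed; V_d in [%.3g, %.3g] ml, delta V_d = %.3g ml\n",
              s$n, s$n_crossed, s$min_V_d, s$max_V_d, s$delta_V_d))
  invisible(x)
}

#' Summary statistics of a sweep
#'
#' @param object A `gfap_sweep` object.
#' @param ... Unused.
#' @return A list with `n`, `n_crossed`, `min_V_d`, `max_V_d` and
#'   `delta_V_d = max - min` over crossed points (ml).
#' @export
summary.gfap_sweep <- function(object, ...) attr(object, "summary")

#' Local one-parameter sensitivity sweep
#'
#' Varies a single parameter over supplied values with everything else held
#' at the base (by default, population-average) values, and records the
#' detection volume at each point. Values outside the published range for
#' that parameter produce a warning, not an error, since published scenarios
#' themselves step outside the ranges (e.g. a rapid-necrosis rate of
#' 0.013/day).
#'
#' @param name Parameter name (one of the ranged parameters; `"Vn0"` sweeps
#'   the tied pair `Vn0 = Vk0`).
#' @param values Numeric values to sweep.
#' @param threshold Serum cut-off (ng/ml).
#' @param params Base parameter set.
#' @param t_end Simulation horizon (days).
#' @return A `gfap_sweep` data frame (one row per value).
#' @examples
#' local_sweep("Q_N", c(1.3e-4, 3.1e-4, 5.7e-4))
#' @export
local_sweep <- function(name, values, threshold = 0.12,
                        params = default_parameters(), t_end = 3000) {
  rng <- parameter_ranges()
  if (name %in% rng$parameter) {
    r <- rng[rng$parameter == name, ]
    if (any(values < r$low | values > r$high))
      warning("some values lie outside the published range [",
              r$low, ", ", r$high, "] for ", name, call. = FALSE)
  } else if (!name %in% .PARAM_NAMES) {
    stop("unknown parameter: ", name, call. = FALSE)
  }
  plist <- lapply(values, function(v) {
    p <- params
    p[[name]] <- v
    if (name == "Vn0") p$Vk0 <- v
    p
  })
  ev <- .sweep_eval(plist, threshold, t_end)
  grid <- stats::setNames(data.frame(values), name)
  .sweep_result(grid, ev$V_d, ev$status, name, threshold)
}

#' Factorial sweep over the transfer-fraction parameters
#'
#' Full-factorial grid over the three parameters of the Hill transfer
#' fraction (`K_max`, `K_half`, `h`), all other parameters at their base
#' values. The defaults cover the published ranges at 11 points per axis.
#'
#' @param K_max_values,K_half_values,h_values Grid axes.
#' @param threshold Serum cut-off (ng/ml).
#' @param params Base parameter set.
#' @param t_end Simulation horizon (days).
#' @return A `gfap_sweep` data frame (one row per grid point).
#' @examples
#' kt_sweep(0.5, 225, 7)  # degenerate 1x1x1 grid: delta V_d = 0
#' @export
kt_sweep <- function(K_max_values = seq(0.3, 0.8, length.out = 11),
                     K_half_values = seq(100, 300, length.out = 11),
                     h_values = seq(3, 9, length.out = 11),
                     threshold = 0.12, params = default_parameters(),
                     t_end = 3000) {
  grid <- expand.grid(K_max = K_max_values, K_half = K_half_values,
                      h = h_values, KEEP.OUT.ATTRS = FALSE)
  plist <- lapply(seq_len(nrow(grid)), function(i) {
    p <- params
    p$K_max <- grid$K_max[i]
    p$K_half <- grid$K_half[i]
    p$h <- grid$h[i]
    p
  })
  ev <- .sweep_eval(plist, threshold, t_end)
  .sweep_result(grid, ev$V_d, ev$status, c("K_max", "K_half", "h"), threshold)
}

#' Constrained sweep over tumour and necrosis growth parameters
#'
#' Crosses a grid of tumour growth parameter combinations (`V_Tmax`, `R_T`)
#' with a grid of necrosis combinations (`V_Nmax`, `R_N`, `Vn0`; the transfer
#' onset `Vk0` is tied to `Vn0`). Combinations violating the containment
#' constraint `V_Nmax < V_Tmax` (or any other structural invariant) are
#' flagged `"excluded"` and not simulated.
#'
#' @param tumour_grid Data frame with columns `V_Tmax`, `R_T`.
#' @param necrosis_grid Data frame with columns `V_Nmax`, `R_N`, `Vn0`.
#' @param threshold Serum cut-off (ng/ml).
#' @param params Base parameter set.
#' @param t_end Simulation horizon (days).
#' @return A `gfap_sweep` data frame (one row per admissible or excluded
#'   combination).
#' @examples
#' growth_necrosis_sweep(
#'   data.frame(V_Tmax = 158, R_T = 0.008),
#'   data.frame(V_Nmax = 150, R_N = c(0.005, 0.009), Vn0 = 0.5))
#' @export
growth_necrosis_sweep <- function(tumour_grid, necrosis_grid,
                                  threshold = 0.12,
                                  params = default_parameters(),
                                  t_end = 3000) {
  stopifnot(all(c("V_Tmax", "R_T") %in% names(tumour_grid)),
            all(c("V_Nmax", "R_N", "Vn0") %in% names(necrosis_grid)))
  idx <- expand.grid(i = seq_len(nrow(tumour_grid)),
                     j = seq_len(nrow(necrosis_grid)))
  grid <- cbind(tumour_grid[idx$i, c("V_Tmax", "R_T"), drop = FALSE],
                necrosis_grid[idx$j, c("V_Nmax", "R_N", "Vn0"), drop = FALSE])
  rownames(grid) <- NULL

  n <- nrow(grid)
  vd <- rep(NA_real_, n)
  status <- rep("excluded", n)
  for (i in seq_len(n)) {
    p <- params
    p$V_Tmax <- grid$V_Tmax[i]; p$R_T <- grid$R_T[i]
    p$V_Nmax <- grid$V_Nmax[i]; p$R_N <- grid$R_N[i]
    p$Vn0 <- grid$Vn0[i];       p$Vk0 <- grid$Vn0[i]
    ok <- tryCatch({ validate_parameters(p); TRUE },
                   error = function(e) FALSE)
    if (!ok || p$Vn0 >= p$V_Tmax) next
    res <- detect(p, threshold, t_end = t_end)
    if (res$crossed) { vd[i] <- res$V_d; status[i] <- "crossed" }
    else status[i] <- "not_crossed"
  }
  .sweep_result(grid, vd, status,
                c("V_Tmax", "R_T", "V_Nmax", "R_N", "Vn0"), threshold)
}

#' Simultaneous sweep over the patient baseline parameters
#'
#' Factorial grid over the healthy baseline concentration `C_H` and the
#' elimination rate `gamma` with an average tumour. These two parameters are
#' properties of the patient, not the tumour, yet shift the detection volume.
#'
#' @param C_H_values Baseline concentrations (ng/ml), all `< threshold`.
#' @param gamma_values Elimination rates (1/day).
#' @param threshold Serum cut-off (ng/ml).
#' @param params Base parameter set.
#' @param t_end Simulation horizon (days).
#' @return A `gfap_sweep` data frame.
#' @examples
#' baseline_sweep(c(0, 0.012, 0.05), c(0.5, 0.7, 1))
#' @export
baseline_sweep <- function(C_H_values = seq(0, 0.11, length.out = 11),
                           gamma_values = seq(0.5, 1, length.out = 11),
                           threshold = 0.12,
                           params = default_parameters(), t_end = 3000) {
  if (any(C_H_values < 0) || any(C_H_values >= threshold))
    stop("C_H values must lie in [0, threshold)", call. = FALSE)
  grid <- expand.grid(C_H = C_H_values, gamma = gamma_values,
                      KEEP.OUT.ATTRS = FALSE)
  plist <- lapply(seq_len(nrow(grid)), function(i) {
    p <- params
    p$C_H <- grid$C_H[i]
    p$gamma <- grid$gamma[i]
    p
  })
  ev <- .sweep_eval(plist, threshold, t_end)
  .sweep_result(grid, ev$V_d, ev$status, c("C_H", "gamma"), threshold)
}

# Evaluate expr with a temporary RNG state seeded by `seed`.
.with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Sample a virtual-patient cohort
#'
#' Draws parameter sets independently and uniformly within the published
#' ranges, with the transfer onset tied to the necrosis onset
#' (`Vk0 = Vn0`, matching the model assumption that barrier damage and
#' necrosis begin together). Draws violating the structural constraints
#' (necrotic containment, reachable onset, `K_half > Tk0`) are rejected and
#' redrawn, so every returned member passes strict validation. Reproducible
#' for a fixed seed; the caller's RNG state is left untouched.
#'
#' @param n Number of patients, `>= 1`.
#' @param seed Integer seed.
#' @return An object of class `gfap_cohort`: list with `seed`, `draws` (data
#'   frame of sampled values, one row per patient) and `params` (list of
#'   validated `gfap_params`).
#' @examples
#' cohort <- sample_cohort(5, seed = 42)
#' cohort$draws$R_T
#' @export
sample_cohort <- function(n, seed) {
  stopifnot(n >= 1)
  rng <- parameter_ranges()
  rng <- rng[rng$parameter != "Vk0", ]  # tied to Vn0
  draw_one <- function() {
    v <- stats::setNames(
      stats::runif(nrow(rng), rng$low, rng$high), rng$parameter)
    p <- unclass(default_parameters())
    p[names(v)] <- v
    p$Vk0 <- p$Vn0
    p
  }
  params <- vector("list", n)
  .with_seed(seed, {
    for (i in seq_len(n)) {
      for (attempt in seq_len(10000)) {
        p <- draw_one()
        ok <- tryCatch({ validate_parameters(p, strict = TRUE); TRUE },
                       error = function(e) FALSE)
        if (ok) break
        p <- NULL
      }
      if (is.null(p))
        stop("could not draw an admissible parameter set", call. = FALSE)
      params[[i]] <- structure(p, class = "gfap_params")
    }
  })
  draws <- do.call(rbind, lapply(params, function(p)
    as.data.frame(unclass(p))))
  structure(list(seed = seed, draws = draws, params = params),
            class = "gfap_cohort")
}

#' @export
print.gfap_cohort <- function(x, ...) {
  cat(sprintf("Virtual cohort: %d parameter sets (seed %d)\n",
              nrow(x$draws), x$seed))
  invisible(x)
}
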