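#' Kinetic rate constants of the two-tissue-compartment FDG model
#'
#' `K1` (ml/ml/min) is blood-to-tissue transport, `k2` (1/min) tissue-to-blood
#' efflux, `k3` (1/min) phosphorylation of FDG to FDG-6-phosphate, and `k4`
#' (1/min) dephosphorylation. All rates are per minute and non-negative.
#'
#' @param K1,k2,k3,k4 non-negative rate constants.
#' @return A named numeric vector of class `kinetic_params`.
#' @export
kinetic_params <- function(K1, k2, k3, k4 = 0) {
  p <- c(K1 = as.numeric(K1), k2 = as.numeric(k2),
         k3 = as.numeric(k3), k4 = as.numeric(k4))
  if (any(!is.finite(p)) || any(p < 0))
    stop("kinetic constants must be finite and non-negative")
  structure(p, class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("K1 = %.4g ml/ml/min, k2 = %.4g, k3 = %.4g, k4 = %.4g (1/min)\n",
              x["K1"], x["k2"], x["k3"], x["k4"]))
  invisible(x)
}

# Eigenrates of the two-tissue system and the kernel coefficients.
# h(t) = K1/(a2-a1) * [(k3+k4-a1) e^(-a1 t) + (a2-k3-k4) e^(-a2 t)],
# a_{1,2} = ((k2+k3+k4) -/+ sqrt((k2+k3+k4)^2 - 4 k2 k4)) / 2.
# When the discriminant vanishes the kernel degenerates to the confluent
# form K1 e^(-a t) [1 + (k3+k4-a) t]; the `repeated` flag marks that case.

#' Impulse response of the two-tissue-compartment model
#'
#' Returns the coefficients of the tissue impulse response
#' `h(t) = A1 exp(-a1 t) + A2 exp(-a2 t)` (or its confluent limit
#' `exp(-a t) (A + B t)` at a repeated eigenrate), such that the total
#' tissue curve is the convolution of the plasma input with `h`.
#' `h(0) = K1` always; `h(t) >= 0` for all `t >= 0`.
#'
#' @param params a [kinetic_params()].
#' @return A list with `alphas` (eigenrates, 1/min), `amps` (amplitudes),
#'   `repeated` (logical), and for the repeated case `slope` (the
#'   coefficient of the `t exp(-a t)` term).
#' @export
impulse_response <- function(params) {
  p <- unclass(params)
  K1 <- p[["K1"]]; k2 <- p[["k2"]]; k3 <- p[["k3"]]; k4 <- p[["k4"]]
  s <- k2 + k3 + k4
  disc <- s^2 - 4 * k2 * k4
  disc <- max(disc, 0)
  rt <- sqrt(disc)
  a1 <- (s - rt) / 2
  a2 <- (s + rt) / 2
  # repeated root: relative gap below sqrt(eps) of the scale
  if (rt <= sqrt(.Machine$double.eps) * max(s, 1)) {
    a <- s / 2
    list(alphas = c(a, a), amps = c(K1, 0), slope = K1 * (k3 + k4 - a),
         repeated = TRUE)
  } else {
    A1 <- K1 * (k3 + k4 - a1) / (a2 - a1)
    A2 <- K1 * (a2 - (k3 + k4)) / (a2 - a1)
    list(alphas = c(a1, a2), amps = c(A1, A2), slope = 0, repeated = FALSE)
  }
}

#' Evaluate the impulse response at given times
#'
#' @param params a [kinetic_params()].
#' @param t_min times in minutes.
#' @return h(t) values.
#' @export
impulse_response_at <- function(params, t_min) {
  ir <- impulse_response(params)
  if (ir$repeated) {
    exp(-ir$alphas[1] * t_min) * (ir$amps[1] + ir$slope * t_min)
  } else {
    ir$amps[1] * exp(-ir$alphas[1] * t_min) +
      ir$amps[2] * exp(-ir$alphas[2] * t_min)
  }
}

# A curve sampled at frame mid-times extends flat over the tail of the last
# frame by the interpolation contract; anything shorter than the last frame
# start is a genuine coverage failure.
check_coverage <- function(input_fn, schedule) {
  last_start <- schedule$start_s[length(schedule)]
  if (max(input_fn$times_s) < last_start - 1e-6)
    stop("input function covers only ", max(input_fn$times_s),
         " s but the schedule extends to ", max(schedule$end_s), " s")
  invisible(TRUE)
}

# Internal fine time grid (minutes) covering a schedule, and the frame
# averaging operator over it. dt_s = 1 s by default; all frame boundaries in
# the supported schedules are whole seconds, so trapezoidal frame means are
# exact for the piecewise-linear model output.
make_time_grid <- function(schedule, dt_s = 1) {
  t_end <- max(schedule$end_s)
  t_s <- seq(0, t_end, by = dt_s)
  starts <- round(schedule$start_s / dt_s) + 1L
  ends <- round(schedule$end_s / dt_s) + 1L
  list(t_min = t_s / 60, dt_min = dt_s / 60, starts = starts, ends = ends)
}

# Trapezoidal mean of the fine-grid curve over each frame interval.
frame_average <- function(ct, grid) {
  .tcm_frame_means(ct, grid$starts, grid$ends)
}

# Tissue curve on the fine grid for given params and fine-grid plasma input.
# The convolution recursion runs in compiled code (src/tcm.cpp); it is exact
# for a piecewise-linear input.
tissue_curve_fine <- function(params, cp_fine, dt_min) {
  p <- unclass(params)
  .tcm_tissue_curve(cp_fine, dt_min, p[["K1"]], p[["k2"]], p[["k3"]],
                    p[["k4"]])
}

#' Predict a frame-averaged tissue time--activity curve
#'
#' Computes the total tissue concentration `C_T = C_P (x) h` by exact
#' convolution of the piecewise-linear plasma input with the model's
#' exponential kernel on a fine internal grid (1 s), then averages over each
#' frame interval -- matching how PET frames integrate activity.
#'
#' @param params a [kinetic_params()].
#' @param input_fn an [input_function()] covering the schedule.
#' @param schedule a [frame_schedule()].
#' @param dt_s internal grid step in seconds.
#' @return numeric vector of per-frame mean activities (kBq/ml).
#' @export
predict_tac <- function(params, input_fn, schedule, dt_s = 1) {
  stopifnot(inherits(schedule, "frame_schedule"))
  check_coverage(input_fn, schedule)
  grid <- make_time_grid(schedule, dt_s)
  cp <- evaluate_input_function(input_fn, grid$t_min * 60)
  ct <- tissue_curve_fine(params, cp, grid$dt_min)
  frame_average(ct, grid)
}

#' Tissue curve by numerical ODE integration (cross-check route)
#'
#' Integrates the two-tissue state equations
#' `dC_E/dt = K1 C_P - (k2 + k3) C_E + k4 C_M`,
#' `dC_M/dt = k3 C_E - k4 C_M`
#' with a stiff solver and returns frame means of `C_T = C_E + C_M`. This is
#' an independent route to the same prediction as [predict_tac()] and is used
#' to validate the analytic convolution; it is far too slow for voxel-wise
#' fitting.
#'
#' @inheritParams predict_tac
#' @param rtol,atol solver tolerances.
#' @return numeric vector of per-frame mean activities.
#' @export
predict_tac_ode <- function(params, input_fn, schedule, rtol = 1e-10,
                            atol = 1e-12) {
  p <- unclass(params)
  grid <- make_time_grid(schedule, dt_s = 1)
  deriv <- function(t, y, parms) {
    cp <- evaluate_input_function(input_fn, t * 60)
    list(c(p[["K1"]] * cp - (p[["k2"]] + p[["k3"]]) * y[1] + p[["k4"]] * y[2],
           p[["k3"]] * y[1] - p[["k4"]] * y[2]))
  }
  sol <- deSolve::lsoda(c(CE = 0, CM = 0), grid$t_min, deriv, NULL,
                        rtol = rtol, atol = atol)
  ct <- sol[, "CE"] + sol[, "CM"]
  frame_average(ct, grid)
}

#' Glucose-transport ratio CE/CP
#'
#' The steady-state ratio of free tissue tracer to plasma tracer,
#' `CE/CP = K1 / (k2 + k3 / LC)` with lumped factor `LC = 0.26` by default.
#' Increased glucose transport accompanies neuronal activation while being
#' relatively insensitive to plasma glucose, so this ratio serves as the
#' activation surrogate in voxel-wise group comparisons.
#'
#' @param params a [kinetic_params()] (or any named vector with K1, k2, k3).
#' @param lumped_factor positive dimensionless divisor applied to k3.
#' @return The dimensionless ratio.
#' @examples
#' glucose_transport_ratio(kinetic_params(0.1, 0.2, 0.052))  # 0.25
#' @export
glucose_transport_ratio <- function(params, lumped_factor = 0.26) {
  if (!is.numeric(lumped_factor) || lumped_factor <= 0)
    stop("lumped_factor must be positive")
  p <- unclass(params)
  denom <- p[["k2"]] + p[["k3"]] / lumped_factor
  if (any(denom <= 0))
    stop("CE/CP undefined: k2 + k3/lumped_factor must be positive")
  unname(p[["K1"]] / denom)
}
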