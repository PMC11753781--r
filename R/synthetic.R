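# Seeded generators for every input the pipeline consumes: plasma input
# functions, kinetic phantoms with group effects, fluorescence/firing-rate
# traces, and behavioral tables. All generators are pure functions of their
# arguments: RNG state is saved and restored around each draw.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a parametric plasma input function
#'
#' A sum-of-exponentials bolus: each decaying term `A_i exp(-r_i tau)` is
#' paired with a common fast rising edge, giving
#' `C_P(tau) = sum_i A_i (exp(-r_i tau) - exp(-r_rise tau))` for
#' `tau = t - delay` (zero before the delay). With `r_rise` at least as large
#' as every decay rate and non-negative amplitudes the curve is non-negative
#' everywhere and zero at injection. The defaults emulate a mouse FDG bolus:
#' a sharp peak inside the first minute followed by a fast washout and a slow
#' metabolic tail over the 43-minute acquisition.
#'
#' @param amplitude_params non-negative amplitudes (kBq/ml), one per decay
#'   term.
#' @param rate_params strictly positive decay rates (1/min), one per term.
#' @param rise_rate rate of the rising edge (1/min); must be >= all decay
#'   rates.
#' @param delay_min delay between scan start and injection, minutes >= 0.
#' @param schedule a [frame_schedule()] the curve must cover.
#' @param dt_s sampling step of the returned curve, seconds.
#' @return An [input_function()] densely sampled on `[0, end of schedule]`.
#' @export
generate_input_function <- function(amplitude_params = c(35, 6),
                                    rate_params = c(2, 0.02),
                                    rise_rate = 5, delay_min = 0.25,
                                    schedule = fdg_frame_schedule(),
                                    dt_s = 1) {
  if (length(schedule) == 0L) stop("schedule must not be empty")
  if (length(amplitude_params) != length(rate_params))
    stop("one amplitude per decay rate required")
  if (any(rate_params <= 0)) stop("decay rates must be strictly positive")
  if (any(amplitude_params < 0)) stop("amplitudes must be non-negative")
  if (rise_rate < max(rate_params))
    stop("rise_rate must be >= every decay rate (non-negativity)")
  if (delay_min < 0) stop("delay must be >= 0")
  t_s <- seq(0, max(schedule$end_s), by = dt_s)
  tau <- pmax((t_s - delay_min * 60) / 60, 0)
  v <- rep(0, length(t_s))
  for (i in seq_along(amplitude_params))
    v <- v + amplitude_params[i] *
      (exp(-rate_params[i] * tau) - exp(-rise_rate * tau))
  input_function(t_s, pmax(v, 0))
}

#' Phantom specification
#'
#' Describes a digital FDG phantom: grid, voxel spacing, labelled tissue
#' regions each carrying one set of kinetic constants, a blood-pool region,
#' a multiplicative noise level, and group effects (per-region K1
#' multipliers applied to the second group of a study).
#'
#' @param grid_shape integer length-3 voxel counts.
#' @param voxel_spacing_mm three positive lengths; default the scanner's
#'   0.4 x 0.4 x 0.8 mm.
#' @param regions named list; each element a list with `voi` (a [voi()]) and
#'   `params` (a [kinetic_params()]). Regions must be pairwise disjoint.
#' @param blood_region a [voi()] of blood-pool voxels, disjoint from all
#'   tissue regions.
#' @param noise_cv fractional standard deviation of multiplicative Gaussian
#'   frame noise, >= 0.
#' @param group_effects named numeric vector of K1 multipliers keyed by
#'   region label (applied by [generate_group_study()]).
#' @param seed integer seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape, voxel_spacing_mm = c(0.4, 0.4, 0.8),
                         regions, blood_region = NULL, noise_cv = 0.05,
                         group_effects = numeric(0), seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L))
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (length(regions) == 0L || is.null(names(regions)))
    stop("regions must be a named list")
  all_lin <- integer(0)
  for (nm in names(regions)) {
    r <- regions[[nm]]
    stopifnot(inherits(r$voi, "voi"), inherits(r$params, "kinetic_params"))
    check_voi_in_grid(r$voi, grid_shape)
    all_lin <- c(all_lin, voi_linear_index(r$voi, grid_shape))
  }
  if (!is.null(blood_region)) {
    check_voi_in_grid(blood_region, grid_shape)
    all_lin <- c(all_lin, voi_linear_index(blood_region, grid_shape))
  }
  if (anyDuplicated(all_lin))
    stop("regions (including the blood region) must be disjoint")
  if (length(group_effects) &&
      !all(names(group_effects) %in% names(regions)))
    stop("group_effects name regions that do not exist")
  structure(list(grid_shape = grid_shape,
                 voxel_spacing_mm = as.numeric(voxel_spacing_mm),
                 regions = regions, blood_region = blood_region,
                 noise_cv = noise_cv, group_effects = group_effects,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Rectangular-box VOI helper
#'
#' @param x,y,z integer ranges (e.g. `3:8`) of included voxel indices.
#' @param label VOI label.
#' @return A [voi()] covering the box.
#' @export
box_voi <- function(x, y, z, label = "box") {
  voi(as.matrix(expand.grid(x = x, y = y, z = z)), label = label)
}

#' Default desk-scale phantom
#'
#' A 20 x 20 x 10 grid at 0.4 x 0.4 x 0.8 mm with three tissue regions of
#' distinct gray/white-matter-like kinetics, a small blood pool, 5% frame
#' noise, and a 15% K1 elevation of the `striatum` region as the default
#' group effect.
#'
#' @param seed integer seed.
#' @param noise_cv noise level override.
#' @param group_effects group-effect override.
#' @return A [phantom_spec()].
#' @export
default_phantom_spec <- function(seed = 1L, noise_cv = 0.05,
                                 group_effects = c(striatum = 1.15)) {
  phantom_spec(
    grid_shape = c(20, 20, 10),
    regions = list(
      cortex = list(voi = box_voi(3:8, 3:8, 2:5, "cortex"),
                    params = kinetic_params(0.12, 0.25, 0.06, 0.006)),
      striatum = list(voi = box_voi(12:17, 3:8, 2:5, "striatum"),
                      params = kinetic_params(0.10, 0.20, 0.05, 0.008)),
      white = list(voi = box_voi(3:8, 12:17, 5:8, "white"),
                   params = kinetic_params(0.06, 0.18, 0.03, 0.01))),
    blood_region = box_voi(13:16, 13:16, 6:8, "blood"),
    noise_cv = noise_cv, group_effects = group_effects, seed = seed)
}

#' Compact phantom for power studies
#'
#' A 10 x 10 x 5 grid with a small `target` region (the one carrying the
#' group effect), a `reference` region and a blood pool. Small enough that a
#' full two-group study (n = 8 vs 8) fits in seconds, which makes repeated
#' seeded power simulations practical.
#'
#' @param seed integer seed.
#' @param noise_cv frame noise level.
#' @param effect K1 multiplier applied to the target region in group B.
#' @return A [phantom_spec()].
#' @export
compact_phantom_spec <- function(seed = 1L, noise_cv = 0.05,
                                 effect = 1.15) {
  phantom_spec(
    grid_shape = c(10, 10, 5),
    regions = list(
      target = list(voi = box_voi(2:4, 2:4, 2:3, "target"),
                    params = kinetic_params(0.10, 0.20, 0.05, 0.008)),
      reference = list(voi = box_voi(7:9, 2:4, 2:3, "reference"),
                       params = kinetic_params(0.12, 0.25, 0.06, 0.006))),
    blood_region = box_voi(7:9, 7:9, 4:5, "blood"),
    noise_cv = noise_cv, group_effects = c(target = effect), seed = seed)
}

#' Simulate a dynamic phantom image
#'
#' Every tissue voxel carries the frame-averaged two-tissue-compartment
#' prediction for its region's constants; blood-pool voxels carry the
#' frame-averaged input function scaled by the standardized volume fraction
#' 0.6 (so that [pve_correct()] on the extracted blood TAC exactly inverts
#' the construction); unassigned voxels are zero. Multiplicative Gaussian
#' noise of CV `noise_cv` is applied to every frame value.
#'
#' @param spec a [phantom_spec()].
#' @param input_fn an [input_function()] covering the default schedule.
#' @param schedule a [frame_schedule()].
#' @param k1_multipliers optional named numeric vector of per-region K1
#'   multipliers (used for group-B animals).
#' @param seed seed override; defaults to `spec$seed`.
#' @param volume_fraction blood-pool recovery fraction.
#' @return A list with `image` (a [dynamic_image()]) and `truth` (a
#'   `parametric_map` holding the assigned constants per voxel).
#' @export
generate_phantom <- function(spec, input_fn,
                             schedule = fdg_frame_schedule(),
                             k1_multipliers = NULL, seed = NULL,
                             volume_fraction = 0.6) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(seed)) seed <- spec$seed
  grid <- make_time_grid(schedule)
  cp_fine <- evaluate_input_function(input_fn, grid$t_min * 60)
  nfr <- length(schedule)
  nvox <- prod(spec$grid_shape)
  flat <- matrix(0, nrow = nvox, ncol = nfr)

  blank <- array(NA_real_, dim = spec$grid_shape)
  truth <- list(K1 = blank, k2 = blank, k3 = blank, k4 = blank,
                CEoverCP = blank, fit_rss = blank,
                converged = array(FALSE, dim = spec$grid_shape),
                voxel_spacing_mm = spec$voxel_spacing_mm)

  for (nm in names(spec$regions)) {
    r <- spec$regions[[nm]]
    p <- unclass(r$params)
    if (!is.null(k1_multipliers) && nm %in% names(k1_multipliers))
      p[["K1"]] <- p[["K1"]] * k1_multipliers[[nm]]
    params <- kinetic_params(p[["K1"]], p[["k2"]], p[["k3"]], p[["k4"]])
    tac <- frame_average(tissue_curve_fine(params, cp_fine, grid$dt_min),
                         grid)
    lin <- voi_linear_index(r$voi, spec$grid_shape)
    flat[lin, ] <- matrix(tac, nrow = length(lin), ncol = nfr, byrow = TRUE)
    truth$K1[lin] <- p[["K1"]]; truth$k2[lin] <- p[["k2"]]
    truth$k3[lin] <- p[["k3"]]; truth$k4[lin] <- p[["k4"]]
    truth$CEoverCP[lin] <- glucose_transport_ratio(params)
    truth$converged[lin] <- TRUE
  }
  if (!is.null(spec$blood_region)) {
    if_frames <- frame_average(cp_fine, grid)
    lin <- voi_linear_index(spec$blood_region, spec$grid_shape)
    flat[lin, ] <- matrix(volume_fraction * if_frames,
                          nrow = length(lin), ncol = nfr, byrow = TRUE)
  }
  if (spec$noise_cv > 0)
    flat <- with_seed(seed,
      flat * (1 + spec$noise_cv * matrix(stats::rnorm(length(flat)),
                                         nrow = nvox)))
  class(truth) <- "parametric_map"
  list(image = dynamic_image(array(flat, dim = c(spec$grid_shape, nfr)),
                             spec$voxel_spacing_mm, schedule),
       truth = truth)
}

#' Simulate a two-group phantom study
#'
#' Draws `n_per_group` phantom animals per group from a common spec; group B
#' animals additionally carry the spec's `group_effects` K1 multipliers.
#' Per-animal seeds are `seed + animal index`, with group B indices
#' following group A's, so the study is reproducible animal by animal.
#'
#' @param spec a [phantom_spec()].
#' @param input_fn shared [input_function()].
#' @param n_per_group animals per group, >= 2.
#' @param seed study seed; default `spec$seed`.
#' @param schedule a [frame_schedule()].
#' @return A list with `group_a`, `group_b` (lists of [dynamic_image()]),
#'   `truth_a`, `truth_b` (parametric truth maps) and `spec`.
#' @export
generate_group_study <- function(spec, input_fn, n_per_group = 8,
                                 seed = NULL,
                                 schedule = fdg_frame_schedule()) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (n_per_group < 2) stop("need n_per_group >= 2 for group statistics")
  if (is.null(seed)) seed <- spec$seed
  ga <- lapply(seq_len(n_per_group), function(i)
    generate_phantom(spec, input_fn, schedule, seed = seed + i))
  gb <- lapply(seq_len(n_per_group), function(i)
    generate_phantom(spec, input_fn, schedule,
                     k1_multipliers = spec$group_effects,
                     seed = seed + n_per_group + i))
  list(group_a = lapply(ga, `[[`, "image"),
       group_b = lapply(gb, `[[`, "image"),
       truth_a = ga[[1]]$truth, truth_b = gb[[1]]$truth, spec = spec)
}

#' Trace specification for synthetic GCaMP recordings
#'
#' @param sampling_interval_s sampling step, seconds.
#' @param baseline_level resting fluorescence, AU.
#' @param bleach_rate photobleaching rate, 1/min, >= 0.
#' @param response_amplitude added fluorescence of a responder during the
#'   agonist window, AU.
#' @param response_window `(start, end)` seconds of the agonist application
#'   (default an 8-minute window starting at 10 min).
#' @param highK_amplitude deflection of the terminal high-potassium
#'   depolarization, AU, > 0.
#' @param highK_window `(start, end)` seconds of the high-K+ application.
#' @param noise_sd additive Gaussian noise SD, AU.
#' @param duration_s total recording length.
#' @param seed integer seed.
#' @return An object of class `trace_spec`.
#' @export
trace_spec <- function(sampling_interval_s = 5, baseline_level = 1000,
                       bleach_rate = 0.02, response_amplitude = 150,
                       response_window = c(600, 1080),
                       highK_amplitude = 600,
                       highK_window = c(1500, 1620),
                       noise_sd = 20, duration_s = 1800, seed = 1L) {
  if (bleach_rate < 0) stop("bleach_rate must be >= 0")
  if (highK_amplitude <= 0) stop("highK_amplitude must be > 0")
  if (diff(response_window) <= 0 || diff(highK_window) <= 0)
    stop("windows must be ordered (start < end)")
  if (response_window[2] > highK_window[1])
    stop("response and high-K+ windows must not overlap")
  if (highK_window[2] > duration_s)
    stop("windows must lie within the recording")
  structure(list(sampling_interval_s = sampling_interval_s,
                 baseline_level = baseline_level, bleach_rate = bleach_rate,
                 response_amplitude = response_amplitude,
                 response_window = response_window,
                 highK_amplitude = highK_amplitude,
                 highK_window = highK_window, noise_sd = noise_sd,
                 duration_s = duration_s, seed = as.integer(seed)),
            class = "trace_spec")
}

#' Simulate GCaMP fluorescence traces with known responder labels
#'
#' Every trace carries a bleaching trend
#' `baseline_level * exp(-bleach_rate * t)`, the terminal high-K+
#' deflection, and additive Gaussian noise. The first
#' `round(n * responder_fraction)` traces additionally carry
#' `response_amplitude` during the agonist window.
#'
#' @param spec a [trace_spec()].
#' @param n number of traces, >= 0.
#' @param responder_fraction proportion in `[0, 1]`.
#' @return A list with `traces` (list of [trace()] objects, annotated with
#'   `baseline`, `response` and `highK` windows) and `is_responder`
#'   (logical ground-truth labels).
#' @export
generate_traces <- function(spec, n, responder_fraction = 0.5) {
  stopifnot(inherits(spec, "trace_spec"))
  if (n < 0) stop("n must be >= 0")
  if (responder_fraction < 0 || responder_fraction > 1)
    stop("responder_fraction must be in [0, 1]")
  n_resp <- round(n * responder_fraction)
  labels <- seq_len(n) <= n_resp
  t_s <- seq(0, spec$duration_s, by = spec$sampling_interval_s)
  rw <- spec$response_window
  windows <- list(baseline = c(rw[1] - 240, rw[1]),
                  response = c(rw[2] - 240, rw[2]),
                  highK = spec$highK_window)
  traces <- with_seed(spec$seed, lapply(seq_len(n), function(i) {
    v <- spec$baseline_level * exp(-spec$bleach_rate * t_s / 60)
    if (labels[i])
      v <- v + spec$response_amplitude * (t_s >= rw[1] & t_s < rw[2])
    v <- v + spec$highK_amplitude *
      (t_s >= spec$highK_window[1] & t_s < spec$highK_window[2])
    if (spec$noise_sd > 0)
      v <- v + spec$noise_sd * stats::rnorm(length(t_s))
    trace(t_s, v, windows)
  }))
  list(traces = traces, is_responder = labels)
}

#' Simulate behavioral tables
#'
#' Produces the three record structures the behavioral metrics consume:
#' conditioned-place-preference session times (per animal and day, times in
#' the paired compartment, the other compartment and the middle area summing
#' to the 1800-s session), two-bottle daily intakes (solution and water, g),
#' and a locomotor activity series (counts per minute bin) spanning a
#' pre/post ICV-injection design.
#'
#' @param seed integer seed.
#' @param n_animals animals per table.
#' @param n_pre_days number of CPP pre-test days.
#' @param session_s CPP session length, seconds.
#' @param cpp_effect additive shift (seconds) of paired-compartment time on
#'   the test day, emulating a developed place preference.
#' @return A list with data frames `cpp`, `bottles` and `activity`.
#' @export
generate_behavior_tables <- function(seed = 1L, n_animals = 8,
                                     n_pre_days = 3, session_s = 1800,
                                     cpp_effect = 200) {
  with_seed(seed, {
    rows <- list()
    for (a in seq_len(n_animals)) {
      for (d in seq_len(n_pre_days + 1L)) {
        phase <- if (d <= n_pre_days) "pre" else "test"
        t_mid <- round(stats::runif(1, 100, 300))
        base_paired <- (session_s - t_mid) * stats::runif(1, 0.40, 0.48)
        t_paired <- round(base_paired + if (phase == "test") cpp_effect else 0)
        t_other <- session_s - t_mid - t_paired
        rows[[length(rows) + 1L]] <- data.frame(
          animal = a, day = d, phase = phase, t_paired = t_paired,
          t_other = t_other, t_middle = t_mid)
      }
    }
    cpp <- do.call(rbind, rows)

    bottles <- do.call(rbind, lapply(seq_len(n_animals), function(a) {
      sol <- pmax(stats::rnorm(2, 3.5, 0.5), 0.1)
      wat <- pmax(stats::rnorm(2, 1.2, 0.3), 0.1)
      data.frame(animal = a, day = 1:2, solution_g = round(sol, 2),
                 water_g = round(wat, 2))
    }))

    bins <- 0:119                       # minutes; injection at t = 60
    base <- 40 + 15 * exp(-bins / 45)
    post <- 1 + 0.8 * exp(-pmax(bins - 60, 0) / 20) * (bins >= 60)
    activity <- data.frame(
      bin_min = bins,
      counts = pmax(round(base * post + stats::rnorm(length(bins), 0, 4)), 0),
      injection_min = 60)

    list(cpp = cpp, bottles = bottles, activity = activity)
  })
}
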