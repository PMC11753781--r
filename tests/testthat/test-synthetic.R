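test_that("generated input functions satisfy bolus invariants", {
  sched <- fdg_frame_schedule()
  cp <- generate_input_function(schedule = sched)
  expect_equal(evaluate_input_function(cp, 0), 0)
  expect_true(all(cp$values >= 0))
  expect_equal(max(cp$times_s), 2580)
  # zero amplitudes give the zero curve
  z <- generate_input_function(amplitude_params = c(0, 0), schedule = sched)
  expect_true(all(z$values == 0))
  # delay: identically zero before the injection delay
  expect_true(all(evaluate_input_function(cp, c(0, 5, 14.9)) == 0))
  expect_error(generate_input_function(rate_params = c(-1, 0.1),
                                       schedule = sched), "positive")
  expect_error(generate_input_function(rise_rate = 1, schedule = sched),
               "rise_rate")
})

test_that("input-function peak matches a dense closed-form scan", {
  sched <- fdg_frame_schedule()
  amps <- c(35, 6); rates <- c(2, 0.02); rise <- 5; delay <- 0.25
  cp <- generate_input_function(amps, rates, rise, delay, sched)
  # independent oracle: evaluate the closed form on a 10x finer grid
  t_fine <- seq(0, 2580, by = 0.1)
  tau <- pmax((t_fine - delay * 60) / 60, 0)
  ref <- amps[1] * (exp(-rates[1] * tau) - exp(-rise * tau)) +
    amps[2] * (exp(-rates[2] * tau) - exp(-rise * tau))
  t_peak_ref <- t_fine[which.max(ref)]
  t_peak <- cp$times_s[which.max(cp$values)]
  expect_lt(abs(t_peak - t_peak_ref), 1)     # within one coarse sample
  expect_lt(abs(max(cp$values) - max(ref)) / max(ref), 1e-3)
})

test_that("noiseless phantom voxels equal the model prediction exactly", {
  spec <- tiny_phantom_spec(noise_cv = 0)
  sched <- fdg_frame_schedule()
  cp <- generate_input_function(schedule = sched)
  ph <- generate_phantom(spec, cp, sched)
  for (nm in names(spec$regions)) {
    r <- spec$regions[[nm]]
    pred <- predict_tac(r$params, cp, sched)
    v1 <- r$voi$voxel_indices[1, ]
    expect_equal(ph$image$values[v1[1], v1[2], v1[3], ], pred,
                 tolerance = 1e-12, info = nm)
  }
  # unassigned voxels stay zero
  expect_equal(ph$image$values[3, 6, 3, ], rep(0, length(sched)))
})

test_that("phantom generation is bit-reproducible under a fixed seed", {
  spec <- tiny_phantom_spec(noise_cv = 0.05, seed = 7)
  sched <- fdg_frame_schedule()
  cp <- generate_input_function(schedule = sched)
  a <- generate_phantom(spec, cp, sched)
  b <- generate_phantom(spec, cp, sched)
  expect_identical(a$image$values, b$image$values)
  c2 <- generate_phantom(spec, cp, sched, seed = 8)
  expect_false(identical(a$image$values, c2$image$values))
})

test_that("blood voxels are the 0.6-scaled frame-averaged input", {
  spec <- tiny_phantom_spec(noise_cv = 0)
  sched <- fdg_frame_schedule()
  cp <- generate_input_function(schedule = sched)
  ph <- generate_phantom(spec, cp, sched)
  grid <- fdgmap:::make_time_grid(sched)
  if_frames <- fdgmap:::frame_average(
    evaluate_input_function(cp, grid$t_min * 60), grid)
  v1 <- spec$blood_region$voxel_indices[1, ]
  expect_equal(ph$image$values[v1[1], v1[2], v1[3], ], 0.6 * if_frames,
               tolerance = 1e-12)
})

test_that("overlapping regions are rejected at spec construction", {
  expect_error(phantom_spec(
    grid_shape = c(6, 6, 3),
    regions = list(
      a = list(voi = box_voi(1:3, 1:3, 1:2), params = kinetic_params(0.1, 0.2, 0.05)),
      b = list(voi = box_voi(3:5, 3:5, 2:3), params = kinetic_params(0.1, 0.2, 0.05))),
    noise_cv = 0), "disjoint")
  expect_error(phantom_spec(c(4, 4, 2), regions = list(
    a = list(voi = box_voi(1:5, 1, 1), params = kinetic_params(0.1, 0.2, 0.05)))),
    "outside")
})

test_that("group studies derive per-animal seeds and apply K1 effects", {
  spec <- tiny_phantom_spec(noise_cv = 0.05, seed = 3,
                            group_effects = c(r1 = 1.15))
  sched <- fdg_frame_schedule()
  cp <- generate_input_function(schedule = sched)
  st <- generate_group_study(spec, cp, n_per_group = 2, seed = 3)
  st2 <- generate_group_study(spec, cp, n_per_group = 2, seed = 3)
  expect_identical(st$group_a[[1]]$values, st2$group_a[[1]]$values)
  expect_false(identical(st$group_a[[1]]$values, st$group_a[[2]]$values))
  # truth maps: K1 scaled by 1.15 in r1, untouched elsewhere
  lin1 <- fdgmap:::voi_linear_index(spec$regions$r1$voi, spec$grid_shape)
  lin2 <- fdgmap:::voi_linear_index(spec$regions$r2$voi, spec$grid_shape)
  expect_equal(st$truth_b$K1[lin1], 1.15 * st$truth_a$K1[lin1])
  expect_equal(st$truth_b$K1[lin2], st$truth_a$K1[lin2])
  expect_error(generate_group_study(spec, cp, n_per_group = 1), ">= 2")

  # factor 1.0 leaves the truth identical between groups
  spec2 <- tiny_phantom_spec(group_effects = c(r1 = 1.0))
  st3 <- generate_group_study(spec2, cp, n_per_group = 2)
  expect_equal(st3$truth_b$CEoverCP, st3$truth_a$CEoverCP)
})

test_that("synthetic traces carry the constructed features and labels", {
  # no noise, no bleach, no responders: flat except the high-K+ window
  sp <- trace_spec(noise_sd = 0, bleach_rate = 0, seed = 5)
  out <- generate_traces(sp, n = 4, responder_fraction = 0)
  expect_false(any(out$is_responder))
  tr <- out$traces[[1]]
  in_hk <- tr$times_s >= 1500 & tr$times_s < 1620
  expect_true(all(tr$values[!in_hk] == sp$baseline_level))
  expect_true(all(tr$values[in_hk] == sp$baseline_level + sp$highK_amplitude))

  # a noiseless responder shows exactly the configured amplitude
  out2 <- generate_traces(sp, n = 2, responder_fraction = 1)
  q <- quantify_response(out2$traces[[1]], c(360, 600), c(840, 1080))
  expect_equal(q$response, sp$response_amplitude)

  out3 <- generate_traces(trace_spec(seed = 2), 200, 0.5)
  expect_equal(sum(out3$is_responder), 100L)
  expect_error(generate_traces(sp, -1), ">= 0")
  expect_error(generate_traces(sp, 5, 1.5), "\\[0, 1\\]")
  expect_error(trace_spec(highK_amplitude = 0), "> 0")
  expect_error(trace_spec(response_window = c(600, 1600)), "overlap")
})

test_that("behavior tables conserve session time and reproduce by seed", {
  tabs <- generate_behavior_tables(seed = 11)
  expect_true(all(tabs$cpp$t_paired + tabs$cpp$t_other +
                    tabs$cpp$t_middle == 1800))
  expect_true(all(tabs$cpp$t_paired >= 0 & tabs$cpp$t_other >= 0))
  expect_true(all(tabs$bottles$solution_g >= 0 & tabs$bottles$water_g >= 0))
  expect_true(all(tabs$activity$counts >= 0))
  expect_identical(tabs, generate_behavior_tables(seed = 11))
  expect_false(identical(tabs$cpp, generate_behavior_tables(seed = 12)$cpp))
})

test_that("generators leave the global RNG stream untouched", {
  set.seed(123); r1 <- rnorm(1)
  set.seed(123)
  invisible(generate_behavior_tables(seed = 4))
  invisible(generate_traces(trace_spec(seed = 9), 3, 0.5))
  expect_equal(rnorm(1), r1)
})
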