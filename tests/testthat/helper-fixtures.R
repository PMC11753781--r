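# Shared fixtures: a short schedule for fast unit tests, a small phantom,
# and canonical parameter sets. The full 25-frame schedule is used where a
# test is about the acquisition itself.

short_schedule <- function() {
  frame_schedule(c(rep(10, 6), rep(30, 4), rep(60, 3)))  # 360 s, 13 frames
}

test_input_function <- function(schedule = short_schedule()) {
  generate_input_function(schedule = schedule)
}

# three distinct, physiologically plausible parameter sets
test_param_sets <- function() {
  list(kinetic_params(0.10, 0.20, 0.050, 0.010),
       kinetic_params(0.15, 0.30, 0.080, 0.005),
       kinetic_params(0.06, 0.15, 0.025, 0.000))
}

# tiny phantom: 6 x 6 x 3 grid, two tissue boxes and a blood box
tiny_phantom_spec <- function(noise_cv = 0, seed = 1L,
                              group_effects = numeric(0)) {
  phantom_spec(
    grid_shape = c(6, 6, 3),
    regions = list(
      r1 = list(voi = box_voi(1:2, 1:3, 1:2, "r1"),
                params = kinetic_params(0.10, 0.20, 0.05, 0.01)),
      r2 = list(voi = box_voi(4:6, 1:2, 1:3, "r2"),
                params = kinetic_params(0.06, 0.15, 0.03, 0.005))),
    blood_region = box_voi(4:5, 5:6, 1:2, "blood"),
    noise_cv = noise_cv, group_effects = group_effects, seed = seed)
}

# synthetic GCaMP trace sampled at 5 s with known windows
test_trace_spec <- function(...) trace_spec(...)
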