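test_that("noiseless forward-then-fit round trip recovers parameters", {
  sched <- fdg_frame_schedule()
  cp <- generate_input_function(schedule = sched)
  ctx <- tcm_context(cp, sched)
  for (truth in test_param_sets()) {
    tac <- predict_tac(truth, cp, sched)
    fit <- fit_tac(tac, cp, sched, context = ctx)
    expect_true(fit$converged)
    th <- unclass(truth)
    rel <- abs(coef(fit) - th) / pmax(th, 1e-3)
    expect_true(all(rel < 0.01),
                info = paste("rel errors:", paste(signif(rel, 3),
                                                  collapse = " ")))
  }
})

test_that("degenerate curves yield a flagged non-converged zero fit", {
  sched <- short_schedule()
  cp <- test_input_function(sched)
  z <- fit_tac(rep(0, length(sched)), cp, sched)
  expect_false(z$converged)
  expect_equal(unname(coef(z)), rep(0, 4))
  bad <- rep(1, length(sched)); bad[3] <- NaN
  expect_false(fit_tac(bad, cp, sched)$converged)
})

test_that("fitting is deterministic and independent of other voxels", {
  sched <- fdg_frame_schedule()
  cp <- generate_input_function(schedule = sched)
  truth <- kinetic_params(0.1, 0.2, 0.05, 0.01)
  set.seed(5)
  tac <- predict_tac(truth, cp, sched) * (1 + 0.05 * rnorm(25))
  f1 <- fit_tac(tac, cp, sched)
  f2 <- fit_tac(tac, cp, sched)
  expect_identical(coef(f1), coef(f2))
})

test_that("pin_k4 fixes k4 at zero and still fits the free parameters", {
  sched <- fdg_frame_schedule()
  cp <- generate_input_function(schedule = sched)
  truth <- kinetic_params(0.12, 0.25, 0.06, 0)
  tac <- predict_tac(truth, cp, sched)
  fit <- fit_tac(tac, cp, sched, pin_k4 = TRUE)
  expect_equal(unname(coef(fit)["k4"]), 0)
  expect_equal(unname(coef(fit)["K1"]), 0.12, tolerance = 1e-3)
})

test_that("noisy recovery: median K1 error under 5% CV stays below 10%", {
  sched <- fdg_frame_schedule()
  cp <- generate_input_function(schedule = sched)
  ctx <- tcm_context(cp, sched)
  truth <- kinetic_params(0.1, 0.2, 0.05, 0.01)
  mu <- predict_tac(truth, cp, sched)
  set.seed(21)
  errs <- replicate(40, {
    y <- mu * (1 + 0.05 * rnorm(length(mu)))
    abs(coef(fit_tac(y, cp, sched, context = ctx))[["K1"]] - 0.1) / 0.1
  })
  expect_lt(median(errs), 0.10)
})

test_that("model-object methods are coherent", {
  sched <- fdg_frame_schedule()
  cp <- generate_input_function(schedule = sched)
  truth <- kinetic_params(0.1, 0.2, 0.05, 0.01)
  set.seed(2)
  tac <- predict_tac(truth, cp, sched) * (1 + 0.03 * rnorm(25))
  fit <- fit_tac(tac, cp, sched)
  expect_equal(residuals(fit), tac - fitted(fit))
  expect_equal(deviance(fit), fit$rss)
  expect_equal(predict(fit), fitted(fit))
  expect_equal(fit$cecp, glucose_transport_ratio(fit$params))
  s <- summary(fit)
  expect_equal(unname(s$coefficients[, "Estimate"]), unname(coef(fit)))
  sims <- simulate(fit, nsim = 3, seed = 9, cv = 0.05)
  expect_identical(dim(sims), c(25L, 3L))
  expect_identical(sims, simulate(fit, nsim = 3, seed = 9, cv = 0.05))
  expect_output(print(fit), "Two-tissue-compartment")
})

test_that("fit_image recovers a noiseless phantom and respects the mask", {
  spec <- tiny_phantom_spec(noise_cv = 0)
  sched <- fdg_frame_schedule()
  cp <- generate_input_function(schedule = sched)
  ph <- generate_phantom(spec, cp, sched)
  mask <- spec$regions$r1$voi
  pmap <- fit_image(ph$image, cp, mask = mask)
  lin <- fdgmap:::voi_linear_index(mask, spec$grid_shape)
  expect_true(all(pmap$converged[lin]))
  for (nm in c("K1", "k2", "k3", "k4", "CEoverCP")) {
    rel <- abs(pmap[[nm]][lin] - ph$truth[[nm]][lin]) /
      pmax(ph$truth[[nm]][lin], 1e-3)
    expect_true(all(rel < 0.01), info = nm)
  }
  # everything outside the mask is unfitted and excluded
  expect_true(all(is.na(pmap$K1[-lin])))
  expect_false(any(pmap$converged[-lin]))
})

test_that("parametric maps tabulate and write to disk coherently", {
  spec <- tiny_phantom_spec(noise_cv = 0)
  sched <- fdg_frame_schedule()
  cp <- generate_input_function(schedule = sched)
  ph <- generate_phantom(spec, cp, sched)
  idif <- pve_correct(extract_voi_tac(ph$image, spec$blood_region))
  pmap <- fit_image(ph$image, idif, mask = voi(cbind(1:2, 1, 1)))
  tab <- as.data.frame(pmap)
  expect_named(tab, c("voxel_x", "voxel_y", "voxel_z", "K1", "k2", "k3",
                      "k4", "CEoverCP", "fit_rss", "converged"))
  expect_equal(nrow(tab), 2L)
  stem <- file.path(withr::local_tempdir(), "maps")
  paths <- write_parametric_map(pmap, stem)
  expect_true(all(file.exists(paths)))
  k1 <- read_map(paste0(stem, "_K1.nii.gz"))
  expect_equal(k1$values[1, 1, 1], pmap$K1[1, 1, 1], tolerance = 1e-6)
})
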