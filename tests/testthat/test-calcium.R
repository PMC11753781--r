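flat_trace <- function(level = 100, n = 360, dt = 5,
                       windows = list(baseline = c(360, 600),
                                      response = c(840, 1080))) {
  trace(seq(0, by = dt, length.out = n), rep(level, n), windows)
}

test_that("bleach correction centres a flat baseline at zero", {
  tr <- flat_trace(level = 250)
  out <- correct_bleaching(tr)
  base <- fdgmap:::window_values(out, "baseline")
  expect_lt(abs(mean(base)), 1e-8)
  expect_equal(out$windows, tr$windows)
})

test_that("bleach correction removes a pure exponential exactly", {
  t_s <- seq(0, 1795, by = 5)
  y <- 200 + 800 * exp(-0.03 * t_s / 60)
  tr <- trace(t_s, y, list(baseline = c(0, 600)))
  out <- correct_bleaching(tr)
  expect_lt(max(abs(out$values)), 1e-6 * 800)
  expect_equal(attr(out, "bleach_model"), "exponential")
})

test_that("bleach correction recovers a square response under bleaching", {
  # exponential bleach + 8-min square response of known amplitude
  t_s <- seq(0, 1795, by = 5)
  amp <- 120
  y <- 1000 * exp(-0.05 * t_s / 60) + amp * (t_s >= 600 & t_s < 1080)
  tr <- trace(t_s, y, list(baseline = c(360, 600), response = c(840, 1080)))
  out <- correct_bleaching(tr, "baseline")
  q <- quantify_response(out)
  expect_lt(abs(q$response - amp) / amp, 0.05)
})

test_that("too-short baselines are rejected", {
  tr <- flat_trace()
  expect_error(correct_bleaching(tr, c(0, 20)), "at least 10 samples")
})

test_that("quantify_response is the window-mean difference with baseline SD", {
  tr <- flat_trace()
  q0 <- quantify_response(tr)
  expect_equal(q0$response, 0)

  t_s <- seq(0, 1195, by = 5)
  y <- ifelse(t_s >= 840 & t_s < 1080, 4, 1)
  tr2 <- trace(t_s, y, list(baseline = c(360, 600), response = c(840, 1080)))
  q <- quantify_response(tr2)
  expect_equal(q$response, 3)
  expect_equal(q$sigma, 0)

  set.seed(13)
  y3 <- rnorm(length(t_s))
  tr3 <- trace(t_s, y3, list(baseline = c(360, 600), response = c(840, 1080)))
  q3 <- quantify_response(tr3)
  sel_b <- t_s >= 360 & t_s < 600
  sel_r <- t_s >= 840 & t_s < 1080
  expect_equal(q3$response, mean(y3[sel_r]) - mean(y3[sel_b]))
  expect_equal(q3$sigma, sd(y3[sel_b]))
  expect_error(quantify_response(tr3, c(0, 600), c(500, 900)), "overlap")
})

test_that("the 3-sigma criterion is strict at the boundary", {
  expect_true(classify_responder(3.5, 1)$responder)
  expect_equal(classify_responder(3.5, 1)$z_score, 3.5)
  expect_false(classify_responder(3.0, 1)$responder)   # exactly 3 sigma
  expect_false(classify_responder(-5, 1)$responder)    # inhibition
  expect_true(classify_responder(-5, 1, signed = TRUE)$responder)
  expect_error(classify_responder(1, 0), "sigma")
  # degenerate threshold: any positive response qualifies
  expect_true(classify_responder(1e-6, 1, threshold_multiple = 0)$responder)
  expect_false(classify_responder(0, 1, threshold_multiple = 0)$responder)
})

test_that("responder calls are invariant to trace rescaling", {
  set.seed(41)
  t_s <- seq(0, 1495, by = 5)
  y <- 100 + rnorm(length(t_s), sd = 3) + 20 * (t_s >= 840 & t_s < 1080)
  w <- list(baseline = c(360, 600), response = c(840, 1080))
  for (c_scale in c(0.5, 1, 7)) {
    q <- quantify_response(trace(t_s, c_scale * y, w))
    expect_equal(q$response / q$sigma,
                 quantify_response(trace(t_s, y, w))$response /
                   quantify_response(trace(t_s, y, w))$sigma,
                 tolerance = 1e-12)
  }
})

test_that("high-K+ normalization and population test behave as specified", {
  expect_equal(normalize_to_highK(20, 100), 20)
  expect_equal(normalize_to_highK(0, 100), 0)
  expect_equal(normalize_to_highK(100, 100), 100)
  expect_error(normalize_to_highK(10, 0), "> 0")

  zeros <- population_response(rep(0, 6))
  expect_equal(zeros$mean, 0)
  expect_equal(zeros$p, 1)
  expect_equal(population_response(c(-2, 2, -1, 1))$mean, 0)

  set.seed(8)
  x <- rnorm(20, mean = 5)
  r <- population_response(x)
  t_ref <- mean(x) / (sd(x) / sqrt(20))
  expect_equal(r$t, t_ref, tolerance = 1e-12)
  expect_equal(r$p, 2 * pt(-abs(t_ref), 19), tolerance = 1e-12)
  expect_equal(r$sem, sd(x) / sqrt(20))
  expect_error(population_response(1), "at least two")
})

test_that("firing-rate classification uses 10-s bins and 24 baseline points", {
  # 240 s baseline at 2 Hz with slight jitter, then a 1 Hz step
  set.seed(3)
  t_s <- seq(0, 479.9, by = 0.5)
  base_rates <- rep(rnorm(24, 2, 0.2), each = 20)
  rates <- c(base_rates, rep(3, length(t_s) - length(base_rates)))
  tr <- trace(t_s, rates, list(response = c(240, 480)))
  res <- classify_firing_responder(tr)
  expect_equal(res$baseline_mean, mean(base_rates[seq(1, 480, by = 20)]),
               tolerance = 1e-9)
  expect_equal(res$delta_frequency, 3 - res$baseline_mean)
  expect_true(res$call$responder)   # delta ~1 Hz >> 3 * SD(~0.2)

  # flat baseline has zero SD: degenerate, same contract as classify_responder
  flat <- trace(t_s, c(rep(2, 480), rep(3, length(t_s) - 480)),
                list(response = c(240, 480)))
  expect_error(classify_firing_responder(flat), "sigma")

  shorty <- trace(seq(0, 99.5, by = 0.5), rep(2, 200),
                  list(response = c(50, 99)))
  expect_error(classify_firing_responder(shorty), "baseline bins")
})

test_that("population delta-frequency matches a signed-rank oracle", {
  set.seed(19)
  x <- rnorm(15, mean = 0.4, sd = 0.5)
  r <- population_delta_frequency(x)
  # independent recomputation: rank |x|, sum ranks of positive values,
  # normal approximation with continuity correction (two-sided)
  rk <- rank(abs(x))
  V <- sum(rk[x > 0])
  n <- length(x)
  mu <- n * (n + 1) / 4
  sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
  z <- (V - mu - sign(V - mu) * 0.5) / sigma
  p_ref <- 2 * pnorm(-abs(z))
  expect_equal(r$V, V)
  expect_equal(r$p, p_ref, tolerance = 1e-10)
})
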