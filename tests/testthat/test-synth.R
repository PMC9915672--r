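test_that("noise-free trial responses equal the tuning function exactly", {
  cfg <- synth_config(n_neurons = 6, frac_monotonic = 1, noise_sd = 0,
                      frac_tagged = 0, param_cv = 0, seed = 2)
  pop <- generate_population(cfg)
  # every neuron carries exactly the no-laser mean parameters; at 90 dB the
  # sigmoid evaluates to y0 + yrange / (1 + exp((x0 - 90) / dx))
  expected_90 <- -0.12 + 0.88 / (1 + exp((55 - 90) / 11))
  r90 <- pop$table$response[pop$table$level == 90 & pop$table$laser == "none"]
  expect_equal(r90, rep(expected_90, length(r90)))
  # and the full table matches direct evaluation of the stored ground truth
  key <- match(paste(pop$table$neuron, pop$table$laser),
               paste(pop$truth$neuron, pop$truth$laser))
  mu <- sigmoid_response(pop$table$level, pop$truth$y0[key],
                         pop$truth$yrange[key], pop$truth$x_center[key],
                         pop$truth$width[key])
  expect_equal(pop$table$response, mu)
})

test_that("generation is deterministic given the seed", {
  cfg <- synth_config(n_neurons = 8, seed = 11)
  a <- generate_population(cfg)
  b <- generate_population(cfg)
  expect_identical(a, b)
  expect_identical(generate_traces(a)$F, generate_traces(b)$F)
  c_ <- generate_population(synth_config(n_neurons = 8, seed = 12))
  expect_false(identical(a$table$response, c_$table$response))
})

test_that("kind fractions and tagging fractions are honored", {
  pop <- generate_population(synth_config(n_neurons = 20, frac_monotonic = 1,
                                          seed = 3))
  expect_false("gaussian" %in% pop$truth$kind)
  pop2 <- generate_population(synth_config(n_neurons = 50, frac_monotonic = 0.4,
                                           frac_tagged = 0.1, seed = 3))
  per_neuron <- pop2$truth[pop2$truth$laser == "none", ]
  expect_equal(sum(per_neuron$kind == "sigmoid"), 20)
  expect_equal(sum(per_neuron$tagged), 5)
})

test_that("high-laser parameter shifts carry the condition signature", {
  pop <- generate_population(synth_config(n_neurons = 40, condition = "SST",
                                          param_cv = 0, seed = 4))
  tr <- pop$truth
  sig <- tr[tr$kind == "sigmoid", ]
  expect_true(all(sig$x_center[sig$laser == "high"] >
                  sig$x_center[sig$laser == "none"]))
  gau <- tr[tr$kind == "gaussian", ]
  expect_true(all(gau$yrange[gau$laser == "high"] <
                  gau$yrange[gau$laser == "none"]))
  pop_v <- generate_population(synth_config(n_neurons = 40, condition = "VIP",
                                            param_cv = 0, seed = 4))
  sig_v <- pop_v$truth[pop_v$truth$kind == "sigmoid", ]
  expect_true(all(sig_v$yrange[sig_v$laser == "high"] >
                  sig_v$yrange[sig_v$laser == "none"]))
  # control: the laser changes nothing
  pop_c <- generate_population(synth_config(n_neurons = 10, condition = "control",
                                            seed = 4))
  tc <- pop_c$truth
  expect_equal(tc[tc$laser == "high", c("y0", "yrange", "x_center", "width")],
               tc[tc$laser == "none", c("y0", "yrange", "x_center", "width")],
               ignore_attr = TRUE)
})

test_that("gaussian ground-truth means stay within 10-80 dB", {
  pop <- generate_population(synth_config(n_neurons = 100, frac_monotonic = 0,
                                          param_cv = 0.5, seed = 5))
  expect_true(all(pop$truth$x_center >= 10 & pop$truth$x_center <= 80))
})

test_that("traces round-trip through the calibration window", {
  cfg <- synth_config(n_neurons = 4, noise_sd = 0.3, seed = 6)
  pop <- generate_population(cfg)
  traces <- generate_traces(pop)
  fr <- traces$frame_rate
  onset <- traces$onset_frame
  win <- list(start_s = 0, duration_s = 1)
  err <- c()
  for (i in 1:4) for (k in seq_len(nrow(traces$trials))) {
    dff <- compute_dff(traces$F[i, k, ], (onset - fr):(onset - 1))
    got <- window_response(dff, win, fr, onset)
    tab <- pop$table
    row <- tab[tab$neuron == i &
               tab$level == traces$trials$level[k] &
               tab$laser == traces$trials$laser[k] &
               tab$trial == traces$trials$trial[k], ]
    err <- c(err, got - row$response)
  }
  # windowing noise: unit-sd frame noise averaged over 30 window frames plus
  # baseline-normalization error (sd estimated from 30 frames) ~ 0.35 sd
  # combined; check the bulk of errors against 3 sd and the center is clean
  expect_lt(stats::quantile(abs(err), 0.95), 3 * 0.35)
  expect_lt(mean(abs(err)), 0.35)
  expect_lt(abs(mean(err)), 0.1)
})

test_that("zero-amplitude trials give near-zero windowed responses", {
  cfg <- synth_config(n_neurons = 2, noise_sd = 0, param_cv = 0, seed = 7)
  pop <- generate_population(cfg)
  pop$table$response <- 0
  traces <- generate_traces(pop)
  onset <- traces$onset_frame
  fr <- traces$frame_rate
  dff <- compute_dff(traces$F[1, 1, ], (onset - fr):(onset - 1))
  got <- window_response(dff, list(start_s = 0, duration_s = 1), fr, onset)
  expect_lt(abs(got), 1)  # pure baseline noise in the window mean
})

test_that("channel signals encode bleedthrough and tagging", {
  cfg <- synth_config(n_neurons = 60, frac_tagged = 0.1,
                      bleedthrough_coef = 0.3, seed = 8)
  pop <- generate_population(cfg)
  ch <- generate_channel_signals(pop, background_sd = 0.2, elevation = 5)
  res <- identify_tagged_cells(ch$green, ch$red, ch$background_sd)
  expect_equal(res$bleedthrough_coef, 0.3, tolerance = 0.05)
  expect_identical(unname(res$tagged), ch$tagged)
  # with no bleedthrough the slope is ~0
  cfg0 <- synth_config(n_neurons = 60, frac_tagged = 0,
                       bleedthrough_coef = 0, seed = 8)
  ch0 <- generate_channel_signals(generate_population(cfg0), background_sd = 0.2)
  res0 <- identify_tagged_cells(ch0$green, ch0$red, 0.2)
  expect_lt(abs(res0$bleedthrough_coef), 0.01)
  # untagged population: tagging rate is at most the 2-sigma false-positive
  # rate of the z test on ~300-frame means (tiny)
  expect_lt(mean(res0$tagged), 0.05)
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(n_neurons = 1))
  expect_error(synth_config(frac_monotonic = 1.2))
  expect_error(synth_config(noise_sd = -1))
  expect_error(synth_config(levels = c(30, 50)))       # must contain 0
  expect_error(synth_config(levels = c(0, 50, 30)))    # ascending
  expect_error(synth_config(frame_rate = 0))
})
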