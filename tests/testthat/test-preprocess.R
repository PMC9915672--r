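test_that("dF/Fstd arithmetic and affine invariance", {
  base <- c(8, 12, 10, 10, 8, 12)          # mean 10, sd 2
  trace <- c(base, 14, 10, 6)
  dff <- compute_dff(trace, seq_along(base))
  expect_equal(dff[7], (14 - 10) / stats::sd(base))
  # frames equal to the baseline mean map to exactly 0
  expect_equal(compute_dff(c(base, rep(10, 4)), seq_along(base))[7:10], rep(0, 4))
  # positive affine transform of the raw trace leaves dF/Fstd unchanged
  expect_equal(compute_dff(3 * trace + 7, seq_along(base)), dff)
  expect_error(compute_dff(rep(5, 10), 1:4), "degenerate")
})

test_that("window_response is the plain mean over window frames", {
  fr <- 10; onset <- 11
  trace <- c(rep(0, 10), rep(2, 20))
  expect_equal(window_response(trace, list(start_s = 0, duration_s = 1), fr, onset), 2)
  tr2 <- c(rep(0, 15), rep(2, 15))
  expect_equal(window_response(tr2, list(start_s = 0, duration_s = 1), fr, onset),
               mean(tr2[11:20]))
  expect_error(window_response(trace, list(start_s = 3, duration_s = 1), fr, onset),
               "out of")
})

test_that("optimal window matches an exhaustive d-prime scan", {
  fr <- 20; onset <- fr + 1
  n_frames <- onset + 5 * fr
  t_from_onset <- (seq_len(n_frames) - onset) / fr
  kernel <- exp(-pmax(t_from_onset - 0.3, 0) / 1) - exp(-pmax(t_from_onset - 0.3, 0) / 0.05)
  kernel[t_from_onset < 0.3] <- 0
  set.seed(1)
  trials <- t(replicate(8, 3 * kernel + stats::rnorm(n_frames, 0, 0.3)))
  win <- optimal_window(trials, fr, onset)

  # independent brute-force oracle
  starts <- (0:(4 * fr)) / fr
  base <- rowMeans(trials[, 1:fr])
  dp <- sapply(starts, function(s) {
    i0 <- onset + round(s * fr)
    w <- rowMeans(trials[, i0:(i0 + fr - 1)])
    abs(mean(w) - mean(base)) / sqrt((stats::var(w) + stats::var(base)) / 2)
  })
  expect_equal(win$start_s, starts[which.max(dp)])
  # the selected window covers the kernel mass near its onset delay
  expect_lte(abs(win$start_s - 0.3), 0.5)
})

test_that("optimal window is shift-equivariant", {
  fr <- 10; onset <- fr + 1
  n_frames <- onset + 6 * fr
  t_rel <- (seq_len(n_frames) - onset) / fr
  bump <- function(delay) ifelse(t_rel >= delay & t_rel < delay + 1, 1, 0)
  set.seed(2)
  noise <- matrix(stats::rnorm(4 * n_frames, 0, 0.05), 4)
  w1 <- optimal_window(sweep(noise, 2, bump(0.5), "+"), fr, onset)
  w2 <- optimal_window(sweep(noise, 2, bump(1.5), "+"), fr, onset)
  expect_equal(w2$start_s - w1$start_s, 1)
})

test_that("flat traces give zero d-prime everywhere, tie broken earliest", {
  fr <- 10; onset <- fr + 1
  set.seed(3)
  # traces constant in time with trial-to-trial offsets: every window's
  # per-trial means equal the baseline means, so d' = 0 for every start
  n_frames <- onset + 5 * fr
  trials <- matrix(stats::rnorm(5), nrow = 5, ncol = n_frames)
  win <- optimal_window(trials, fr, onset)
  expect_equal(win$start_s, 0)
  expect_equal(win$dprime, 0)
})

test_that("fixed window equals an independent exhaustive scan", {
  cfg <- synth_config(n_neurons = 5, noise_sd = 0.3, onset_delay_s = 0.3,
                      seed = 21)
  pop <- generate_population(cfg)
  traces <- generate_traces(pop)
  win <- fixed_window(traces)

  # independent oracle: stats::t.test per neuron and condition, Bonferroni
  fr <- traces$frame_rate; onset <- traces$onset_frame
  cond <- paste(traces$trials$level, traces$trials$laser)
  dff <- array(NA_real_, dim(traces$F))
  for (i in 1:5) for (k in seq_len(nrow(traces$trials))) {
    dff[i, k, ] <- compute_dff(traces$F[i, k, ], (onset - fr):(onset - 1))
  }
  base <- apply(dff[, , (onset - fr):(onset - 1)], c(1, 2), mean)
  starts <- (0:(4 * fr)) / fr
  counts <- sapply(starts, function(s) {
    i0 <- onset + round(s * fr)
    w <- apply(dff[, , i0:(i0 + fr - 1)], c(1, 2), mean)
    resp <- 0
    for (i in 1:5) {
      ps <- sapply(unique(cond), function(cc) {
        rows <- which(cond == cc)
        stats::t.test(w[i, rows], base[i, rows], paired = TRUE)$p.value
      })
      if (any(pmin(ps * 21, 1) < 0.01)) resp <- resp + 1
    }
    resp
  })
  expect_equal(win$start_s, starts[which.max(counts)])
  expect_equal(unname(win$n_responsive), max(counts))

  tab <- window_table(traces, "fixed")
  expect_identical(attr(tab, "window_mode"), "fixed")
  expect_equal(nrow(tab), 5 * 21 * 10)
  expect_true(all(is.finite(tab$response)))
})

test_that("pure-noise tracesets yield near-zero responsive counts", {
  cfg <- synth_config(n_neurons = 10, noise_sd = 0, param_cv = 0, seed = 22)
  pop <- generate_population(cfg)
  pop$table$response <- 0            # no stimulus-evoked signal at all
  traces <- generate_traces(pop)
  win <- fixed_window(traces)
  # Bonferroni-corrected p < 0.01 over 21 tests per neuron: false positives
  # are rare even maximized over 121 candidate starts
  expect_lte(win$n_responsive, 2)
})

test_that("bleedthrough correction and 2-sigma tagging", {
  set.seed(4)
  green <- matrix(stats::rnorm(50 * 100, 50, 5), 50)
  red <- 0.3 * green                        # exact bleedthrough, no offset
  res <- identify_tagged_cells(green, red, background_sd = 1)
  expect_equal(res$bleedthrough_coef, 0.3, tolerance = 1e-9)
  expect_equal(unname(res$z), rep(0, 50), tolerance = 1e-9)
  expect_false(any(res$tagged))
  # a cell elevated by 5 sigma is tagged
  red[7, ] <- red[7, ] + 5
  res2 <- identify_tagged_cells(green, red, background_sd = 1)
  expect_true(res2$tagged[7])
  expect_equal(sum(res2$tagged), 1)
  # constant green: slope undefined, set to 0 with a warning
  gconst <- matrix(1, 4, 10)
  expect_warning(res3 <- identify_tagged_cells(gconst, gconst * 0 + 3, 1),
                 "constant green")
  expect_equal(res3$bleedthrough_coef, 0)
})
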