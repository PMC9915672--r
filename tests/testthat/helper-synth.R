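# Shared fixtures, built in code.

empirical_levels <- c(0, 30, 50, 60, 70, 80, 90)

# Simulate one response-level curve from trial draws: n_trials per level with
# per-trial Gaussian noise, returning the estimated mean and sem per level.
simulate_curve <- function(params, kind, trial_sd, n_trials = 10,
                           levels = empirical_levels) {
  mu <- evaluate_model(params, levels, kind)
  trials <- vapply(mu, function(m) stats::rnorm(n_trials, m, trial_sd),
                   numeric(n_trials))
  list(mean = colMeans(trials),
       sem = apply(trials, 2, stats::sd) / sqrt(n_trials),
       levels = levels)
}

# Tuning parameters drawn around the population means used by the generator
# (20% coefficient of variation), per model kind.
draw_params <- function(kind) {
  if (kind == "sigmoid") {
    c(stats::rnorm(1, -0.12, 0.024), stats::rnorm(1, 0.88, 0.176),
      stats::rnorm(1, 55, 11), max(1, stats::rnorm(1, 11, 2.2)))
  } else {
    xm <- stats::rnorm(1, 50, 10)
    while (xm < 15 || xm > 75) xm <- stats::rnorm(1, 50, 10)
    c(stats::rnorm(1, -0.04, 0.008), stats::rnorm(1, 0.54, 0.108),
      xm, max(1, stats::rnorm(1, 13, 2.6)))
  }
}

# A small deterministic response table built directly from per-neuron mean
# matrices (rows = neurons, cols = levels), identical across trials.
table_from_means <- function(means_by_laser, levels = empirical_levels,
                             n_trials = 2) {
  out <- list()
  for (ll in names(means_by_laser)) {
    m <- means_by_laser[[ll]]
    for (i in seq_len(nrow(m))) for (j in seq_along(levels)) {
      out[[length(out) + 1]] <- data.frame(
        neuron = i, level = levels[j], laser = ll,
        trial = seq_len(n_trials), response = m[i, j]
      )
    }
  }
  do.call(rbind, out)
}
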