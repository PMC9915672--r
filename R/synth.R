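#' Configuration for the synthetic-data generator
#'
#' Defines the study conditions emulated by [generate_population()],
#' [generate_traces()] and [generate_channel_signals()]: a population of
#' monotonic (sigmoid-tuned) and nonmonotonic (Gaussian-tuned) neurons
#' responding to noise bursts at seven sound pressure levels while an
#' inhibitory interneuron class (SST or VIP) is optogenetically driven at
#' three laser powers (none, medium, high).
#'
#' The central tuning parameters are the mean sigmoid and Gaussian parameter
#' sets of the two-cell model (see [two_cell_config()]); high-laser parameter
#' shifts follow the same per-condition overrides, the medium laser applies
#' half the high-laser effect, and `"control"` applies no laser effect at all.
#'
#' @param n_neurons Number of neurons (>= 2).
#' @param frac_monotonic Fraction of neurons with monotonic (sigmoid) tuning.
#' @param levels Sound pressure levels in dB SPL, ascending, containing 0.
#' @param lasers Ordered laser conditions.
#' @param n_trials Trials per sound x laser combination.
#' @param noise_sd Per-trial additive Gaussian noise sd (dF/F units).
#' @param frac_tagged Fraction of cells tagged as opsin-expressing interneurons.
#' @param bleedthrough_coef Dimensionless green-to-red channel bleedthrough.
#' @param frame_rate Imaging frame rate in Hz.
#' @param condition Interneuron class being activated: `"SST"`, `"VIP"`, or
#'   `"control"` (laser has no effect on tuning).
#' @param param_cv Coefficient of variation for per-neuron tuning-parameter
#'   draws around the population means.
#' @param heteroscedastic If `TRUE`, trial noise sd scales with the absolute
#'   mean response (`noise_sd * (0.5 + 0.5 * |mean|)`); homoscedastic by
#'   default.
#' @param onset_delay_s Delay from stimulus onset to calcium-response onset
#'   in the generated traces (seconds).
#' @param seed Integer seed; all randomness in the generators flows from it.
#' @return A list of class `"synth_config"`.
#' @export
synth_config <- function(n_neurons = 60,
                         frac_monotonic = 0.4,
                         levels = c(0, 30, 50, 60, 70, 80, 90),
                         lasers = c("none", "medium", "high"),
                         n_trials = 10,
                         noise_sd = 0.5,
                         frac_tagged = 0.06,
                         bleedthrough_coef = 0.3,
                         frame_rate = 30,
                         condition = c("SST", "VIP", "control"),
                         param_cv = 0.2,
                         heteroscedastic = FALSE,
                         onset_delay_s = 0.3,
                         seed = 1L) {
  condition <- match.arg(condition)
  if (n_neurons < 2) stop("n_neurons must be >= 2", call. = FALSE)
  for (f in c(frac_monotonic, frac_tagged)) {
    if (f < 0 || f > 1) stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (length(levels) == 0 || is.unsorted(levels, strictly = TRUE) || !(0 %in% levels)) {
    stop("levels must be strictly ascending and contain 0", call. = FALSE)
  }
  if (frame_rate <= 0) stop("frame_rate must be positive", call. = FALSE)
  if (n_trials < 2) stop("n_trials must be >= 2", call. = FALSE)
  structure(list(
    n_neurons = as.integer(n_neurons), frac_monotonic = frac_monotonic,
    levels = levels, lasers = lasers, n_trials = as.integer(n_trials),
    noise_sd = noise_sd, frac_tagged = frac_tagged,
    bleedthrough_coef = bleedthrough_coef, frame_rate = frame_rate,
    condition = condition, param_cv = param_cv,
    heteroscedastic = heteroscedastic, onset_delay_s = onset_delay_s,
    seed = as.integer(seed)
  ), class = "synth_config")
}

# Population-mean tuning parameters per model kind and laser power.
# Columns: y0, yrange, x_center (x0 or xmean), width (dx or sigma).
# High-laser rows carry the condition-specific overrides; medium applies half
# the high-laser change on each parameter.
.condition_means <- function(kind, condition) {
  base <- if (kind == "sigmoid") c(-0.12, 0.88, 55, 11) else c(-0.04, 0.54, 50, 13)
  high <- base
  if (condition == "SST") {
    if (kind == "sigmoid") high[3] <- 68 else high[c(1, 2)] <- c(-0.07, 0.27)
  } else if (condition == "VIP") {
    if (kind == "sigmoid") high[2] <- 1.43 else high[2:4] <- c(0.86, 54, 17)
  }
  out <- rbind(none = base, medium = base + 0.5 * (high - base), high = high)
  colnames(out) <- c("y0", "yrange", "x_center", "width")
  out
}

#' Generate a synthetic neuronal population and its trial response table
#'
#' Draws per-neuron tuning parameters from independent Gaussians centred on
#' the population-mean parameter sets (sd = `param_cv` times the mean
#' magnitude), applies the laser-condition parameter shifts, and produces the
#' trial-level response table: each trial response is the neuron's tuning
#' function evaluated at the sound level plus independent Gaussian noise.
#'
#' @param config A [synth_config()].
#' @return A list of class `"synth_population"` with elements
#'   \describe{
#'     \item{truth}{data frame of ground-truth parameters: one row per
#'       neuron x laser with columns `neuron`, `kind`, `tagged`, `laser`,
#'       `y0`, `yrange`, `x_center`, `width`.}
#'     \item{table}{the response table: `neuron`, `level`, `laser`, `trial`,
#'       `response` (dF/Fstd units), one row per trial.}
#'     \item{config}{the configuration used.}
#'   }
#' @export
#' @examples
#' pop <- generate_population(synth_config(n_neurons = 10, seed = 7))
#' head(pop$table)
generate_population <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_neurons
  n_mono <- round(config$frac_monotonic * n)
  kind <- sample(rep(c("sigmoid", "gaussian"), c(n_mono, n - n_mono)))
  tagged <- rep(FALSE, n)
  tagged[sample.int(n, round(config$frac_tagged * n))] <- TRUE

  truth <- vector("list", n)
  for (i in seq_len(n)) {
    means <- .condition_means(kind[i], config$condition)
    # one per-neuron deviation, shared across laser powers so that only the
    # condition effect differs between powers
    dev <- stats::rnorm(4, 0, config$param_cv * abs(means["none", ]))
    par <- sweep(means, 2, dev, "+")
    par[, "width"] <- pmax(par[, "width"], 1)
    if (kind[i] == "gaussian") par[, "x_center"] <- pmin(pmax(par[, "x_center"], 10), 80)
    truth[[i]] <- data.frame(
      neuron = i, kind = kind[i], tagged = tagged[i],
      laser = rownames(par), par, row.names = NULL
    )
  }
  truth <- do.call(rbind, truth)

  grid <- expand.grid(
    trial = seq_len(config$n_trials), level = config$levels,
    laser = config$lasers, neuron = seq_len(n),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[, c("neuron", "level", "laser", "trial")]
  key <- match(
    paste(grid$neuron, grid$laser),
    paste(truth$neuron, truth$laser)
  )
  mu <- ifelse(
    truth$kind[key] == "sigmoid",
    sigmoid_response(grid$level, truth$y0[key], truth$yrange[key],
                     truth$x_center[key], truth$width[key]),
    gaussian_response(grid$level, truth$y0[key], truth$yrange[key],
                      truth$x_center[key], truth$width[key])
  )
  sd_trial <- if (config$heteroscedastic) {
    config$noise_sd * (0.5 + 0.5 * abs(mu))
  } else {
    config$noise_sd
  }
  grid$response <- mu + stats::rnorm(nrow(grid), 0, sd_trial)
  structure(list(truth = truth, table = grid, config = config),
            class = "synth_population")
}

# Difference-of-exponentials calcium kernel sampled on the frame grid,
# zero before the onset delay. t in seconds from stimulus onset.
.calcium_kernel <- function(t, delay = 0.3, tau_rise = 0.05, tau_decay = 1.0) {
  u <- pmax(t - delay, 0)
  k <- exp(-u / tau_decay) - exp(-u / tau_rise)
  k[t < delay] <- 0
  k
}

#' Generate frame-level fluorescence traces for a synthetic population
#'
#' Builds raw-fluorescence traces with one second of baseline noise followed
#' by a calcium-like transient (fast rise, ~1 s decay, configurable onset
#' delay), scaled so that the mean dF/Fstd over the first post-onset second
#' reproduces each trial's tabled response.
#'
#' @param population A `"synth_population"` from [generate_population()].
#' @param post_s Seconds of trace retained after stimulus onset (>= 5 so a
#'   sliding 1-s window can start anywhere in 0-4 s).
#' @return A list of class `"trace_set"` with elements `F` (array neuron x
#'   trial x frame, raw fluorescence a.u.), `frame_rate`, `onset_frame`
#'   (1-based index of the stimulus-onset frame), and `trials` (data frame
#'   mapping the trial axis to `level`, `laser`, `trial`).
#' @export
generate_traces <- function(population, post_s = 5.5) {
  stopifnot(inherits(population, "synth_population"), post_s >= 5)
  config <- population$config
  fr <- config$frame_rate
  set.seed(config$seed + 1L)

  onset_frame <- round(fr) + 1L              # 1 s of baseline before onset
  n_frames <- round((1 + post_s) * fr)
  t_from_onset <- (seq_len(n_frames) - onset_frame) / fr
  kernel <- .calcium_kernel(t_from_onset, delay = config$onset_delay_s)
  win <- onset_frame:(onset_frame + round(fr) - 1L)  # the [0,1] s window
  kernel_gain <- mean(kernel[win])

  tab <- population$table
  trials <- unique(tab[, c("level", "laser", "trial")])
  trials <- trials[order(match(trials$laser, config$lasers), trials$level, trials$trial), ]
  rownames(trials) <- NULL
  n <- config$n_neurons
  n_tr <- nrow(trials)

  resp <- matrix(NA_real_, n, n_tr)
  idx <- match(
    paste(tab$level, tab$laser, tab$trial),
    paste(trials$level, trials$laser, trials$trial)
  )
  resp[cbind(tab$neuron, idx)] <- tab$response

  f0 <- 100                                  # baseline fluorescence, a.u.
  sd_b <- 1                                  # baseline noise sd, a.u.
  F <- array(stats::rnorm(n * n_tr * n_frames, f0, sd_b), dim = c(n, n_tr, n_frames))
  amp <- resp / kernel_gain                  # a.u. per unit dF/Fstd response
  signal <- outer(amp, kernel)               # neuron x trial x frame
  F <- F + sd_b * signal
  structure(list(F = F, frame_rate = fr, onset_frame = onset_frame,
                 trials = trials),
            class = "trace_set")
}

#' Generate per-cell green/red channel summary signals
#'
#' Emulates the interneuron-tagging measurement: the green channel carries
#' activity-driven fluctuations, and the red (static-marker) channel is
#' bleedthrough from the green plus, for tagged cells, a constant elevation
#' above the background, plus background noise.
#'
#' @param population A `"synth_population"` from [generate_population()].
#' @param n_frames Frames of channel signal per cell.
#' @param background_sd Red-channel background noise sd (a.u.).
#' @param elevation Red-channel elevation of tagged cells, in units of
#'   `background_sd` (default 5, comfortably above the 2-sigma tagging rule).
#' @return A list with matrices `green` and `red` (cells x frames),
#'   `background_sd`, `background_mean` (0), and the ground-truth `tagged`
#'   flags.
#' @export
generate_channel_signals <- function(population, n_frames = 300,
                                     background_sd = 1, elevation = 5) {
  stopifnot(inherits(population, "synth_population"))
  config <- population$config
  set.seed(config$seed + 2L)
  n <- config$n_neurons
  tagged <- population$truth$tagged[match(seq_len(n), population$truth$neuron)]
  g0 <- stats::runif(n, 30, 70)              # per-cell green baseline
  green <- matrix(stats::rnorm(n * n_frames, 0, 5), n, n_frames) + g0
  red <- config$bleedthrough_coef * green +
    tagged * elevation * background_sd +
    matrix(stats::rnorm(n * n_frames, 0, background_sd), n, n_frames)
  list(green = green, red = red, background_sd = background_sd,
       background_mean = 0, tagged = tagged)
}
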