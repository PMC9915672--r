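#' Response-level curves (mean and sem per level) from a response table
#'
#' @param table A response table (`neuron`, `level`, `laser`, `trial`,
#'   `response`; fixed-window responses by convention).
#' @return Data frame `neuron`, `laser`, `level`, `mean`, `sem`.
#' @export
response_level_curves <- function(table) {
  mean_agg <- stats::aggregate(response ~ neuron + laser + level, table, mean)
  sem_agg <- stats::aggregate(response ~ neuron + laser + level, table,
                              function(x) stats::sd(x) / sqrt(length(x)))
  out <- merge(mean_agg, sem_agg, by = c("neuron", "laser", "level"),
               suffixes = c(".mean", ".sem"))
  names(out)[names(out) == "response.mean"] <- "mean"
  names(out)[names(out) == "response.sem"] <- "sem"
  out[order(out$neuron, out$laser, out$level), ]
}

#' Monotonicity index of a response-level curve
#'
#' `MI = (response at the highest level - response at 0 dB) / (max - min)`
#' of the mean curve, after normalizing the curve so that
#' `abs(max(response)) <= 1`. MI near 1 indicates a monotonically increasing
#' curve; MI near 0 a curve that returns to its spontaneous response at the
#' highest level. The index is invariant under positive affine transforms of
#' the curve. A flat curve has an undefined MI and returns `NA`.
#'
#' @param means Mean responses, one per level, ordered as `levels`.
#' @param levels Sound pressure levels (ascending, first must be 0).
#' @return MI (dimensionless) or `NA_real_` for a flat curve.
#' @export
#' @examples
#' monotonicity_index(c(0, .2, .5, 1, .5, .2, .1), c(0, 30, 50, 60, 70, 80, 90)) # 0.1
monotonicity_index <- function(means, levels) {
  stopifnot(length(means) == length(levels), !is.unsorted(levels),
            levels[1] == 0)
  if (max(means) == min(means)) return(NA_real_)
  m <- means / max(abs(means))
  (m[which.max(levels)] - m[1]) / (max(m) - min(m))
}

#' Classify a response-level curve by its monotonicity index
#'
#' MI < 0.3 is nonmonotonic, MI > 0.7 monotonic; values between are
#' ambiguous (such curves are fit with both models and the better fit kept).
#'
#' @param mi Monotonicity index.
#' @return `"monotonic"`, `"nonmonotonic"`, or `"ambiguous"`.
#' @export
classify_monotonicity <- function(mi) {
  stopifnot(is.finite(mi))
  if (mi < 0.3) "nonmonotonic" else if (mi > 0.7) "monotonic" else "ambiguous"
}

#' Weighted McFadden pseudo-R-squared objective
#'
#' The quantity minimized when fitting response-level curves:
#' `1 - R2 = sum((y - mean)^2 / sem^2) / sum((grand_mean - mean)^2 / sem^2)`,
#' the sem-weighted squared error of the model relative to that of the
#' intercept-only model (the grand mean of the level means). It equals 0 for
#' a model that interpolates the data and exactly 1 for the intercept model,
#' and unlike a plain R-squared it admits level-dependent sem.
#'
#' sem values are floored at `1e-6 * max(abs(mean), 1)` to avoid infinite
#' weights.
#'
#' @param pred Model predictions at the levels.
#' @param means Observed mean responses.
#' @param sems Observed standard errors of the mean.
#' @return `1 - R2` (0 = perfect fit, 1 = intercept model).
#' @export
mcfadden_objective <- function(pred, means, sems) {
  stopifnot(length(pred) == length(means), length(means) == length(sems),
            all(sems >= 0))
  floor_ <- 1e-6 * max(abs(means), 1)
  w <- 1 / pmax(sems, floor_)^2
  den <- sum(w * (mean(means) - means)^2)
  if (den == 0) stop("degenerate objective: flat mean curve", call. = FALSE)
  sum(w * (pred - means)^2) / den
}

#' Interpolation-based overfitting diagnostic for a fitted curve
#'
#' Checks that the fitted model is not overfit to the empirical sound
#' levels: a piecewise-linear interpolant is built through the model's
#' values at the 7 empirical levels, and compared with the analytic model
#' evaluated at the 13-point grid including the intermediate levels
#' (15, 40, 55, 65, 75, 85 dB). Returns the R-squared
#' `1 - sum((model - interpolant)^2) / sum((interpolant - mean)^2)`;
#' fits with a value below 0.25 are rejected.
#'
#' @param params Model parameters (see [evaluate_model()]).
#' @param kind `"sigmoid"` or `"gaussian"`.
#' @param levels The empirical levels (default `c(0,30,50,60,70,80,90)`).
#' @return Interpolated-error R-squared; `NA` if the interpolant is constant.
#' @export
interpolated_error <- function(params, kind,
                               levels = c(0, 30, 50, 60, 70, 80, 90)) {
  intermediate <- c(15, 40, 55, 65, 75, 85)
  grid13 <- sort(c(levels, intermediate))
  fitted7 <- evaluate_model(params, levels, kind)
  interp <- stats::approx(levels, fitted7, xout = grid13)$y
  model13 <- evaluate_model(params, grid13, kind)
  den <- sum((interp - mean(interp))^2)
  if (den == 0) return(NA_real_)
  1 - sum((model13 - interp)^2) / den
}

# Random starting point for one model kind, per the documented ranges.
.random_start <- function(means, kind) {
  rng <- max(means) - min(means)
  rng <- max(rng, 1e-3)
  c(
    stats::runif(1, min(means) - rng, max(means)),   # y0
    stats::runif(1, 1e-6, 2 * rng),                  # yrange
    stats::runif(1, 0, 90),                          # x0 / xmean
    stats::runif(1, 1, 45)                           # dx / sigma
  )
}

# Multi-start minimization of the McFadden objective for one model kind.
# Width <= 0 is excluded by a penalty. Returns best params/objective and the
# number of starts that converged.
.fit_kind <- function(means, sems, levels, kind, n_starts) {
  obj <- function(p) {
    if (!all(is.finite(p)) || p[4] <= 0) return(1e10)
    mcfadden_objective(evaluate_model(p, levels, kind), means, sems)
  }
  best <- NULL
  n_ok <- 0L
  for (k in seq_len(n_starts)) {
    res <- tryCatch(
      stats::optim(.random_start(means, kind), obj, method = "Nelder-Mead",
                   control = list(maxit = 500, reltol = 1e-8)),
      error = function(e) NULL
    )
    if (is.null(res) || res$convergence != 0 || !is.finite(res$value) ||
        res$value >= 1e10 || !all(is.finite(res$par))) {
      next
    }
    n_ok <- n_ok + 1L
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) return(NULL)
  list(params = best$par, objective = best$value, n_successful = n_ok)
}

#' Fit a response-level curve with the sigmoid/Gaussian model
#'
#' Classifies the curve by monotonicity index, then fits the corresponding
#' model (both models for ambiguous curves, keeping the higher R-squared) by
#' multi-start derivative-free minimization of the weighted McFadden
#' objective (16 random starts; a fit requires at least 2 convergent
#' starts). Gaussian fits whose mean falls outside \[10, 80\] dB are refit
#' with the sigmoid model, since a peak supported by a single extreme level
#' cannot distinguish monotonic from nonmonotonic tuning. A fit is accepted
#' when McFadden R-squared > 0.8 and the interpolated error is >= 0.25.
#'
#' @param means Mean responses per level.
#' @param sems Standard errors per level.
#' @param levels Sound pressure levels (ascending, starting at 0).
#' @param n_starts Number of random optimizer starts.
#' @param seed Optional integer seed for the start draws.
#' @return A one-row data frame: `mi`, `class`, `kind`, `y0`, `yrange`,
#'   `x_center`, `width`, `mcfadden_r2`, `interp_error`,
#'   `n_successful_starts`, `refit`, `accepted`. `kind` is `"none"` when no
#'   start converged or the curve is flat.
#' @export
fit_curve <- function(means, sems, levels = c(0, 30, 50, 60, 70, 80, 90),
                      n_starts = 16, seed = NULL) {
  stopifnot(length(means) == length(levels), length(sems) == length(levels))
  if (!is.null(seed)) set.seed(seed)
  empty <- data.frame(
    mi = NA_real_, class = NA_character_, kind = "none",
    y0 = NA_real_, yrange = NA_real_, x_center = NA_real_, width = NA_real_,
    mcfadden_r2 = NA_real_, interp_error = NA_real_,
    n_successful_starts = 0L, refit = FALSE, accepted = FALSE,
    stringsAsFactors = FALSE
  )
  mi <- monotonicity_index(means, levels)
  if (is.na(mi)) return(empty)
  cls <- classify_monotonicity(mi)
  empty$mi <- mi; empty$class <- cls

  kinds <- switch(cls,
    monotonic = "sigmoid",
    nonmonotonic = "gaussian",
    ambiguous = c("sigmoid", "gaussian")
  )
  fits <- list()
  for (k in kinds) fits[[k]] <- .fit_kind(means, sems, levels, k, n_starts)
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) return(empty)
  kind <- names(fits)[which.min(vapply(fits, `[[`, numeric(1), "objective"))]
  fit <- fits[[kind]]

  refit <- FALSE
  if (kind == "gaussian" && (fit$params[3] < 10 || fit$params[3] > 80)) {
    refit <- TRUE
    kind <- "sigmoid"
    fit <- if ("sigmoid" %in% names(fits)) fits[["sigmoid"]] else {
      .fit_kind(means, sems, levels, "sigmoid", n_starts)
    }
    if (is.null(fit)) { empty$refit <- TRUE; return(empty) }
  }

  r2 <- 1 - fit$objective
  ie <- interpolated_error(fit$params, kind, levels)
  accepted <- fit$n_successful >= 2 && r2 > 0.8 && !is.na(ie) && ie >= 0.25 &&
    (kind != "gaussian" || (fit$params[3] >= 10 && fit$params[3] <= 80))
  data.frame(
    mi = mi, class = cls, kind = kind,
    y0 = fit$params[1], yrange = fit$params[2],
    x_center = fit$params[3], width = fit$params[4],
    mcfadden_r2 = r2, interp_error = ie,
    n_successful_starts = fit$n_successful, refit = refit, accepted = accepted,
    stringsAsFactors = FALSE
  )
}

#' Fit response-level curves for every neuron and laser power
#'
#' @param curves Output of [response_level_curves()].
#' @param n_starts Random starts per fit.
#' @param seed Integer seed; per-curve sub-seeds are derived from it so the
#'   result is reproducible and independent of iteration order.
#' @return Data frame with one row per neuron x laser (columns of
#'   [fit_curve()] plus `neuron` and `laser`).
#' @export
fit_population <- function(curves, n_starts = 16, seed = 1L) {
  keys <- unique(curves[, c("neuron", "laser")])
  out <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    cc <- curves[curves$neuron == keys$neuron[i] & curves$laser == keys$laser[i], ]
    cc <- cc[order(cc$level), ]
    fit <- fit_curve(cc$mean, cc$sem, cc$level, n_starts = n_starts,
                     seed = (seed + 7919L * i) %% .Machine$integer.max)
    out[[i]] <- cbind(keys[i, , drop = FALSE], fit)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
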