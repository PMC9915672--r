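#' Two-cell model configuration
#'
#' The analytic localist-versus-distributed model: one monotonic cell
#' (sigmoid tuning) and one nonmonotonic cell (Gaussian tuning), with
#' per-condition parameter sets for no interneuron activation and for SST or
#' VIP activation at high laser power. Only the parameters affected by each
#' condition differ from the no-activation values: SST activation shifts the
#' sigmoid midpoint rightward (55 to 68 dB) and shrinks the Gaussian offset
#' and range; VIP activation grows the sigmoid range and broadens/shifts the
#' Gaussian.
#'
#' @param sigmoid Named list of sigmoid parameter vectors
#'   `(y0, yrange, x0, dx)` per condition (`none`, `SST`, `VIP`).
#' @param gaussian Named list of Gaussian parameter vectors
#'   `(y0, yrange, xmean, sigma)` per condition.
#' @param levels Sound-level grid in dB SPL (default 0-90 in 1 dB steps).
#' @return A list of class `"two_cell_config"`.
#' @export
two_cell_config <- function(
    sigmoid = list(
      none = c(y0 = -0.12, yrange = 0.88, x0 = 55, dx = 11),
      SST  = c(y0 = -0.12, yrange = 0.88, x0 = 68, dx = 11),
      VIP  = c(y0 = -0.12, yrange = 1.43, x0 = 55, dx = 11)
    ),
    gaussian = list(
      none = c(y0 = -0.04, yrange = 0.54, xmean = 50, sigma = 13),
      SST  = c(y0 = -0.07, yrange = 0.27, xmean = 50, sigma = 13),
      VIP  = c(y0 = -0.04, yrange = 0.86, xmean = 54, sigma = 17)
    ),
    levels = 0:90) {
  stopifnot(identical(names(sigmoid), names(gaussian)),
            all(vapply(c(sigmoid, gaussian), length, integer(1)) == 4),
            0 %in% levels)
  structure(list(sigmoid = sigmoid, gaussian = gaussian, levels = levels),
            class = "two_cell_config")
}

#' Two-cell model responses on the sound-level grid
#'
#' Row 1 is the monotonic (sigmoid) cell, row 2 the nonmonotonic (Gaussian)
#' cell, evaluated at every level of the grid. The trajectory form subtracts
#' each cell's response at 0 dB, so the population trajectory starts at the
#' origin.
#'
#' @param config A [two_cell_config()].
#' @param condition `"none"`, `"SST"`, or `"VIP"`.
#' @param subtract_silence If `TRUE`, subtract each cell's 0 dB response.
#' @return 2 x length(levels) matrix with rownames
#'   `c("monotonic", "nonmonotonic")` and colnames the levels.
#' @export
model_responses <- function(config, condition, subtract_silence = FALSE) {
  stopifnot(inherits(config, "two_cell_config"),
            condition %in% names(config$sigmoid))
  lv <- config$levels
  r <- rbind(
    monotonic = evaluate_model(config$sigmoid[[condition]], lv, "sigmoid"),
    nonmonotonic = evaluate_model(config$gaussian[[condition]], lv, "gaussian")
  )
  colnames(r) <- lv
  if (subtract_silence) r <- r - r[, which(lv == 0)]
  r
}

#' Separation-angle matrix of the two-cell model
#'
#' Angle between the silence-referenced response vectors
#' `r(s1) - r(0)` and `r(s2) - r(0)` for every pair of nonzero sound levels.
#' Entries where either vector has zero length are `NA` and are excluded
#' from summaries.
#'
#' @param config A [two_cell_config()].
#' @param condition `"none"`, `"SST"`, or `"VIP"`.
#' @return Symmetric matrix (nonzero levels x nonzero levels), degrees,
#'   diagonal 0.
#' @export
angle_matrix <- function(config, condition) {
  r <- model_responses(config, condition, subtract_silence = TRUE)
  lv <- config$levels
  nz <- lv[lv != 0]
  v <- r[, as.character(nz), drop = FALSE]
  n <- length(nz)
  norms <- sqrt(colSums(v^2))
  A <- matrix(NA_real_, n, n, dimnames = list(nz, nz))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    A[i, j] <- if (i == j) 0 else separation_angle(v[, i], v[, j])
  }
  A
}

#' Vector-length matrix of the two-cell model
#'
#' Euclidean distance `||r(s2) - r(s1)||` between the raw (non-subtracted)
#' two-cell responses for every pair of sound levels.
#'
#' @param config A [two_cell_config()].
#' @param condition `"none"`, `"SST"`, or `"VIP"`.
#' @return Symmetric matrix (levels x levels), a.u., diagonal 0.
#' @export
length_matrix <- function(config, condition) {
  r <- model_responses(config, condition, subtract_silence = FALSE)
  lv <- config$levels
  n <- length(lv)
  L <- matrix(0, n, n, dimnames = list(lv, lv))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    L[i, j] <- vector_length(r[, i], r[, j])
  }
  L
}

#' Mean condition difference over a range of sound-level pairs
#'
#' Mean, over unordered pairs `s1 < s2` with both levels inside `range`, of
#' `matrix_cond - matrix_none` (diagonal excluded, `NA` entries dropped).
#'
#' @param matrix_cond,matrix_none Matrices on the same level grid (dimnames
#'   are the levels).
#' @param range Length-2 numeric, inclusive level range (e.g. `c(1, 90)` or
#'   `c(30, 90)`).
#' @return Scalar mean difference (degrees or a.u.).
#' @export
mean_condition_difference <- function(matrix_cond, matrix_none,
                                      range = c(1, 90)) {
  stopifnot(identical(dimnames(matrix_cond), dimnames(matrix_none)),
            length(range) == 2)
  lv <- as.numeric(rownames(matrix_cond))
  keep <- lv >= range[1] & lv <= range[2]
  if (sum(keep) < 2) stop("empty pair range", call. = FALSE)
  d <- matrix_cond[keep, keep] - matrix_none[keep, keep]
  mean(d[upper.tri(d)], na.rm = TRUE)
}

#' The eight mean condition differences of the two-cell model
#'
#' Mean separation-angle and vector-length differences (condition minus no
#' activation) over sound pairs 1-90 dB and 30-90 dB, for SST and VIP
#' activation.
#'
#' @param config A [two_cell_config()].
#' @return Data frame `condition`, `metric`, `range`, `value`.
#' @export
two_cell_summary <- function(config = two_cell_config()) {
  A0 <- angle_matrix(config, "none")
  L0 <- length_matrix(config, "none")
  rows <- list()
  for (cond in c("SST", "VIP")) {
    Ac <- angle_matrix(config, cond)
    Lc <- length_matrix(config, cond)
    for (rg in list(c(1, 90), c(30, 90))) {
      rows[[length(rows) + 1]] <- data.frame(
        condition = cond,
        metric = c("angle", "length"),
        range = paste0(rg[1], "-", rg[2]),
        value = c(mean_condition_difference(Ac, A0, rg),
                  mean_condition_difference(Lc, L0, rg))
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Gain-regime curve of one model cell under interneuron activation
#'
#' Pairs the cell's response without activation with its response under the
#' condition, at every grid level, and labels the gain regime from a linear
#' fit of on-laser versus off-laser response: slope below 1 is divisive,
#' above 1 multiplicative; a negative intercept is subtractive, a positive
#' one additive; combinations are labelled jointly and slope ~= 1 with
#' intercept ~= 0 is the identity.
#'
#' @param config A [two_cell_config()].
#' @param cell `"monotonic"` or `"nonmonotonic"`.
#' @param condition `"none"`, `"SST"`, or `"VIP"`.
#' @param fit_range Level range (dB) over which the linear fit is taken.
#' @param slope_tol Half-width of the slope band counted as "~= 1".
#' @param intercept_tol Half-width of the intercept band counted as "~= 0"
#'   (a.u.).
#' @return List with `pairs` (data frame `level`, `off`, `on`), `slope`,
#'   `intercept`, and `regime` (character label).
#' @export
gain_curve <- function(config, cell = c("monotonic", "nonmonotonic"),
                       condition, fit_range = c(0, 90),
                       slope_tol = 0.05, intercept_tol = 0.02) {
  cell <- match.arg(cell)
  off <- model_responses(config, "none")[cell, ]
  on <- model_responses(config, condition)[cell, ]
  lv <- config$levels
  pairs <- data.frame(level = lv, off = off, on = on, row.names = NULL)
  keep <- lv >= fit_range[1] & lv <= fit_range[2]
  fit <- stats::lm(on ~ off, data = pairs[keep, ])
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  comp <- character(0)
  if (slope < 1 - slope_tol) comp <- c(comp, "divisive")
  if (slope > 1 + slope_tol) comp <- c(comp, "multiplicative")
  if (intercept < -intercept_tol) comp <- c(comp, "subtractive")
  if (intercept > intercept_tol) comp <- c(comp, "additive")
  regime <- if (length(comp) == 0) "identity" else paste(comp, collapse = "+")
  list(pairs = pairs, slope = slope, intercept = intercept, regime = regime)
}
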