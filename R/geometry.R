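#' Mean population vector for one sound and laser condition
#'
#' The per-neuron mean response over trials at the given condition,
#' optionally with the same-laser silence (0 dB) vector subtracted so the
#' vector originates at the population's response to silence.
#'
#' @param table A response table (fixed-window responses for geometry).
#' @param level Sound pressure level (dB SPL).
#' @param laser Laser condition.
#' @param subtract_silence If `TRUE`, subtract the same-laser 0 dB vector.
#' @return Named numeric vector (one entry per neuron).
#' @export
mean_population_vector <- function(table, level, laser, subtract_silence = FALSE) {
  sub <- table[table$level == level & table$laser == laser, ]
  if (nrow(sub) == 0) stop("condition not present in table", call. = FALSE)
  v <- tapply(sub$response, sub$neuron, mean)
  v <- stats::setNames(as.numeric(v), names(v))[order(as.numeric(names(v)))]
  if (subtract_silence) {
    v <- v - mean_population_vector(table, 0, laser, subtract_silence = FALSE)
  }
  v
}

#' Separation angle between two population vectors
#'
#' `acos(u . v / (|u| |v|))` in degrees, in \[0, 180\]. Both vectors should be
#' silence-subtracted at the same laser power. Zero-norm inputs have an
#' undefined angle and return `NA` (excluded from summaries).
#'
#' @param u,v Numeric vectors of equal length.
#' @return Angle in degrees, or `NA_real_` for a zero-norm input.
#' @export
#' @examples
#' separation_angle(c(1, 0), c(0, 1)) # 90
#' separation_angle(c(1, 0), c(1, 1)) # 45
separation_angle <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(NA_real_)
  acos(max(-1, min(1, sum(u * v) / (nu * nv)))) * 180 / pi
}

#' Euclidean length between two population vectors
#'
#' @param a,b Numeric vectors of equal length (raw, non-subtracted mean
#'   population vectors).
#' @return `||b - a||` (a.u.), nonnegative and symmetric.
#' @export
vector_length <- function(a, b) {
  if (length(a) != length(b)) stop("dimension mismatch", call. = FALSE)
  sqrt(sum((b - a)^2))
}

#' Population-geometry summary of a response table
#'
#' For each laser power: the matrix of separation angles between
#' silence-subtracted mean population vectors to each pair of nonzero sound
#' levels, and the matrix of Euclidean lengths between the raw mean
#' population vectors to each pair of sound levels. Laser-minus-none
#' difference matrices and per-|delta-level| means are included, along with
#' the mean over unordered pairs of each difference matrix (diagonal
#' excluded).
#'
#' @param table A response table (fixed-window responses).
#' @return A list of class `"geometry_summary"`:
#'   \describe{
#'     \item{angle, length}{named lists of symmetric matrices per laser.}
#'     \item{angle_diff, length_diff}{difference matrices, laser minus
#'       no-laser, for each non-none laser.}
#'     \item{mean_angle_diff, mean_length_diff}{named numeric: mean over
#'       unordered pairs of each difference matrix.}
#'     \item{by_delta}{data frame `laser`, `metric`, `delta`, `mean`.}
#'   }
#' @export
geometry_summary <- function(table) {
  lasers <- unique(table$laser)
  levels <- sort(unique(table$level))
  nz <- levels[levels != 0]

  angle <- length_ <- list()
  for (ll in lasers) {
    vecs_sub <- lapply(nz, function(s) mean_population_vector(table, s, ll, TRUE))
    vecs_raw <- lapply(levels, function(s) mean_population_vector(table, s, ll, FALSE))
    A <- matrix(NA_real_, length(nz), length(nz), dimnames = list(nz, nz))
    for (i in seq_along(nz)) for (j in seq_along(nz)) {
      A[i, j] <- if (i == j) 0 else separation_angle(vecs_sub[[i]], vecs_sub[[j]])
    }
    L <- matrix(0, length(levels), length(levels), dimnames = list(levels, levels))
    for (i in seq_along(levels)) for (j in seq_along(levels)) {
      L[i, j] <- vector_length(vecs_raw[[i]], vecs_raw[[j]])
    }
    angle[[ll]] <- A
    length_[[ll]] <- L
  }

  others <- setdiff(lasers, "none")
  angle_diff <- lapply(angle[others], function(m) m - angle[["none"]])
  length_diff <- lapply(length_[others], function(m) m - length_[["none"]])
  pair_mean <- function(m) mean(m[upper.tri(m)], na.rm = TRUE)

  by_delta <- do.call(rbind, lapply(lasers, function(ll) {
    rbind(
      .delta_means(angle[[ll]], ll, "angle"),
      .delta_means(length_[[ll]], ll, "length")
    )
  }))

  structure(list(
    angle = angle, length = length_,
    angle_diff = angle_diff, length_diff = length_diff,
    mean_angle_diff = vapply(angle_diff, pair_mean, numeric(1)),
    mean_length_diff = vapply(length_diff, pair_mean, numeric(1)),
    by_delta = by_delta
  ), class = "geometry_summary")
}

# Mean matrix entry per |level difference| over unordered pairs.
.delta_means <- function(m, laser, metric) {
  lv <- as.numeric(rownames(m))
  ut <- which(upper.tri(m), arr.ind = TRUE)
  delta <- abs(lv[ut[, 2]] - lv[ut[, 1]])
  vals <- m[ut]
  agg <- tapply(vals, delta, mean, na.rm = TRUE)
  data.frame(laser = laser, metric = metric,
             delta = as.numeric(names(agg)), mean = as.numeric(agg),
             row.names = NULL)
}
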