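#' Lifetime sparseness of a neuron's response across sound levels
#'
#' Rolls-Tovee-style sparseness adapted to fluorescence responses:
#' `S = (1 - (sum(r)/n)^2 / (sum(r^2)/n)) / (1 - 1/n)`,
#' where `r` are the neuron's mean responses to the `n` nonzero sound levels
#' (baseline-subtracted, negative values rectified to zero before the
#' computation). `S = 0` when all responses are equal; `S = 1` when exactly
#' one level elicits a response. Neurons with no positive response have
#' undefined sparseness and return `NA` (they are excluded from summaries).
#'
#' @param r Numeric vector of per-level mean responses (dF/F units).
#' @return Sparseness in \[0, 1\], or `NA_real_` if all rectified responses
#'   are zero.
#' @export
#' @examples
#' neuron_sparseness(c(1, 0, 0, 0, 0, 0))   # one-hot: 1
#' neuron_sparseness(rep(2, 6))             # uniform: 0
#' neuron_sparseness(c(1, 1, 0, 0, 0, 0))   # 0.8
neuron_sparseness <- function(r) {
  stopifnot(length(r) >= 2, all(is.finite(r)))
  r <- pmax(r, 0)
  if (all(r == 0)) return(NA_real_)
  n <- length(r)
  (1 - (sum(r) / n)^2 / (sum(r^2) / n)) / (1 - 1 / n)
}

#' Lifetime sparseness for every neuron in a response table
#'
#' Computes, for each neuron and laser power, the sparseness of its mean
#' responses to the nonzero sound levels after subtracting its own response
#' to silence (0 dB) at the same laser power.
#'
#' @param table A response table (`neuron`, `level`, `laser`, `trial`,
#'   `response`), ideally from optimal windows.
#' @param lasers Laser conditions to include (default: all in the table).
#' @return Data frame `neuron`, `laser`, `sparseness` (`NA` where undefined).
#' @export
population_sparseness <- function(table, lasers = unique(table$laser)) {
  means <- .neuron_level_means(table)
  out <- expand.grid(neuron = sort(unique(means$neuron)), laser = lasers,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$sparseness <- mapply(function(nn, ll) {
    m <- means[means$neuron == nn & means$laser == ll, ]
    m <- m[order(m$level), ]
    ref <- m$mean[m$level == 0]
    neuron_sparseness(m$mean[m$level != 0] - ref)
  }, out$neuron, out$laser)
  out
}

#' Activity sparseness of a population
#'
#' Fraction of neurons NOT responding above threshold to each sound level,
#' relative to silence. The reference is each neuron's mean response at 0 dB
#' either at the same laser power (`reference = "same"`) or at no laser
#' (`reference = "none"`). The threshold is the standard deviation, across
#' neurons, of the mean response at 0 dB with no laser. 0 means every neuron
#' is active; 1 means none is.
#'
#' When `reference = "none"`, the 0 dB / no-laser point is 100% by
#' construction and is omitted from the output.
#'
#' @param table A response table (optimal-window responses).
#' @param reference `"same"` (silence at the same laser power) or `"none"`
#'   (silence with no laser).
#' @return Data frame `laser`, `level`, `activity_sparseness` (in \[0, 1\]).
#' @export
activity_sparseness <- function(table, reference = c("same", "none")) {
  reference <- match.arg(reference)
  means <- .neuron_level_means(table)
  if (nrow(means) == 0) stop("empty population", call. = FALSE)
  neurons <- sort(unique(means$neuron))
  lasers <- unique(table$laser)
  levels <- sort(unique(means$level))
  threshold <- stats::sd(means$mean[means$level == 0 & means$laser == "none"])
  ref_laser <- function(ll) if (reference == "same") ll else "none"
  out <- expand.grid(level = levels, laser = lasers,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$activity_sparseness <- mapply(function(lev, ll) {
    m <- means[means$laser == ll & means$level == lev, ]
    m <- m$mean[order(m$neuron)]
    r <- means[means$laser == ref_laser(ll) & means$level == 0, ]
    r <- r$mean[order(r$neuron)]
    mean(!(m > r + threshold))
  }, out$level, out$laser)
  if (reference == "none") {
    out <- out[!(out$laser == "none" & out$level == 0), ]
  }
  rownames(out) <- NULL
  out
}

#' Empirical cumulative distribution of sparseness values
#'
#' @param values Numeric vector in \[0, 1\]; `NA`s are dropped.
#' @return Data frame `value`, `cdf` (nondecreasing, ending at 1), sorted by
#'   value.
#' @export
sparseness_cdf <- function(values) {
  values <- values[!is.na(values)]
  stopifnot(length(values) > 0, all(values >= 0 & values <= 1))
  v <- sort(values)
  data.frame(value = v, cdf = seq_along(v) / length(v))
}

# Per-neuron mean response by level and laser.
.neuron_level_means <- function(table) {
  agg <- stats::aggregate(response ~ neuron + level + laser, data = table, FUN = mean)
  names(agg)[names(agg) == "response"] <- "mean"
  agg
}
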