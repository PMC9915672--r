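#' Decoder configuration
#'
#' @param variance_capture Fraction of variance the PCA projection must
#'   capture (default 0.70).
#' @param n_oversample Trials per class after oversampling (default 60).
#' @param n_folds Cross-validation folds (default 10).
#' @param cost Linear-SVM regularization parameter C (default 1; the decoder
#'   is used without hyperparameter tuning).
#' @param seed Integer seed controlling fold assignment and KDE draws.
#' @return A list of class `"decoder_config"`.
#' @export
decoder_config <- function(variance_capture = 0.70, n_oversample = 60,
                           n_folds = 10, cost = 1, seed = 1L) {
  stopifnot(variance_capture > 0, variance_capture <= 1,
            n_oversample >= 2, n_folds >= 2)
  structure(list(variance_capture = variance_capture,
                 n_oversample = as.integer(n_oversample),
                 n_folds = as.integer(n_folds), cost = cost,
                 seed = as.integer(seed)),
            class = "decoder_config")
}

#' Project trials onto the leading principal components
#'
#' Keeps the smallest number of components whose cumulative explained
#' variance reaches `variance_capture`.
#'
#' @param x Trial x neuron response matrix (>= 2 trials).
#' @param variance_capture Fraction of variance to capture.
#' @return Trial x n score matrix (n components kept).
#' @export
project_pca <- function(x, variance_capture = 0.70) {
  stopifnot(is.matrix(x), nrow(x) >= 2)
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  v <- p$sdev^2
  if (sum(v) == 0) stop("degenerate input: zero variance", call. = FALSE)
  n <- which(cumsum(v) / sum(v) >= variance_capture - 1e-12)[1]
  p$x[, seq_len(n), drop = FALSE]
}

#' Oversample a class by Gaussian kernel density estimation
#'
#' Fits a Gaussian KDE to the class trials (product kernel, Scott's-rule
#' bandwidth per dimension) and draws `target` samples from it: each sample
#' is a randomly chosen trial plus Gaussian noise with the per-dimension
#' bandwidth. Dimensions with zero spread fall back to a tiny jitter so the
#' kernel is never singular.
#'
#' @param x Class trials, n x d matrix (n >= 2).
#' @param target Number of samples to draw.
#' @param seed Optional integer seed.
#' @return `target` x d matrix of samples.
#' @export
oversample_kde <- function(x, target = 60, seed = NULL) {
  stopifnot(is.matrix(x), nrow(x) >= 2)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(x); d <- ncol(x)
  s <- apply(x, 2, stats::sd)
  s[s == 0] <- 1e-8 * max(1, max(abs(x)))     # jitter fallback
  h <- n^(-1 / (d + 4)) * s                   # Scott's rule
  idx <- sample.int(n, target, replace = TRUE)
  out <- x[idx, , drop = FALSE] +
    matrix(stats::rnorm(target * d), target, d) %*% diag(h, d, d)
  attr(out, "parent") <- idx
  out
}

#' One-vs-rest linear SVM decoding of sound pressure level
#'
#' For each sound level at the given laser power: project all trials of that
#' laser condition onto the leading PCs (fit once per laser condition),
#' balance the 10-vs-60 two-class problem by KDE-oversampling the one-level
#' class to 60 trials, then train a linear-kernel SVM with stratified
#' 10-fold cross-validation and report the mean validation accuracy.
#'
#' Folds are assigned at the level of the original trials, and each KDE
#' sample inherits the fold of its parent trial. This keeps samples derived
#' from the same measured trial on one side of every train/validation split,
#' so the cross-validated accuracy is not inflated by resampling leakage and
#' label shuffling yields chance (0.5) accuracy.
#'
#' @param table A response table (fixed-window responses) with 10 trials per
#'   level x laser.
#' @param laser Laser condition to decode within.
#' @param config A [decoder_config()].
#' @param shuffle If `TRUE`, permute the class labels of the assembled
#'   two-class dataset before training (permutation chance baseline: labels
#'   are independent of the responses, so accuracy ~= 0.5). Note that
#'   permuting the trial-to-level assignment instead would leave a chance
#'   label/level-cluster imbalance that a linear SVM can exploit in a
#'   dataset of only 10 trials per level, biasing the "chance" level upward.
#' @return Data frame `level`, `accuracy` (mean validation accuracy in
#'   \[0, 1\]).
#' @export
decode_levels <- function(table, laser, config = decoder_config(),
                          shuffle = FALSE) {
  stopifnot(inherits(config, "decoder_config"))
  sub <- table[table$laser == laser, ]
  levels <- sort(unique(sub$level))
  if (length(levels) < 2) stop("need at least two levels to decode", call. = FALSE)
  sub <- sub[order(sub$level, sub$trial, sub$neuron), ]
  neurons <- sort(unique(sub$neuron))
  key <- paste(sub$level, sub$trial)
  trial_keys <- unique(key)
  X <- matrix(sub$response[order(match(key, trial_keys), match(sub$neuron, neurons))],
              nrow = length(trial_keys), byrow = TRUE)
  y_level <- sub$level[match(trial_keys, key)]
  set.seed(config$seed)
  Z <- project_pca(X, config$variance_capture)

  acc <- vapply(levels, function(lv) {
    pos <- Z[y_level == lv, , drop = FALSE]
    neg <- Z[y_level != lv, , drop = FALSE]
    if (nrow(pos) == 0) stop("missing level", call. = FALSE)
    pos_os <- oversample_kde(pos, config$n_oversample)
    dat <- rbind(pos_os, neg)
    lab <- factor(rep(c("pos", "neg"), c(nrow(pos_os), nrow(neg))))
    # folds by original trial: KDE samples inherit their parent's fold
    pos_folds <- sample(rep_len(seq_len(config$n_folds), nrow(pos)))
    neg_folds <- sample(rep_len(seq_len(config$n_folds), nrow(neg)))
    folds <- c(pos_folds[attr(pos_os, "parent")], neg_folds)
    if (shuffle) lab <- sample(lab)
    fold_acc <- vapply(seq_len(config$n_folds), function(f) {
      tr <- folds != f
      fit <- e1071::svm(dat[tr, , drop = FALSE], lab[tr], kernel = "linear",
                        cost = config$cost, scale = FALSE)
      pred <- stats::predict(fit, dat[!tr, , drop = FALSE])
      mean(pred == lab[!tr])
    }, numeric(1))
    mean(fold_acc)
  }, numeric(1))
  data.frame(level = levels, accuracy = acc)
}
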