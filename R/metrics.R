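#' Squared correlation between predictions and observations
#'
#' The default follows common QSAR reporting: the squared Pearson correlation
#' between predicted and observed values (affine-invariant). The
#' coefficient of determination `1 - SS_res/SS_tot` is available via
#' `method = "determination"`.
#'
#' @param predicted,observed numeric vectors (>= 3 pairs).
#' @param method `"pearson"` (default) or `"determination"`.
#' @return scalar R^2.
#' @export
r_squared <- function(predicted, observed,
                      method = c("pearson", "determination")) {
  method <- match.arg(method)
  stopifnot(length(predicted) == length(observed))
  if (length(observed) < 3L) stop("need at least 3 pairs")
  if (stats::sd(observed) == 0)
    stop("R^2 is undefined for constant observations")
  if (method == "pearson") {
    if (stats::sd(predicted) == 0)
      stop("R^2 (squared Pearson) is undefined for constant predictions")
    stats::cor(predicted, observed)^2
  } else {
    1 - sum((observed - predicted)^2) / sum((observed - mean(observed))^2)
  }
}

#' Fraction of predictions within an n-fold factor
#'
#' For log10-scale values, the fraction of pairs whose prediction is within a
#' multiplicative factor `fold` of the measurement, i.e.
#' `|pred - obs| <= log10(fold)`; the boundary counts as within.
#'
#' @param predicted_log10,observed_log10 numeric vectors on the log10 scale.
#' @param fold multiplicative factor (> 1), e.g. 2 or 3.
#' @return fraction in `[0, 1]`.
#' @export
fold_accuracy <- function(predicted_log10, observed_log10, fold) {
  stopifnot(length(predicted_log10) == length(observed_log10), fold > 1)
  if (!length(predicted_log10)) stop("empty input")
  mean(abs(predicted_log10 - observed_log10) <= log10(fold))
}

#' Summarize prediction accuracy for one endpoint
#'
#' The live-performance summary archived after each model refresh: R^2, the
#' standard error of prediction (RMSE on the modeling scale) and the
#' fractions of compounds predicted within 2-fold and 3-fold of the
#' measurement (for log10-scale endpoints).
#'
#' @param predicted,observed numeric vectors on the modeling (log10) scale.
#' @param method passed to [r_squared()].
#' @return list with `r_squared`, `std_error`, `within_2fold`,
#'   `within_3fold`, `n`.
#' @export
evaluation_report <- function(predicted, observed, method = "pearson") {
  list(r_squared = r_squared(predicted, observed, method),
       std_error = sqrt(mean((predicted - observed)^2)),
       within_2fold = fold_accuracy(predicted, observed, 2),
       within_3fold = fold_accuracy(predicted, observed, 3),
       n = length(observed))
}

#' Prediction accuracy binned by training-set similarity
#'
#' Assigns each test compound its maximum Tanimoto similarity to the training
#' set, bins compounds over `[0, 1]` and reports the per-bin count and R^2
#' (undefined, `NA`, for bins with fewer than `min_n` compounds): the
#' similarity/accuracy table behind coverage analyses.
#'
#' @param predicted,observed numeric vectors over the test set.
#' @param test,training lists of [molecule()]s or `fingerprint`s; `test` may
#'   be omitted when `similarities` is given.
#' @param breaks increasing bin edges covering `[0, 1]`.
#' @param similarities optional precomputed max-similarity per test compound.
#' @param min_n minimum compounds for a defined per-bin R^2.
#' @param radius,n_bits fingerprint settings.
#' @return data.frame with columns `lower`, `upper`, `n`, `r_squared`.
#' @export
similarity_bin_analysis <- function(predicted, observed, test = NULL,
                                    training = NULL,
                                    breaks = seq(0, 1, by = 0.2),
                                    similarities = NULL, min_n = 3L,
                                    radius = 2L, n_bits = 2048L) {
  stopifnot(length(predicted) == length(observed))
  if (breaks[1L] > 0 || breaks[length(breaks)] < 1)
    stop("breaks must cover [0, 1]")
  if (is.null(similarities)) {
    stopifnot(!is.null(test), !is.null(training))
    as_fp <- function(x) if (inherits(x, "fingerprint")) x
                         else circular_fingerprint(x, radius, n_bits)
    train_fps <- lapply(training, as_fp)
    similarities <- vapply(test, function(m) {
      q <- as_fp(m)
      max(vapply(train_fps, tanimoto, numeric(1), fpB = q))
    }, numeric(1))
  }
  stopifnot(length(similarities) == length(predicted))
  bin <- cut(similarities, breaks, include.lowest = TRUE)
  out <- data.frame(lower = breaks[-length(breaks)], upper = breaks[-1L])
  out$n <- as.integer(table(bin))
  out$r_squared <- vapply(levels(bin), function(lv) {
    ix <- which(bin == lv)
    if (length(ix) < min_n) return(NA_real_)
    if (stats::sd(observed[ix]) == 0 || stats::sd(predicted[ix]) == 0)
      return(NA_real_)
    r_squared(predicted[ix], observed[ix])
  }, numeric(1))
  out
}

#' Chronological train/test split
#'
#' Orders compounds by registration date (stable on ties) and puts the
#' oldest `round(n * train_fraction)` in the training set and the newest
#' remainder in the test set, so the test set always contains the newer
#' compounds.
#'
#' @param x list of objects carrying a `$date` (molecules, labeled examples)
#'   or a vector coercible to `Date`.
#' @param train_fraction fraction of compounds to train on, in (0, 1).
#' @param allow_order_fallback when dates are missing: if `TRUE`, input
#'   order stands in for chronology; if `FALSE` (default) an error is raised.
#' @return list with `train` and `test` (subsets of `x`, or index vectors
#'   when `x` is a date vector), plus attribute `"indices"`.
#' @export
chronological_split <- function(x, train_fraction = 0.8,
                                allow_order_fallback = FALSE) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  if (is.list(x)) {
    dates <- vapply(x, function(e)
      if (is.null(e$date)) NA_real_ else as.numeric(as.Date(e$date)),
      numeric(1))
  } else {
    dates <- as.numeric(as.Date(x))
  }
  n <- length(dates)
  if (anyNA(dates)) {
    if (!allow_order_fallback)
      stop("missing registration dates; set allow_order_fallback = TRUE ",
           "to split by input order")
    dates <- seq_len(n)
  }
  ord <- order(dates, seq_len(n))
  n_train <- round(n * train_fraction)
  if (n_train < 1L || n_train >= n)
    stop("train_fraction leaves an empty train or test set")
  train_ix <- ord[seq_len(n_train)]
  test_ix <- ord[(n_train + 1L):n]
  out <- if (is.list(x)) list(train = x[train_ix], test = x[test_ix])
         else list(train = train_ix, test = test_ix)
  attr(out, "indices") <- list(train = train_ix, test = test_ix)
  out
}
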