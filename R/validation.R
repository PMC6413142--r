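# Model validation: error metrics, LOO and external Q2, rm2,
# points-out splitting and Y-randomization.

#' Average absolute error (vol%)
#' @param y observed values.
#' @param yhat predicted values, same length.
#' @return mean of `|y - yhat|`.
#' @export
aae <- function(y, yhat) {
  if (length(y) == 0L || length(y) != length(yhat)) {
    stop("'y' and 'yhat' must be non-empty vectors of equal length",
         call. = FALSE)
  }
  mean(abs(y - yhat))
}

#' Root-mean-square error (vol%)
#' @inheritParams aae
#' @return square root of the mean squared residual.
#' @export
rmse <- function(y, yhat) {
  if (length(y) == 0L || length(y) != length(yhat)) {
    stop("'y' and 'yhat' must be non-empty vectors of equal length",
         call. = FALSE)
  }
  sqrt(mean((y - yhat)^2))
}

#' Leave-one-out cross-validated Q2
#'
#' `Q2_LOO = 1 - PRESS / SStot`, each prediction coming from the model
#' refitted without that record. The default computes PRESS by the exact
#' hat-matrix shortcut `e_i / (1 - h_i)`; `method = "refit"` runs the
#' explicit n-fold refit loop (identical up to numerical precision, kept as
#' the self-check route).
#'
#' @param matrix a `mixture_matrix`.
#' @param subset descriptor names of the model (default: all columns).
#' @param method `"shortcut"` (hat-matrix PRESS) or `"refit"`.
#' @return Q2 value (at most 1; can be negative).
#' @export
q2_loo <- function(matrix, subset = colnames(matrix$X),
                   method = c("shortcut", "refit")) {
  stopifnot(inherits(matrix, "mixture_matrix"))
  method <- match.arg(method)
  X <- matrix$X[, subset, drop = FALSE]
  y <- matrix$y
  n <- length(y)
  q <- ncol(X)
  if (n <= q + 2L) stop("need n > q + 2 for leave-one-out", call. = FALSE)
  A <- cbind(1, X)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("constant response: Q2 undefined", call. = FALSE)

  if (method == "shortcut") {
    qr_ <- qr(A)
    if (qr_$rank < ncol(A)) {
      stop("singular design in leave-one-out", call. = FALSE)
    }
    res <- y - drop(A %*% qr.coef(qr_, y))
    h <- rowSums(qr.qy(qr_, diag(1, n, qr_$rank))^2)
    if (any(1 - h < 1e-12)) {
      stop("leverage 1 record(s): ",
           paste(which(1 - h < 1e-12), collapse = ", "),
           "; leave-one-out design is singular without them", call. = FALSE)
    }
    press <- sum((res / (1 - h))^2)
  } else {
    press <- 0
    for (i in seq_len(n)) {
      beta <- qr.coef(qr(A[-i, , drop = FALSE]), y[-i])
      if (anyNA(beta)) {
        stop("leave-one-out design singular without record ", i,
             call. = FALSE)
      }
      press <- press + (y[i] - sum(A[i, ] * beta))^2
    }
  }
  1 - press / sst
}

#' Random points-out train/test split
#'
#' Uniform split without replacement into a training set of
#' `round(train_fraction * N)` records and the complementary test set;
#' "points out" means any composition of any pair can land in the test set,
#' so the model is tested on new compositions of known mixtures.
#'
#' @param n number of records, or a data.frame of records.
#' @param train_fraction fraction assigned to training (default 0.8).
#' @param seed integer seed; the same seed always gives the same split.
#' @return list with integer index vectors `train` and `test`.
#' @examples
#' s <- points_out_split(181, seed = 7)
#' lengths(s)   # 145 / 36
#' @export
points_out_split <- function(n, train_fraction = 0.8, seed = 1L) {
  if (is.data.frame(n)) n <- nrow(n)
  n <- as.integer(n)
  if (n < 5L) stop("need at least 5 records to split", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("'train_fraction' must lie in (0, 1)", call. = FALSE)
  }
  n_train <- as.integer(round(train_fraction * n))
  train <- withr::with_seed(as.integer(seed),
                            sort(sample.int(n, n_train)))
  list(train = train, test = setdiff(seq_len(n), train))
}

#' External validation Q2
#'
#' `Q2_ext = 1 - sum (y - yhat)^2 / sum (y - ybar_train)^2` over the test
#' set; the denominator is centred on the TRAINING mean, so a model that
#' merely predicts the training mean scores 0.
#'
#' @param y_test observed test values.
#' @param yhat_test predicted test values.
#' @param ybar_train mean of the training responses.
#' @return Q2 value.
#' @export
q2_ext <- function(y_test, yhat_test, ybar_train) {
  if (length(y_test) == 0L || length(y_test) != length(yhat_test)) {
    stop("'y_test' and 'yhat_test' must be non-empty and equal length",
         call. = FALSE)
  }
  denom <- sum((y_test - ybar_train)^2)
  if (denom == 0) {
    stop("degenerate test set: every observation equals the training mean",
         call. = FALSE)
  }
  1 - sum((y_test - yhat_test)^2) / denom
}

#' Roy rm2 metric
#'
#' `rm2 = r2 * (1 - sqrt(r2 - r0^2))`, where r2 is the squared Pearson
#' correlation of observed vs predicted and r0^2 the corresponding
#' through-origin coefficient of determination (observed regressed on
#' predicted without intercept). Penalises predictions that correlate with
#' the observations but are systematically offset or rescaled. Numerical
#' cases with r0^2 slightly above r2 are clamped at `rm2 = r2` with a
#' warning.
#'
#' @param y observed values (at least 3).
#' @param yhat predicted values.
#' @return rm2 value in `[0, 1]` for positively correlated predictions.
#' @export
rm2 <- function(y, yhat) {
  if (length(y) < 3L || length(y) != length(yhat)) {
    stop("need at least 3 paired values", call. = FALSE)
  }
  r2 <- suppressWarnings(stats::cor(y, yhat))^2
  if (is.na(r2)) stop("undefined correlation (constant input)", call. = FALSE)
  k <- sum(y * yhat) / sum(yhat^2)
  r02 <- 1 - sum((y - k * yhat)^2) / sum((y - mean(y))^2)
  diff <- r2 - r02
  if (diff < 0) {
    if (diff < -1e-8) {
      warning("r0^2 exceeded r^2 (", format(diff), "); clamping at 0")
    }
    diff <- 0
  }
  r2 * (1 - sqrt(diff))
}

#' Y-randomization (response permutation) test
#'
#' Shuffles the response, reruns the model-building procedure and records
#' the training R2 of each randomized model. A real structure-property
#' relationship shows an original R2 many standard deviations above the
#' permuted distribution; the summary distance is
#' `(R2_original - mean(R2_random)) / SD(R2_random)` (a max-based variant
#' against the largest permuted R2 is reported alongside). By default the
#' whole descriptor selection is rerun per shuffle, which also guards
#' against selection bias; passing a fixed `subset` skips reselection and
#' is much cheaper.
#'
#' @param matrix a `mixture_matrix`.
#' @param subset fixed descriptor subset, or `NULL` to rerun GA selection
#'   each shuffle.
#' @param ga a [ga_control()] used when `subset` is `NULL`.
#' @param runs number of permutations (>= 50).
#' @param seed integer seed for the permutations.
#' @return object of class `yrand_report`: list with `runs`, `r2_random`,
#'   `max`, `min`, `mean`, `sd`, `r2_original`, `distance` (mean-based) and
#'   `distance_max`.
#' @export
y_randomization <- function(matrix, subset = NULL, ga = ga_control(),
                            runs = 100L, seed = 1L) {
  stopifnot(inherits(matrix, "mixture_matrix"))
  runs <- as.integer(runs)
  if (runs < 50L) stop("'runs' must be at least 50", call. = FALSE)

  model_r2 <- function(mm) {
    if (is.null(subset)) {
      ga_select(mm, ga)$model$stats$r2
    } else {
      fit_mlr(mm, subset)$stats$r2
    }
  }
  r2_orig <- model_r2(matrix)
  r2_rand <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(runs), function(r) {
      mm <- matrix
      mm$y <- sample(mm$y)
      model_r2(mm)
    }, numeric(1))
  })
  m <- mean(r2_rand); s <- stats::sd(r2_rand)
  structure(list(runs = runs, r2_random = r2_rand,
                 max = max(r2_rand), min = min(r2_rand),
                 mean = m, sd = s, r2_original = r2_orig,
                 distance = (r2_orig - m) / s,
                 distance_max = (r2_orig - max(r2_rand)) / s,
                 seed = as.integer(seed)),
            class = "yrand_report")
}

#' @export
print.yrand_report <- function(x, ...) {
  cat("Y-randomization:", x$runs, "response permutations\n")
  cat(sprintf("  random R2: mean %.3f, sd %.3f, range [%.3f, %.3f]\n",
              x$mean, x$sd, x$min, x$max))
  cat(sprintf("  original R2 %.3f -> distance %.1f SD (max-based %.1f SD)\n",
              x$r2_original, x$distance, x$distance_max))
  invisible(x)
}
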