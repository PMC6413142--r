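# Descriptor pre-filtering, MLR fitting and mean-effect analysis.

#' Remove constant and mutually correlated descriptor columns
#'
#' Two-stage reduction of a descriptor matrix before subset selection:
#' (1) drop columns whose variance after unit scaling is at most
#' `near_constant_tol` (they encode no between-mixture difference);
#' (2) walk the remaining column pairs in order and, whenever
#' `|Pearson r| > corr_cutoff`, drop the member with the lower absolute
#' correlation to the response (ties: keep the lexicographically first
#' name). The result contains no pair above the cutoff.
#'
#' @param matrix a `mixture_matrix`.
#' @param near_constant_tol variance threshold on unit-scaled columns.
#' @param corr_cutoff pairwise absolute-correlation cutoff in (0, 1].
#' @return the `mixture_matrix` with surviving columns; dropped names in
#'   attributes `dropped_constant` and `dropped_correlated`.
#' @export
prefilter <- function(matrix, near_constant_tol = 1e-8, corr_cutoff = 0.90) {
  stopifnot(inherits(matrix, "mixture_matrix"))
  if (corr_cutoff <= 0 || corr_cutoff > 1) {
    stop("'corr_cutoff' must lie in (0, 1]", call. = FALSE)
  }
  X <- matrix$X
  y <- matrix$y
  # unit scaling only for the variance screen; correlations are scale-free
  v <- apply(X, 2, function(col) {
    m <- mean(abs(col))
    stats::var(if (m > 0) col / m else col)
  })
  const <- colnames(X)[v <= near_constant_tol]
  keep <- setdiff(colnames(X), const)

  dropped_corr <- character(0)
  ord <- keep  # fixed processing order = column order after the screen
  alive <- ord
  for (a in seq_along(ord)) {
    ci <- ord[a]
    if (!ci %in% alive) next
    for (b in seq_along(ord)) {
      if (b <= a) next
      cj <- ord[b]
      if (!cj %in% alive) next
      r <- suppressWarnings(stats::cor(X[, ci], X[, cj]))
      if (is.na(r) || abs(r) <= corr_cutoff) next
      ry_i <- abs(suppressWarnings(stats::cor(X[, ci], y)))
      ry_j <- abs(suppressWarnings(stats::cor(X[, cj], y)))
      ry_i[is.na(ry_i)] <- 0; ry_j[is.na(ry_j)] <- 0
      drop <- if (ry_i > ry_j) cj
              else if (ry_j > ry_i) ci
              else sort(c(ci, cj))[2]
      alive <- setdiff(alive, drop)
      dropped_corr <- c(dropped_corr, drop)
      if (drop == ci) break
    }
  }
  if (length(alive) == 0L) {
    stop("prefilter removed every descriptor; relax 'near_constant_tol' ",
         "or 'corr_cutoff'", call. = FALSE)
  }
  matrix$X <- X[, alive, drop = FALSE]
  structure(matrix, dropped_constant = const,
            dropped_correlated = unique(dropped_corr))
}

#' Fit an ordinary least squares QSPR model on a descriptor subset
#'
#' Multiple linear regression with intercept of the response on the named
#' descriptor columns, reporting the training statistics of the QSPR
#' convention: R-squared, the standard error of estimate
#' `s = sqrt(SSres / (n - q - 1))` and the overall F statistic
#' `(R2/q) / ((1 - R2)/(n - q - 1))`. A constant response is handled by
#' convention (all coefficients 0, R2 = 0) rather than as an error.
#'
#' @param matrix a `mixture_matrix`.
#' @param subset character vector of descriptor names to use (default: all
#'   columns).
#' @return an object of class `qspr_lfl`; see [qspr_lfl()] for the methods
#'   available on it.
#' @export
fit_mlr <- function(matrix, subset = colnames(matrix$X)) {
  stopifnot(inherits(matrix, "mixture_matrix"))
  miss <- setdiff(subset, colnames(matrix$X))
  if (length(miss) > 0L) {
    stop("subset names not in the matrix: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  X <- matrix$X[, subset, drop = FALSE]
  y <- matrix$y
  n <- length(y)
  q <- ncol(X)
  if (n <= q + 1L) {
    stop("need n > q + 1 observations to fit ", q, " descriptors",
         call. = FALSE)
  }

  sst <- sum((y - mean(y))^2)
  if (sst == 0) {
    coefs <- stats::setNames(rep(0, q), subset)
    fitted <- rep(mean(y), n)
    fit <- list(intercept = mean(y), coefficients = coefs,
                fitted = fitted, residuals = y - fitted,
                stats = list(r2 = 0, s = 0, F = NA_real_, n = n, q = q))
  } else {
    A <- cbind(`(Intercept)` = 1, X)
    qr_ <- qr(A)
    if (qr_$rank < ncol(A)) {
      bad <- colnames(A)[qr_$pivot[seq.int(qr_$rank + 1L, ncol(A))]]
      stop("singular design; collinear column(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    beta <- qr.coef(qr_, y)
    fitted <- drop(A %*% beta)
    res <- y - fitted
    ssres <- sum(res^2)
    r2 <- 1 - ssres / sst
    s <- sqrt(ssres / (n - q - 1))
    Fstat <- (r2 / q) / ((1 - r2) / (n - q - 1))
    fit <- list(intercept = unname(beta[1]),
                coefficients = beta[-1],
                fitted = fitted, residuals = res,
                stats = list(r2 = r2, s = s, F = Fstat, n = n, q = q))
  }

  structure(c(fit, list(subset = subset, rule = matrix$rule,
                        target = matrix$target, matrix = matrix,
                        call = sys.call())),
            class = "qspr_lfl")
}

#' Mean-effect percentages of the model descriptors
#'
#' Signed relative contribution of each descriptor j:
#' `ME_j = (sum_i D_ij a_j) / (sum_j |sum_i D_ij a_j|) * 100`, so the
#' absolute values always total exactly 100. The sign shows the direction
#' in which the descriptor drives the response; the magnitude ranks
#' descriptor importance.
#'
#' @param model a `qspr_lfl` model.
#' @param matrix a `mixture_matrix` holding the model's descriptors
#'   (default: the training matrix stored in the model).
#' @return named numeric vector of signed percentages.
#' @export
mean_effects <- function(model, matrix = model$matrix) {
  stopifnot(inherits(model, "qspr_lfl"), inherits(matrix, "mixture_matrix"))
  a <- model$coefficients
  miss <- setdiff(names(a), colnames(matrix$X))
  if (length(miss) > 0L) {
    stop("matrix lacks model descriptor(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  contrib <- colSums(matrix$X[, names(a), drop = FALSE]) * a
  denom <- sum(abs(contrib))
  if (denom == 0) {
    stop("degenerate model: every descriptor contribution is zero",
         call. = FALSE)
  }
  100 * contrib / denom
}
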