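# Leverage-based applicability domain and Williams-plot data.

#' Leverages of query rows with respect to a training design
#'
#' `h_i = x_i' (X'X)^-1 x_i` with X the training design matrix including
#' the intercept column. On the training rows themselves the leverages are
#' the hat-matrix diagonal and sum to q + 1.
#'
#' @param X_train numeric matrix of training descriptors (no intercept
#'   column; one is added internally).
#' @param X_query matrix of query descriptors (default: the training rows).
#' @return numeric vector of leverages, one per query row.
#' @export
leverage <- function(X_train, X_query = X_train) {
  X_train <- as.matrix(X_train)
  X_query <- as.matrix(X_query)
  if (ncol(X_query) != ncol(X_train)) {
    stop("query and training designs must share columns", call. = FALSE)
  }
  A <- cbind(`(Intercept)` = 1, X_train)
  qr_ <- qr(A)
  if (qr_$rank < ncol(A)) {
    bad <- colnames(A)[qr_$pivot[seq.int(qr_$rank + 1L, ncol(A))]]
    stop("X'X is singular; collinear descriptor column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  inv <- solve(crossprod(A))
  Q <- cbind(1, X_query)
  rowSums((Q %*% inv) * Q)
}

#' Warning leverage threshold
#'
#' `h* = 3 (q + 1) / n`, with q the number of model descriptors and n the
#' training-set size. Training or query records with leverage above h*
#' extrapolate beyond the descriptor space covered by the training data.
#'
#' @param q number of descriptors in the model (>= 1).
#' @param n training-set size (> q + 1).
#' @return the threshold value.
#' @examples
#' leverage_threshold(6, 145)   # 0.1448... (prints as 0.145)
#' @export
leverage_threshold <- function(q, n) {
  if (q < 1 || n <= q + 1) {
    stop("need q >= 1 and n > q + 1", call. = FALSE)
  }
  3 * (q + 1) / n
}

#' Williams-plot applicability-domain report
#'
#' Computes, for every record, the leverage with respect to the training
#' design and the cross-validated standardized residual: for training
#' records the leave-one-out residual divided by the SD of the training
#' LOO residuals; for test records the external prediction residual
#' divided by that same training SD (`residual_scale = "test"` switches
#' the test denominator to the test residual SD). A record is in-domain
#' when `h <= h*` and `|standardized residual| <= 3`; boundary values
#' count as acceptable. Records beyond 3 SD are flagged as outliers.
#'
#' @param model a `qspr_lfl` model.
#' @param matrix a `mixture_matrix` with the model's descriptors covering
#'   train and test records (default: the model's training matrix).
#' @param split optional list with `train`/`test` index vectors into
#'   `matrix` (see [points_out_split()]); default: everything is training.
#' @param residual_scale SD used for test-record standardization,
#'   `"train"` (default) or `"test"`.
#' @return object of class `ad_report`: data.frame-like list with
#'   `h_star`, and per-record `table` (`mixture_id`, `split`, `leverage`,
#'   `std_residual`, `in_domain`, `outlier`).
#' @export
williams <- function(model, matrix = model$matrix, split = NULL,
                     residual_scale = c("train", "test")) {
  stopifnot(inherits(model, "qspr_lfl"), inherits(matrix, "mixture_matrix"))
  residual_scale <- match.arg(residual_scale)
  subset <- model$subset
  X <- matrix$X[, subset, drop = FALSE]
  y <- matrix$y
  n_all <- nrow(X)
  if (is.null(split)) split <- list(train = seq_len(n_all), test = integer(0))

  Xtr <- X[split$train, , drop = FALSE]
  ytr <- y[split$train]
  # refit on the training rows so the report matches the split
  A <- cbind(1, Xtr)
  qr_ <- qr(A)
  if (qr_$rank < ncol(A)) stop("singular training design", call. = FALSE)
  beta <- qr.coef(qr_, ytr)
  res_tr <- ytr - drop(A %*% beta)
  h_tr <- rowSums(qr.qy(qr_, diag(1, nrow(A), qr_$rank))^2)
  loo_res <- res_tr / (1 - h_tr)
  sd_tr <- stats::sd(loo_res)
  # an interpolating (zero-residual) fit standardizes to zero by convention
  standardize <- function(r, s) if (s < 1e-12) rep(0, length(r)) else r / s

  h_all <- numeric(n_all)
  std <- numeric(n_all)
  h_all[split$train] <- leverage(Xtr, Xtr)
  std[split$train] <- standardize(loo_res, sd_tr)
  if (length(split$test) > 0L) {
    Xte <- X[split$test, , drop = FALSE]
    h_all[split$test] <- leverage(Xtr, Xte)
    res_te <- y[split$test] - drop(cbind(1, Xte) %*% beta)
    scale <- if (residual_scale == "train") sd_tr else stats::sd(res_te)
    std[split$test] <- standardize(res_te, scale)
  }

  h_star <- leverage_threshold(length(subset), length(split$train))
  membership <- rep("train", n_all)
  membership[split$test] <- "test"
  tab <- data.frame(
    mixture_id = matrix$records$mixture_id,
    split = membership,
    leverage = h_all,
    std_residual = std,
    in_domain = h_all <= h_star & abs(std) <= 3,
    outlier = abs(std) > 3,
    stringsAsFactors = FALSE)
  structure(list(h_star = h_star, table = tab,
                 q = length(subset), n_train = length(split$train),
                 residual_scale = residual_scale),
            class = "ad_report")
}

#' @export
print.ad_report <- function(x, ...) {
  cat(sprintf("Applicability domain (Williams): h* = %.3f (q = %d, n = %d)\n",
              x$h_star, x$q, x$n_train))
  cat(sprintf("  %d / %d record(s) in domain; %d leverage warning(s); %d outlier(s)\n",
              sum(x$table$in_domain), nrow(x$table),
              sum(x$table$leverage > x$h_star), sum(x$table$outlier)))
  invisible(x)
}

#' Williams plot
#'
#' Leverage versus cross-validated standardized residual, with the
#' applicability-domain rectangle `h <= h*`, `|residual| <= 3` drawn in.
#'
#' @param x an `ad_report` from [williams()].
#' @param ... passed on to [plot()].
#' @return `x`, invisibly.
#' @export
plot.ad_report <- function(x, ...) {
  tab <- x$table
  plot(tab$leverage, tab$std_residual,
       xlab = "leverage h", ylab = "standardized residual",
       xlim = range(0, tab$leverage, x$h_star * 1.15),
       ylim = range(-3.5, 3.5, tab$std_residual),
       pch = ifelse(tab$split == "train", 1, 17),
       col = ifelse(tab$in_domain, "black", "red"), ...)
  graphics::abline(v = x$h_star, lty = 2)
  graphics::abline(h = c(-3, 3), lty = 3)
  graphics::legend("topright", pch = c(1, 17), bty = "n",
                   legend = c("train", "test"))
  invisible(x)
}
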