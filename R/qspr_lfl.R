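# The user-facing fit: mixture matrix -> (GA) subset -> MLR -> validation.

#' Fit a mixture QSPR model for the lower flammability limit
#'
#' One-call interface to the modelling pipeline: builds mixture descriptors
#' from the records and the pure-component descriptor table with the chosen
#' mixing rule, optionally holds out a points-out test set, selects a
#' descriptor subset by GA-MLR (or fits a user-given subset directly) on
#' the training records, and attaches the standard validation statistics
#' (R2, Q2_LOO, and for split fits Q2_ext, AAE and RMSE per set).
#' Deviation-class rules are automatically modelled against the departure
#' of the LFL from the linear pure-component blend.
#'
#' @param records binary-mixture records (`mixture_id, comp1, comp2, x1,
#'   x2, lfl_exp`).
#' @param descriptors pure-component descriptor table
#'   (default [builtin_components()]).
#' @param rule mixing rule, see [mixing_rules()].
#' @param subset explicit descriptor names to fit; `NULL` runs GA
#'   selection.
#' @param ga a [ga_control()] for the selection run.
#' @param split `NULL` (train on everything), a list with `train`/`test`
#'   indices, or a number in (0, 1) taken as the training fraction of a
#'   seeded [points_out_split()].
#' @param split_seed seed for the split when `split` is a fraction.
#' @param pure_lfl named pure-component LFLs (vol%), required by
#'   deviation-class rules.
#' @param prefilter_cutoff if non-`NULL`, run [prefilter()] with this
#'   pairwise correlation cutoff before selection.
#' @return an object of class `qspr_lfl` with `print`, `summary`, `coef`,
#'   `predict`, `fitted`, `residuals`, `simulate` and `plot` (Williams
#'   applicability-domain plot) methods.
#' @examples
#' d <- generate_dataset(synthetic_pure_lfl(), n = 181, seed = 1)
#' fit <- qspr_lfl(d, builtin_components(),
#'                 subset = model_descriptor_names(), split = 0.8)
#' fit
#' @export
qspr_lfl <- function(records, descriptors = builtin_components(),
                     rule = "norm_cont", subset = NULL, ga = ga_control(),
                     split = NULL, split_seed = 1L, pure_lfl = NULL,
                     prefilter_cutoff = NULL) {
  cl <- match.call()
  mm_all <- build_mixture_matrix(records, descriptors, rule = rule,
                                 pure_lfl = pure_lfl)
  if (is.numeric(split) && length(split) == 1L) {
    split <- points_out_split(nrow(records), train_fraction = split,
                              seed = split_seed)
  }
  if (is.null(split)) {
    split <- list(train = seq_len(nrow(records)), test = integer(0))
  }
  mm_train <- mm_all[split$train]
  if (!is.null(prefilter_cutoff)) {
    mm_train <- prefilter(mm_train, corr_cutoff = prefilter_cutoff)
  }

  trace <- NULL
  if (is.null(subset)) {
    sel <- ga_select(mm_train, ga)
    model <- sel$model
    trace <- sel$trace
  } else {
    model <- fit_mlr(mm_train, subset)
  }

  val <- list(r2 = model$stats$r2,
              q2_loo = q2_loo(mm_train, model$subset),
              aae_train = aae(mm_train$y, model$fitted),
              rmse_train = rmse(mm_train$y, model$fitted))
  if (length(split$test) > 0L) {
    mm_test <- mm_all[split$test]
    yhat <- drop(cbind(1, mm_test$X[, model$subset, drop = FALSE]) %*%
                   c(model$intercept, model$coefficients))
    val$q2_ext <- q2_ext(mm_test$y, yhat, mean(mm_train$y))
    val$aae_test <- aae(mm_test$y, yhat)
    val$rmse_test <- rmse(mm_test$y, yhat)
    val$rm2_test <- rm2(mm_test$y, yhat)
  }

  model$call <- cl
  model$matrix_full <- mm_all
  model$split <- split
  model$trace <- trace
  model$validation <- val
  model$descriptor_table <- descriptors
  model
}

#' @export
print.qspr_lfl <- function(x, digits = 4, ...) {
  cat("Mixture QSPR model for LFL",
      if (isTRUE(x$frozen)) " (frozen published form)", "\n", sep = "")
  if (!is.null(x$call)) cat("Call: ", deparse1(x$call), "\n", sep = "")
  cat("Mixing rule: ", x$rule, "  target: ", x$target, "\n\n", sep = "")
  print(round(c("(Intercept)" = x$intercept, x$coefficients), digits))
  with(x$stats, cat(sprintf(
    "\nR2 = %.3f, s = %.3f vol%%, F = %.3f, n = %d (q = %d)\n",
    r2, s, F, n, q)))
  if (!is.null(x$validation$q2_ext)) {
    cat(sprintf("Q2_LOO = %.3f, Q2_ext = %.3f, AAE test = %.3f vol%%\n",
                x$validation$q2_loo, x$validation$q2_ext,
                x$validation$aae_test))
  } else if (!is.null(x$validation$q2_loo)) {
    cat(sprintf("Q2_LOO = %.3f\n", x$validation$q2_loo))
  }
  invisible(x)
}

#' @export
coef.qspr_lfl <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @export
fitted.qspr_lfl <- function(object, ...) object$fitted

#' @export
residuals.qspr_lfl <- function(object, ...) object$residuals

#' Predict mixture LFL values from a fitted model
#'
#' @param object a `qspr_lfl` model.
#' @param newdata `NULL` (fitted values), a `mixture_matrix`, or a
#'   data.frame of mixture records.
#' @param descriptors descriptor table used when `newdata` is a record
#'   data.frame (default: the table stored in the model, else the built-in
#'   one).
#' @param pure_lfl pure-component LFLs for deviation-target models.
#' @param ... unused.
#' @return numeric predictions in the model's target units (vol%).
#' @export
predict.qspr_lfl <- function(object, newdata = NULL, descriptors = NULL,
                             pure_lfl = NULL, ...) {
  if (is.null(newdata)) {
    if (is.null(object$fitted)) {
      stop("frozen model without data; supply 'newdata'", call. = FALSE)
    }
    return(object$fitted)
  }
  if (!inherits(newdata, "mixture_matrix")) {
    if (is.null(descriptors)) {
      descriptors <- object$descriptor_table
      if (is.null(descriptors)) descriptors <- builtin_components()
    }
    if (is.null(pure_lfl)) {
      pure_lfl <- if (!is.null(object$matrix)) object$matrix$pure_lfl
    }
    newdata <- build_mixture_matrix(newdata, descriptors,
                                    rule = object$rule,
                                    pure_lfl = pure_lfl)
  }
  miss <- setdiff(object$subset, colnames(newdata$X))
  if (length(miss) > 0L) {
    stop("newdata lacks descriptor(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  drop(cbind(1, newdata$X[, object$subset, drop = FALSE]) %*%
         c(object$intercept, object$coefficients))
}

#' @export
summary.qspr_lfl <- function(object, ...) {
  out <- list(call = object$call, rule = object$rule, target = object$target,
              stats = object$stats, validation = object$validation,
              frozen = isTRUE(object$frozen))
  if (!is.null(object$matrix)) {
    X <- object$matrix$X[, object$subset, drop = FALSE]
    A <- cbind(`(Intercept)` = 1, X)
    inv <- solve(crossprod(A))
    se <- sqrt(diag(inv)) * object$stats$s
    est <- c(object$intercept, object$coefficients)
    tval <- est / se
    df <- object$stats$n - object$stats$q - 1
    out$coefficients <- cbind(Estimate = est, `Std. Error` = se,
                              `t value` = tval,
                              `Pr(>|t|)` = 2 * stats::pt(-abs(tval), df))
    out$mean_effects <- mean_effects(object)
  } else {
    out$coefficients <- cbind(Estimate = c("(Intercept)" = object$intercept,
                                           object$coefficients))
  }
  class(out) <- "summary.qspr_lfl"
  out
}

#' @export
print.summary.qspr_lfl <- function(x, digits = 4, ...) {
  cat("Mixture QSPR model (rule ", x$rule, ", target ", x$target, ")\n\n",
      sep = "")
  stats::printCoefmat(x$coefficients, digits = digits)
  with(x$stats, cat(sprintf(
    "\nR2 = %.3f, s = %.3f vol%%, F = %.3f, n = %d (q = %d)\n",
    r2, s, F, n, q)))
  v <- x$validation
  if (!is.null(v)) {
    cat(sprintf("Q2_LOO = %.3f", v$q2_loo))
    if (!is.null(v$q2_ext)) {
      cat(sprintf(", Q2_ext = %.3f, rm2 = %.3f", v$q2_ext, v$rm2_test))
      cat(sprintf("\nAAE train/test = %.3f / %.3f vol%%, RMSE train/test = %.3f / %.3f vol%%",
                  v$aae_train, v$aae_test, v$rmse_train, v$rmse_test))
    }
    cat("\n")
  }
  if (!is.null(x$mean_effects)) {
    cat("\nMean effects (%):\n")
    print(round(x$mean_effects, 1))
  }
  invisible(x)
}

#' @export
plot.qspr_lfl <- function(x, ...) {
  if (is.null(x$matrix_full)) {
    ad <- williams(x)
  } else {
    ad <- williams(x, x$matrix_full, x$split)
  }
  plot(ad, ...)
  invisible(ad)
}

#' @export
simulate.qspr_lfl <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(object$fitted)) {
    stop("frozen model without data cannot simulate", call. = FALSE)
  }
  run <- function() object$fitted +
    stats::rnorm(length(object$fitted), sd = object$stats$s)
  sims <- if (is.null(seed)) {
    replicate(nsim, run())
  } else {
    withr::with_seed(as.integer(seed), replicate(nsim, run()))
  }
  out <- as.data.frame(sims)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
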