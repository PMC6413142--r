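# Mixture descriptor matrix: records x named mixture descriptors plus the
# response (LFL, or its deviation from the linear blend).

#' Build the mixture descriptor matrix for a dataset
#'
#' Applies one mixing rule to every record of a binary-mixture table,
#' producing the design matrix X (one column per descriptor) and the
#' response y. Direct and "other" rules are modelled against the LFL
#' itself; deviation rules are automatically paired with the deviation
#' target `lfl_exp - (x1 lfl1 + x2 lfl2)` and therefore require the
#' pure-component LFLs.
#'
#' @param records mixture records (`mixture_id, comp1, comp2, x1, x2,
#'   lfl_exp`), see [read_mixture_csv()] / [generate_dataset()].
#' @param descriptors pure-component descriptor table with `component_id`
#'   and numeric descriptor columns, e.g. [builtin_components()].
#' @param rule mixing-rule name, see [mixing_rules()].
#' @param pure_lfl named pure-component LFL vector (vol%); required for
#'   deviation rules, and appended as the generating attribute otherwise
#'   ignored.
#' @param extra_columns optional character vector of record columns (e.g.
#'   `"x1"`) to carry into X unchanged.
#' @return an object of class `mixture_matrix`: list with `X` (numeric
#'   matrix, named columns), `y`, `target` (`"lfl"` or `"deviation"`),
#'   `rule`, and the `records` used.
#' @export
build_mixture_matrix <- function(records, descriptors, rule = "norm_cont",
                                 pure_lfl = NULL, extra_columns = NULL) {
  .check_records(records)
  rule <- match.arg(rule, mixing_rules()$rule)
  dnames <- setdiff(names(descriptors), c("component_id", "smiles"))
  if (length(dnames) == 0L) stop("no descriptor columns", call. = FALSE)
  idx <- match(c(records$comp1, records$comp2), descriptors$component_id)
  if (anyNA(idx)) {
    stop("component(s) missing from descriptor table: ",
         paste(unique(c(records$comp1, records$comp2)[is.na(idx)]),
               collapse = ", "), call. = FALSE)
  }
  n <- nrow(records)
  D <- as.matrix(descriptors[, dnames, drop = FALSE])
  d1 <- D[idx[seq_len(n)], , drop = FALSE]
  d2 <- D[idx[n + seq_len(n)], , drop = FALSE]
  x1 <- records$x1

  f <- .RULES[[rule]]
  X <- matrix(NA_real_, n, length(dnames),
              dimnames = list(records$mixture_id, dnames))
  for (r in seq_len(n)) X[r, ] <- f(d1[r, ], d2[r, ], x1[r], 1 - x1[r])

  if (rule_class(rule) == "deviation") {
    if (is.null(pure_lfl)) {
      stop("deviation rules model the departure from the linear blend; ",
           "supply 'pure_lfl'", call. = FALSE)
    }
    miss <- setdiff(unique(c(records$comp1, records$comp2)), names(pure_lfl))
    if (length(miss) > 0L) {
      stop("pure_lfl missing for: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    y <- deviation_target(records$lfl_exp, pure_lfl[records$comp1],
                          pure_lfl[records$comp2], x1)
    target <- "deviation"
  } else {
    y <- records$lfl_exp
    target <- "lfl"
  }
  if (!is.null(extra_columns)) {
    X <- cbind(X, as.matrix(records[, extra_columns, drop = FALSE]))
  }
  structure(list(X = X, y = as.numeric(y), target = target, rule = rule,
                 records = records, pure_lfl = pure_lfl),
            class = "mixture_matrix")
}

#' @export
print.mixture_matrix <- function(x, ...) {
  cat(sprintf("<mixture_matrix> %d records x %d descriptors (rule %s, target %s)\n",
              nrow(x$X), ncol(x$X), x$rule, x$target))
  invisible(x)
}

#' Subset the records of a mixture matrix
#' @param x a `mixture_matrix`.
#' @param i row indices.
#' @param ... unused.
#' @return a `mixture_matrix` restricted to rows `i`.
#' @export
`[.mixture_matrix` <- function(x, i, ...) {
  x$X <- x$X[i, , drop = FALSE]
  x$y <- x$y[i]
  x$records <- x$records[i, , drop = FALSE]
  x
}
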