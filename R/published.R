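# The frozen published six-descriptor LFL model (norm_cont mixing).

.PUBLISHED <- list(
  intercept = 2.720,
  coefficients = c("RBN" = -0.567, "MAXDP" = -4.661, "Psi_i_0" = 0.642,
                   "SpMax4_Bh(e)" = 0.544, "Mor24u" = -2.056,
                   "Mor16m" = -23.689),
  rule = "norm_cont",
  target = "lfl",
  stats = list(r2 = 0.964, s = 0.138, F = 606.440, n = 145, q = 6)
)

#' The published six-descriptor LFL model
#'
#' The reported best binary-hydrocarbon LFL model: norm-of-the-molar-
#' contribution mixing of RBN, MAXDP, Psi_i_0, SpMax4_Bh(e), Mor24u and
#' Mor16m, with frozen intercept 2.720 and coefficients (-0.567, -4.661,
#' +0.642, +0.544, -2.056, -23.689) and training statistics R2 = 0.964,
#' s = 0.138, F = 606.440, n = 145. The model was trained on descriptors
#' from a commercial engine whose geometries differ slightly from this
#' package's embedding, so predictions made with native 3D descriptors
#' carry that documented geometry difference.
#'
#' @return a `qspr_lfl` model object (without training data attached).
#' @examples
#' coef(published_model())
#' @export
published_model <- function() {
  structure(list(intercept = .PUBLISHED$intercept,
                 coefficients = .PUBLISHED$coefficients,
                 subset = names(.PUBLISHED$coefficients),
                 rule = .PUBLISHED$rule, target = .PUBLISHED$target,
                 stats = .PUBLISHED$stats, frozen = TRUE,
                 call = quote(published_model())),
            class = "qspr_lfl")
}

#' Predict a binary-mixture LFL with the published model
#'
#' Applies norm_cont mixing `sqrt((x1 d1)^2 + (x2 d2)^2)` per descriptor to
#' the two pure-component descriptor vectors and evaluates the frozen
#' linear model. Symmetric under the component swap
#' `(d1, x1) <-> (d2, 1 - x1)`.
#'
#' @param d1,d2 named descriptor vectors containing the six model
#'   descriptors (extra names are ignored).
#' @param x1 mole fraction of component 1 (vectorised).
#' @return predicted LFL (vol%).
#' @examples
#' z <- stats::setNames(numeric(6), model_descriptor_names())
#' predict_published(z, z, 0.5)   # the intercept, 2.720
#' @export
predict_published <- function(d1, d2, x1) {
  need <- model_descriptor_names()
  if (!all(need %in% names(d1)) || !all(need %in% names(d2))) {
    stop("both descriptor vectors must contain: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  a <- .PUBLISHED$coefficients
  vapply(x1, function(x) {
    D <- mix_descriptors(d1[need], d2[need], x, rule = "norm_cont")
    .PUBLISHED$intercept + sum(a[need] * D[need])
  }, numeric(1))
}

#' Predict the LFL of a built-in hydrocarbon pair
#'
#' Convenience wrapper: looks the two components up in the pinned
#' descriptor table and calls [predict_published()].
#'
#' @param comp1,comp2 component ids from [builtin_components()].
#' @param x1 mole fraction of `comp1` (vectorised).
#' @param descriptors descriptor table (default: the pinned built-in one).
#' @return predicted LFL (vol%).
#' @export
predict_published_pair <- function(comp1, comp2, x1,
                                   descriptors = builtin_components()) {
  row <- function(id) {
    i <- match(id, descriptors$component_id)
    if (is.na(i)) stop("unknown component '", id, "'", call. = FALSE)
    unlist(descriptors[i, setdiff(names(descriptors),
                                  c("component_id", "smiles"))])
  }
  predict_published(row(comp1), row(comp2), x1)
}
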