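# Twelve mixing rules turning pure-component descriptors into mixture
# descriptors, the deviation modelling target, and Le Chatelier's rule.

.RULES <- list(
  # direct combinations
  fmol_sum     = function(d1, d2, x1, x2) x1 * d1 + x2 * d2,
  norm_cont    = function(d1, d2, x1, x2) sqrt((x1 * d1)^2 + (x2 * d2)^2),
  fmol_diff    = function(d1, d2, x1, x2) abs(x1 * d1 - x2 * d2),
  sqr_fmol     = function(d1, d2, x1, x2) x1^2 * d1 + x2^2 * d2,
  root_fmol    = function(d1, d2, x1, x2) sqrt(x1) * d1 + sqrt(x2) * d2,
  sqr_fmol_sum = function(d1, d2, x1, x2) (x1 * d1 + x2 * d2)^2,
  # deviation combinations (delta_x = |x1-x2|, delta_d = |d1-d2|)
  mol_dev      = function(d1, d2, x1, x2) (1 - abs(x1 - x2)) * abs(d1 - d2),
  sqr_mol_dev  = function(d1, d2, x1, x2) (1 - abs(x1 - x2)^2) * abs(d1 - d2),
  mol_dev_sqr  = function(d1, d2, x1, x2) (1 - abs(x1 - x2))^2 * abs(d1 - d2),
  # other combinations (composition-independent)
  cent         = function(d1, d2, x1, x2) (d1 + d2) / 2,
  sqr_diff     = function(d1, d2, x1, x2) (d1 - d2)^2,
  abs_diff     = function(d1, d2, x1, x2) abs(d1 - d2)
)

.RULE_CLASS <- c(fmol_sum = "direct", norm_cont = "direct",
                 fmol_diff = "direct", sqr_fmol = "direct",
                 root_fmol = "direct", sqr_fmol_sum = "direct",
                 mol_dev = "deviation", sqr_mol_dev = "deviation",
                 mol_dev_sqr = "deviation",
                 cent = "other", sqr_diff = "other", abs_diff = "other")

#' The twelve binary mixing rules
#'
#' Catalogue of the formulas that combine pure-component descriptor values
#' d1, d2 with mole fractions x1, x2 = 1 - x1 into a mixture descriptor D.
#' Six direct combinations depend on composition and are modelled against
#' the LFL itself; three deviation combinations (functions of |x1 - x2| and
#' |d1 - d2|) are modelled against the deviation of the LFL from the linear
#' blend (see [deviation_target()]); three "other" combinations ignore
#' composition entirely.
#'
#' @return data.frame with columns `rule` and `class`
#'   (direct/deviation/other).
#' @examples
#' mixing_rules()
#' @export
mixing_rules <- function() {
  data.frame(rule = names(.RULES), class = unname(.RULE_CLASS),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Class of a mixing rule
#' @param rule rule name, one of `mixing_rules()$rule`.
#' @return `"direct"`, `"deviation"` or `"other"`.
#' @export
rule_class <- function(rule) {
  rule <- match.arg(rule, names(.RULES))
  unname(.RULE_CLASS[rule])
}

#' Combine two descriptor vectors into mixture descriptors
#'
#' Applies one mixing rule elementwise to two named descriptor vectors.
#' All twelve formulas are symmetric under the component swap
#' `(d1, x1) <-> (d2, x2)`.
#'
#' @param d1,d2 named numeric descriptor vectors with identical names.
#' @param x1 mole fraction of component 1 in `[0, 1]`; x2 = 1 - x1.
#' @param rule mixing-rule name, see [mixing_rules()].
#' @return named numeric vector of mixture descriptors with attributes
#'   `rule`, `x1`, `x2`.
#' @examples
#' mix_descriptors(c(D = 2), c(D = 4), x1 = 0.3, rule = "fmol_sum")  # 3.4
#' @export
mix_descriptors <- function(d1, d2, x1, rule = "norm_cont") {
  rule <- match.arg(rule, names(.RULES))
  if (is.null(names(d1)) || is.null(names(d2)) ||
      !identical(sort(names(d1)), sort(names(d2)))) {
    stop("'d1' and 'd2' must be named vectors over the same descriptors",
         call. = FALSE)
  }
  if (!is.numeric(x1) || length(x1) != 1L || x1 < 0 || x1 > 1) {
    stop("'x1' must be a single mole fraction in [0, 1]", call. = FALSE)
  }
  d2 <- d2[names(d1)]
  out <- .RULES[[rule]](as.numeric(d1), as.numeric(d2), x1, 1 - x1)
  names(out) <- names(d1)
  structure(out, rule = rule, x1 = x1, x2 = 1 - x1)
}

#' Deviation of a mixture LFL from the linear blend
#'
#' The modelling target used with the deviation mixing rules: the
#' difference between the experimental mixture LFL and the mole-fraction
#' weighted linear contribution of the two pure-component LFLs,
#' `lfl_mix - (x1 lfl1 + x2 lfl2)`.
#'
#' @param lfl_mix experimental mixture LFL (vol%).
#' @param lfl1,lfl2 pure-component LFLs (vol%), positive.
#' @param x1 mole fraction of component 1.
#' @return deviation in vol% (vectorised).
#' @export
deviation_target <- function(lfl_mix, lfl1, lfl2, x1) {
  if (any(c(lfl1, lfl2, lfl_mix) <= 0)) {
    stop("LFL values must be positive", call. = FALSE)
  }
  lfl_mix - (x1 * lfl1 + (1 - x1) * lfl2)
}

#' Le Chatelier's rule for a binary mixture
#'
#' Classical flammability-limit mixing estimate
#' `1 / (x1 / lfl1 + x2 / lfl2)`; always between the two pure LFLs. Used
#' here as the comparison baseline and as the backbone of the synthetic
#' dataset generator.
#'
#' @param lfl1,lfl2 pure-component LFLs (vol%), positive.
#' @param x1 mole fraction of component 1 in `[0, 1]` (vectorised).
#' @return mixture LFL estimate (vol%).
#' @examples
#' le_chatelier(2, 4, 0.5)   # 2.667
#' @export
le_chatelier <- function(lfl1, lfl2, x1) {
  if (any(lfl1 <= 0) || any(lfl2 <= 0)) {
    stop("pure-component LFL values must be positive", call. = FALSE)
  }
  if (any(x1 < 0 | x1 > 1)) {
    stop("'x1' must lie in [0, 1]", call. = FALSE)
  }
  1 / (x1 / lfl1 + (1 - x1) / lfl2)
}
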