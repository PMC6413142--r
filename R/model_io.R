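# Lossless JSON round-trip for fitted models.

#' Write / read a QSPR model as JSON
#'
#' Serialises the model coefficients, mixing rule, target and training
#' statistics (plus any provenance list attached as `model$provenance`)
#' with full double precision, and restores an equivalent `qspr_lfl`
#' object. Training data are not serialised.
#'
#' @param model a `qspr_lfl` model.
#' @param path file path of the JSON document.
#' @return `write_qspr_model`: `path`, invisibly; `read_qspr_model`: a
#'   `qspr_lfl` model.
#' @export
write_qspr_model <- function(model, path) {
  stopifnot(inherits(model, "qspr_lfl"))
  doc <- list(intercept = model$intercept,
              coefficients = as.list(model$coefficients),
              mixing_rule = model$rule,
              target = model$target,
              stats = model$stats[c("r2", "s", "F", "n", "q")],
              provenance = model$provenance)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_qspr_model
#' @export
read_qspr_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  coefs <- unlist(doc$coefficients)
  structure(list(intercept = doc$intercept,
                 coefficients = coefs,
                 subset = names(coefs),
                 rule = doc$mixing_rule,
                 target = doc$target,
                 stats = as.list(doc$stats),
                 provenance = doc$provenance,
                 frozen = TRUE,
                 call = quote(read_qspr_model())),
            class = "qspr_lfl")
}
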