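# Pure components, synthetic binary-mixture datasets, CSV readers/writers.

.COMPONENTS <- data.frame(
  component_id = c("methane", "ethane", "propane", "butane", "isobutane",
                   "ethylene", "propylene", "butylene", "butadiene",
                   "acetylene"),
  # "butylene" fixed to 1-butene and "butadiene" to 1,3-butadiene; both
  # isomer choices are conventions of this package and can be overridden by
  # supplying a custom SMILES/descriptor table.
  smiles = c("C", "CC", "CCC", "CCCC", "CC(C)C",
             "C=C", "CC=C", "CCC=C", "C=CC=C", "C#C"),
  stringsAsFactors = FALSE
)

#' The ten pure hydrocarbon components of the binary-mixture dataset
#'
#' Methane, ethane, propane, butane, isobutane, ethylene, propylene,
#' butylene (taken as 1-butene), butadiene (taken as 1,3-butadiene) and
#' acetylene, with their six model descriptors. By default the descriptors
#' come from the pinned table shipped with the package (computed once by
#' this package's own SMILES -> embedding -> descriptor pipeline, seed 1);
#' `recompute = TRUE` re-runs that pipeline and gives identical values.
#' Pure-substance LFLs are not part of this table: they are measurement
#' inputs that users supply (see [synthetic_pure_lfl()] for the clearly
#' labelled placeholder set used by the synthetic generator).
#'
#' @param recompute logical; recompute descriptors instead of loading the
#'   pinned table.
#' @param seed embedding seed used when `recompute = TRUE`.
#' @return data.frame with `component_id`, `smiles` and the six descriptor
#'   columns of [model_descriptor_names()].
#' @export
builtin_components <- function(recompute = FALSE, seed = 1L) {
  if (recompute) {
    return(descriptor_table(.COMPONENTS$smiles, .COMPONENTS$component_id,
                            seed = seed))
  }
  path <- system.file("extdata", "pure_descriptors.csv", package = "mixlfl",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, check.names = FALSE)
  tab$component_id <- as.character(tab$component_id)
  tab
}

#' Synthetic placeholder pure-component LFL values
#'
#' A fixed set of plausible-magnitude placeholder LFLs (vol%) for the ten
#' built-in hydrocarbons, chosen once so that Le Chatelier mixtures on the
#' 0.1-0.9 mole-fraction grid span roughly 1.7-4.6 vol%, the magnitude
#' range typical of light-hydrocarbon flammability data. These are
#' synthetic stand-ins for generator examples and tests, not measured
#' values; replace them with experimental data for real work.
#'
#' @return named numeric vector (vol%).
#' @export
synthetic_pure_lfl <- function() {
  c(methane = 4.9, ethane = 3.0, propane = 2.1, butane = 1.85,
    isobutane = 1.8, ethylene = 2.75, propylene = 2.4, butylene = 1.65,
    butadiene = 2.0, acetylene = 2.5)
}

#' Generate a synthetic binary-mixture LFL dataset
#'
#' Emulates the structure of a binary hydrocarbon flammability dataset:
#' every unordered pair of components, on a mole-fraction grid, with
#' `lfl_exp = le_chatelier(lfl1, lfl2, x1) + amplitude * x1 * x2 * sign +
#' Normal(0, noise_sd)`. The pairwise sign (+1 or -1, drawn once per pair
#' from the seed) and the `x1 * x2` shape give each pair a smooth
#' composition-dependent departure from Le Chatelier that vanishes at the
#' pure limits, the nonlinearity that direct mixing rules must capture.
#' The generating parameters are attached to the result as attributes.
#'
#' @param pure_lfl named numeric vector of pure-component LFLs (vol%);
#'   names are component ids.
#' @param grid mole fractions for x1, strictly inside (0, 1).
#' @param deviation_amplitude amplitude of the systematic departure from Le
#'   Chatelier (vol%); default 0.4 puts the maximum departure (at x = 0.5)
#'   at 0.1 vol%, the order of experimental LFL reproducibility.
#' @param noise_sd SD of added Gaussian noise (vol%); default 0.1, the
#'   typical experimental error of LFL determination.
#' @param n optional number of records to keep (uniform subsample without
#'   replacement), e.g. 181 to mirror a laboratory-sized compilation.
#' @param seed integer seed; fixes signs, noise and subsampling.
#' @return data.frame of records `mixture_id, comp1, comp2, x1, x2,
#'   lfl_exp` with attributes `pure_lfl`, `deviation_amplitude`,
#'   `noise_sd`, `pair_sign`, `seed`.
#' @examples
#' d <- generate_dataset(synthetic_pure_lfl(), n = 181, seed = 1)
#' nrow(d)
#' @export
generate_dataset <- function(pure_lfl,
                             grid = seq(0.1, 0.9, by = 0.1),
                             deviation_amplitude = 0.4,
                             noise_sd = 0.1,
                             n = NULL,
                             seed = 1L) {
  if (is.null(names(pure_lfl)) || anyNA(pure_lfl) || any(pure_lfl <= 0)) {
    stop("'pure_lfl' must be a named vector of positive LFLs for every ",
         "component", call. = FALSE)
  }
  if (any(grid <= 0 | grid >= 1)) {
    stop("'grid' fractions must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  ids <- names(pure_lfl)
  if (length(ids) < 2L) stop("need at least two components", call. = FALSE)

  pairs <- utils::combn(ids, 2L)
  withr::with_seed(as.integer(seed), {
    pair_sign <- sample(c(-1, 1), ncol(pairs), replace = TRUE)
    rows <- vector("list", ncol(pairs))
    for (p in seq_len(ncol(pairs))) {
      c1 <- pairs[1, p]; c2 <- pairs[2, p]
      x1 <- grid
      base <- le_chatelier(pure_lfl[[c1]], pure_lfl[[c2]], x1)
      lfl <- base + deviation_amplitude * x1 * (1 - x1) * pair_sign[p] +
        stats::rnorm(length(x1), sd = noise_sd)
      rows[[p]] <- data.frame(comp1 = c1, comp2 = c2, x1 = x1, x2 = 1 - x1,
                              lfl_exp = lfl, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    if (any(out$lfl_exp <= 0)) {
      stop("generated a nonpositive LFL; reduce 'noise_sd' or ",
           "'deviation_amplitude'", call. = FALSE)
    }
    if (!is.null(n)) {
      if (n > nrow(out)) stop("'n' exceeds the grid size", call. = FALSE)
      out <- out[sort(sample.int(nrow(out), n)), , drop = FALSE]
    }
  })
  out <- data.frame(mixture_id = sprintf("mix%03d", seq_len(nrow(out))),
                    out, row.names = NULL, stringsAsFactors = FALSE)
  names(pair_sign) <- paste(pairs[1, ], pairs[2, ], sep = ":")
  structure(out, pure_lfl = pure_lfl,
            deviation_amplitude = deviation_amplitude,
            noise_sd = noise_sd, pair_sign = pair_sign,
            seed = as.integer(seed))
}

.check_records <- function(records, generated = FALSE) {
  need <- c("mixture_id", "comp1", "comp2", "x1", "x2", "lfl_exp")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0L) {
    stop("mixture table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  problems <- character(0)
  bad <- which(abs(records$x1 + records$x2 - 1) > 1e-9)
  if (length(bad) > 0L) {
    problems <- c(problems,
                  paste0("row ", bad, ": x1 + x2 != 1 (",
                         records$x1[bad] + records$x2[bad], ")"))
  }
  bad <- which(!(records$lfl_exp > 0))
  if (length(bad) > 0L) {
    problems <- c(problems, paste0("row ", bad, ": nonpositive lfl_exp"))
  }
  bad <- which(records$comp1 == records$comp2)
  if (length(bad) > 0L) {
    problems <- c(problems, paste0("row ", bad, ": comp1 == comp2"))
  }
  rng <- if (generated) c(0.05, 0.95) else c(0, 1)
  bad <- which(records$x1 < rng[1] | records$x1 > rng[2])
  if (length(bad) > 0L) {
    problems <- c(problems, paste0("row ", bad, ": x1 outside [",
                                   rng[1], ", ", rng[2], "]"))
  }
  if (length(problems) > 0L) {
    stop("invalid mixture record(s):\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  invisible(records)
}

#' Read / write a binary-mixture CSV
#'
#' Fixed dialect: UTF-8, comma separator, `.` decimal point, mandatory
#' header `mixture_id,comp1,comp2,x1,x2,lfl_exp`. Reading validates every
#' record (x1 + x2 = 1 within 1e-9, positive LFL, distinct components) and
#' rejects the file with row-numbered messages otherwise; a write followed
#' by a read restores the values exactly to double precision.
#'
#' @param path file path.
#' @param records data.frame of mixture records.
#' @return `read_mixture_csv`: validated data.frame of records;
#'   `write_mixture_csv`: `path`, invisibly.
#' @export
read_mixture_csv <- function(path) {
  records <- utils::read.csv(path, stringsAsFactors = FALSE,
                             colClasses = c(mixture_id = "character",
                                            comp1 = "character",
                                            comp2 = "character"))
  .check_records(records)
}

#' @rdname read_mixture_csv
#' @export
write_mixture_csv <- function(records, path) {
  .check_records(records)
  out <- records[, c("mixture_id", "comp1", "comp2", "x1", "x2", "lfl_exp")]
  for (col in c("x1", "x2", "lfl_exp")) {
    out[[col]] <- sprintf("%.17g", out[[col]])  # bit-exact round trip
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pure-component descriptor table CSV
#'
#' Header `component_id,<descriptor names...>`; one row per component, all
#' descriptor cells numeric. This is the door through which externally
#' computed descriptor tables (e.g. from a commercial engine) enter the
#' pipeline in place of, or merged over, the native ones.
#'
#' @param path file path.
#' @return data.frame with `component_id` plus numeric descriptor columns.
#' @export
read_descriptor_csv <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"component_id" %in% names(tab)) {
    stop("descriptor CSV lacks a 'component_id' column", call. = FALSE)
  }
  tab$component_id <- as.character(tab$component_id)
  dup <- tab$component_id[duplicated(tab$component_id)]
  if (length(dup) > 0L) {
    stop("duplicate component id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  for (col in setdiff(names(tab), c("component_id", "smiles"))) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) & !is.na(tab[[col]]))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric value in column '%s', row %s", col,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    tab[[col]] <- v
  }
  tab
}

#' Merge native and external descriptor tables
#'
#' Joins two descriptor tables on `component_id`. Where both tables carry a
#' descriptor of the same name, the external value wins and a warning
#' reports the overridden columns.
#'
#' @param native,external descriptor data.frames as returned by
#'   [builtin_components()] / [read_descriptor_csv()].
#' @return merged data.frame covering the native components.
#' @export
merge_descriptors <- function(native, external) {
  shared <- setdiff(intersect(names(native), names(external)),
                    c("component_id", "smiles"))
  if (length(shared) > 0L) {
    warning("external descriptor table overrides native column(s): ",
            paste(shared, collapse = ", "), call. = FALSE)
    native <- native[, setdiff(names(native), shared), drop = FALSE]
  }
  merge(native, external, by = "component_id", all.x = TRUE, sort = FALSE)
}
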