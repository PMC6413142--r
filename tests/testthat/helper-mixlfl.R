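# Shared fixtures: small random descriptor matrices built in code.

# minimal mixture_matrix wrapper around an arbitrary design matrix
make_mm <- function(X, y, rule = "norm_cont", target = "lfl") {
  colnames(X) <- colnames(X) %||% paste0("D", seq_len(ncol(X)))
  structure(list(X = X, y = as.numeric(y), target = target, rule = rule,
                 records = data.frame(
                   mixture_id = sprintf("m%04d", seq_len(nrow(X))),
                   comp1 = "a", comp2 = "b",
                   x1 = 0.5, x2 = 0.5,
                   lfl_exp = abs(y) + 1,
                   stringsAsFactors = FALSE),
                 pure_lfl = NULL),
            class = "mixture_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random design with an optional planted linear signal
rand_mm <- function(n, p, seed, beta = NULL, intercept = 2,
                    noise_sd = 0) {
  withr::with_seed(seed, {
    X <- matrix(runif(n * p, -1, 2), n, p,
                dimnames = list(NULL, paste0("D", seq_len(p))))
    y <- if (is.null(beta)) {
      rnorm(n)
    } else {
      intercept + drop(X[, names(beta), drop = FALSE] %*% beta) +
        rnorm(n, sd = noise_sd)
    }
  })
  make_mm(X, y)
}

# synthetic mixture dataset whose response is exactly linear in the
# norm_cont-mixed values of a known descriptor subset
planted_norm_cont_data <- function(n_desc = 20, n_true = 6, seed = 1,
                                   noise_sd = 0, n_records = 181) {
  withr::with_seed(seed, {
    ids <- sprintf("cmp%02d", 1:10)
    D <- matrix(runif(10 * n_desc, 0.2, 3), 10, n_desc,
                dimnames = list(NULL, sprintf("V%02d", seq_len(n_desc))))
    desc <- data.frame(component_id = ids, D, check.names = FALSE,
                       stringsAsFactors = FALSE)
    truth <- sort(sample(colnames(D), n_true))
    beta <- setNames(runif(n_true, -1, 1), truth)

    pairs <- combn(ids, 2)
    grid <- seq(0.1, 0.9, by = 0.1)
    rec <- expand.grid(p = seq_len(ncol(pairs)), x1 = grid)
    rec <- data.frame(mixture_id = sprintf("mix%03d", seq_len(nrow(rec))),
                      comp1 = pairs[1, rec$p], comp2 = pairs[2, rec$p],
                      x1 = rec$x1, x2 = 1 - rec$x1, lfl_exp = 1,
                      stringsAsFactors = FALSE)
    if (n_records < nrow(rec)) {
      rec <- rec[sort(sample.int(nrow(rec), n_records)), , drop = FALSE]
    }
    mm <- build_mixture_matrix(rec, desc, rule = "norm_cont")
    y <- 2 + drop(mm$X[, truth, drop = FALSE] %*% beta) +
      rnorm(nrow(mm$X), sd = noise_sd)
    mm$y <- y
    mm$records$lfl_exp <- pmax(y, 0.1)
  })
  list(mm = mm, truth = truth, beta = beta, descriptors = desc)
}
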