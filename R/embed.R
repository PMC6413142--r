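# Deterministic distance-geometry embedding with a harmonic force field.

# single-bond covalent radii; bond length = (r_i + r_j) * order factor
.COV_RADII <- c(H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
                Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20, I = 1.39)
.ORDER_FACTOR <- function(order) {
  # 1.52 -> 1.33 -> 1.20 for C-C/C=C/C#C; aromatic between single and double
  ifelse(order >= 3, 0.790, ifelse(order >= 2, 0.877, ifelse(order > 1, 0.915, 1)))
}

.ideal_bond_length <- function(graph) {
  r <- .COV_RADII[graph$atoms$element]
  (r[graph$bonds$i] + r[graph$bonds$j]) * .ORDER_FACTOR(graph$bonds$order)
}

# sp / sp2 / sp3 from the largest bond order at the atom
.hybridization <- function(graph) {
  n <- n_atoms(graph)
  maxo <- numeric(n); ndouble <- integer(n)
  for (b in seq_len(nrow(graph$bonds))) {
    for (a in c(graph$bonds$i[b], graph$bonds$j[b])) {
      maxo[a] <- max(maxo[a], graph$bonds$order[b])
      if (graph$bonds$order[b] == 2) ndouble[a] <- ndouble[a] + 1L
    }
  }
  ifelse(maxo >= 3 | ndouble >= 2, 1L, ifelse(maxo > 1, 2L, 3L))
}

#' Embed deterministic 3D coordinates for a molecular graph
#'
#' Generates heavy-atom 3D coordinates by seeded random initialisation
#' followed by minimisation of a harmonic distance force field: bond-length
#' terms from covalent radii scaled by bond order, 1-3 distance terms
#' encoding ideal sp/sp2/sp3 angles (180/120/109.47 degrees), and a soft
#' repulsion between atoms three or more bonds apart. The same graph and
#' seed always give the same coordinates, which is what makes the 3D-MoRSE
#' descriptors of this package reproducible.
#'
#' @param graph a `molgraph` from [parse_smiles()]; at most 100 heavy atoms.
#' @param seed integer random seed for the initial coordinates.
#' @param iterations maximum number of BFGS iterations for the minimiser.
#' @return the graph with `coords` set to an n x 3 matrix (Angstrom).
#' @examples
#' g <- embed_molecule(parse_smiles("C#C"))
#' dist(g$coords)   # C#C bond close to 1.20 Angstrom
#' @export
embed_molecule <- function(graph, seed = 1L, iterations = 200L) {
  stopifnot(inherits(graph, "molgraph"))
  n <- n_atoms(graph)
  if (n > 100L) stop("embedding supports at most 100 heavy atoms", call. = FALSE)
  if (n == 1L) {
    graph$coords <- matrix(0, 1, 3,
                           dimnames = list(NULL, c("x", "y", "z")))
    return(graph)
  }

  bl <- .ideal_bond_length(graph)
  hyb <- .hybridization(graph)
  topo <- .topo_dist(graph)

  # pair targets: (i, j, d0, weight, type) with type 1 harmonic, 2 repulsive
  pi_ <- graph$bonds$i; pj <- graph$bonds$j
  d0 <- bl; w <- rep(100, length(bl)); ty <- rep(1L, length(bl))

  # 1-3 terms through each centre atom
  adj <- vector("list", n)
  blen <- matrix(NA_real_, n, n)
  for (b in seq_along(bl)) {
    i <- graph$bonds$i[b]; j <- graph$bonds$j[b]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    blen[i, j] <- blen[j, i] <- bl[b]
  }
  angle <- c(pi, 2 * pi / 3, acos(-1 / 3))  # sp, sp2, sp3
  for (c_ in seq_len(n)) {
    nb <- adj[[c_]]
    if (length(nb) < 2L) next
    th <- angle[hyb[c_]]
    cmb <- utils::combn(nb, 2L)
    for (k in seq_len(ncol(cmb))) {
      a <- cmb[1, k]; b <- cmb[2, k]
      la <- blen[c_, a]; lb_ <- blen[c_, b]
      pi_ <- c(pi_, a); pj <- c(pj, b)
      d0 <- c(d0, sqrt(la^2 + lb_^2 - 2 * la * lb_ * cos(th)))
      w <- c(w, 30); ty <- c(ty, 1L)
    }
  }
  # soft repulsion for topologically distant pairs
  far <- which(topo >= 3 & upper.tri(topo), arr.ind = TRUE)
  if (nrow(far) > 0L) {
    pi_ <- c(pi_, far[, 1]); pj <- c(pj, far[, 2])
    d0 <- c(d0, rep(2.9, nrow(far)))
    w <- c(w, rep(5, nrow(far))); ty <- c(ty, rep(2L, nrow(far)))
  }

  energy <- function(x) {
    p <- matrix(x, n, 3)
    dx <- p[pi_, , drop = FALSE] - p[pj, , drop = FALSE]
    d <- sqrt(rowSums(dx^2))
    dev <- ifelse(ty == 1L, d - d0, pmin(d - d0, 0))
    sum(w * dev^2)
  }
  gradient <- function(x) {
    p <- matrix(x, n, 3)
    dx <- p[pi_, , drop = FALSE] - p[pj, , drop = FALSE]
    d <- pmax(sqrt(rowSums(dx^2)), 1e-8)
    dev <- ifelse(ty == 1L, d - d0, pmin(d - d0, 0))
    f <- 2 * w * dev / d
    g <- matrix(0, n, 3)
    for (col in 1:3) {
      g[, col] <- g[, col] +
        tapply(f * dx[, col], factor(pi_, levels = seq_len(n)), sum,
               default = 0) -
        tapply(f * dx[, col], factor(pj, levels = seq_len(n)), sum,
               default = 0)
    }
    as.vector(g)
  }

  fit <- NULL
  for (attempt in 0:4) {
    x0 <- withr::with_seed(as.integer(seed) + attempt,
                           stats::rnorm(3 * n, sd = 1.5))
    cand <- stats::optim(x0, energy, gradient, method = "BFGS",
                         control = list(maxit = as.integer(iterations),
                                        reltol = 1e-12))
    p <- matrix(cand$par, n, 3)
    dd <- sqrt(rowSums((p[graph$bonds$i, , drop = FALSE] -
                          p[graph$bonds$j, , drop = FALSE])^2))
    if (all(dd > 0.9 & dd < 1.9)) { fit <- cand; break }
  }
  if (is.null(fit)) {
    stop("3D embedding did not converge to chemically plausible bond ",
         "lengths; try a different seed", call. = FALSE)
  }
  coords <- matrix(fit$par, n, 3, dimnames = list(NULL, c("x", "y", "z")))
  coords <- sweep(coords, 2, colMeans(coords))  # centre for readability
  graph$coords <- coords
  graph
}
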