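# Molecular descriptors of the six-parameter LFL model.

#' Names of the six model descriptors
#'
#' Column order used throughout the package: RBN, MAXDP, Psi_i_0,
#' SpMax4_Bh(e), Mor24u, Mor16m.
#' @return character vector of length 6.
#' @export
model_descriptor_names <- function() {
  c("RBN", "MAXDP", "Psi_i_0", "SpMax4_Bh(e)", "Mor24u", "Mor16m")
}

#' Number of rotatable bonds (RBN)
#'
#' Counts single, non-ring bonds whose two endpoints are both non-terminal
#' heavy atoms (heavy-atom degree at least 2). The conjugated C-C single
#' bond of 1,3-butadiene counts; every bond of isobutane touches a terminal
#' methyl and does not.
#'
#' @param graph a `molgraph`.
#' @return integer rotatable-bond count.
#' @examples
#' rbn(parse_smiles("CCCC"))     # 1
#' rbn(parse_smiles("CC(C)C"))   # 0
#' @export
rbn <- function(graph) {
  stopifnot(inherits(graph, "molgraph"))
  if (nrow(graph$bonds) == 0L) return(0L)
  deg <- .degree(graph)
  with(graph$bonds,
       sum(order == 1 & !in_ring & deg[i] >= 2L & deg[j] >= 2L))
}

#' Kier-Hall intrinsic states
#'
#' Per-atom intrinsic state I = ((2/L)^2 * delta_v + 1) / delta on the
#' hydrogen-suppressed graph, with delta the heavy-atom degree, delta_v the
#' valence connectivity (valence electrons minus attached hydrogens) and L
#' the principal quantum number of the valence shell. For an isolated heavy
#' atom (methane) delta is replaced by max(delta, 1), the convention of the
#' common open descriptor engines.
#'
#' @param graph a `molgraph`.
#' @return numeric vector, one intrinsic state per heavy atom.
#' @examples
#' intrinsic_states(parse_smiles("CC"))    # 2, 2
#' intrinsic_states(parse_smiles("C=C"))   # 3, 3
#' @export
intrinsic_states <- function(graph) {
  stopifnot(inherits(graph, "molgraph"))
  info <- .element_row(graph$atoms$element)
  zv <- c(H = 1, B = 3, C = 4, N = 5, O = 6, F = 7,
          Si = 4, P = 5, S = 6, Cl = 7, Br = 7, I = 7)
  delta_v <- zv[graph$atoms$element] - graph$atoms$nH
  delta <- pmax(.degree(graph), 1L)
  unname(((2 / info$L)^2 * delta_v + 1) / delta)
}

#' Maximal electrotopological positive variation (MAXDP)
#'
#' Field effect of the E-state formalism: for atom i,
#' `dI_i = sum_j (I_i - I_j) / (d_ij + 1)^2` over all other heavy atoms j,
#' with `d_ij` the topological distance. MAXDP is the largest positive
#' `dI_i`, or 0 when no atom has a positive perturbation (any molecule whose
#' atoms share one intrinsic-state value, e.g. ethane).
#'
#' @param graph a `molgraph`.
#' @return non-negative numeric.
#' @export
maxdp <- function(graph) {
  stopifnot(inherits(graph, "molgraph"))
  n <- n_atoms(graph)
  if (n == 1L) return(0)
  I <- intrinsic_states(graph)
  D <- .topo_dist(graph)
  dI <- vapply(seq_len(n), function(i) {
    j <- setdiff(seq_len(n), i)
    sum((I[i] - I[j]) / (D[i, j] + 1)^2)
  }, numeric(1))
  max(c(dI[dI > 0], 0))
}

#' Intrinsic-state pseudoconnectivity index, type 0 (Psi_i_0)
#'
#' Sum over heavy atoms of the inverse square root of the Kier-Hall
#' intrinsic state, the type-0 (atomic) pseudoconnectivity over I values.
#'
#' @param graph a `molgraph`.
#' @return positive numeric.
#' @examples
#' psi_i_0(parse_smiles("CC"))   # 2 / sqrt(2)
#' @export
psi_i_0 <- function(graph) {
  I <- intrinsic_states(graph)
  if (any(I <= 0)) {
    stop("nonpositive intrinsic state: Psi_i_0 is undefined", call. = FALSE)
  }
  sum(I^(-0.5))
}

#' k-th largest Burden-matrix eigenvalue, electronegativity weighted
#'
#' Builds the Burden matrix B: diagonal entries are atomic Sanderson
#' electronegativities relative to carbon (exactly 1 for hydrocarbons);
#' off-diagonal entries are `0.1 * sqrt(bond order)` for bonded pairs
#' (aromatic order 1.5) and 0.001 otherwise. Returns the k-th largest
#' eigenvalue; molecules with fewer than k heavy atoms return 0, the
#' padding convention that keeps SpMax4 defined for methane through propane.
#'
#' @param graph a `molgraph`.
#' @param k which eigenvalue (1 = largest); `SpMax4_Bh(e)` uses `k = 4`.
#' @param weighting diagonal weighting scheme; only Sanderson
#'   electronegativity (`"e"`) is implemented.
#' @return numeric eigenvalue, 0 when `n_atoms(graph) < k`.
#' @examples
#' spmax_bh(parse_smiles("CC"), k = 1)   # 1.1
#' spmax_bh(parse_smiles("C"), k = 4)    # 0 (padding)
#' @export
spmax_bh <- function(graph, k = 4L, weighting = "e") {
  stopifnot(inherits(graph, "molgraph"))
  weighting <- match.arg(weighting, "e")
  if (!is.numeric(k) || length(k) != 1L || k < 1) {
    stop("'k' must be a positive integer", call. = FALSE)
  }
  n <- n_atoms(graph)
  if (n < k) return(0)
  B <- matrix(0.001, n, n)
  diag(B) <- .element_row(graph$atoms$element)$en_sand / 2.746
  for (b in seq_len(nrow(graph$bonds))) {
    v <- 0.1 * sqrt(graph$bonds$order[b])
    B[graph$bonds$i[b], graph$bonds$j[b]] <- v
    B[graph$bonds$j[b], graph$bonds$i[b]] <- v
  }
  ev <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
  ev[as.integer(k)]
}

#' 3D-MoRSE descriptor
#'
#' `Mor(signal) = sum_{i<j} w_i w_j sin(s r_ij) / (s r_ij)` over heavy-atom
#' pairs, with scattering parameter `s = signal - 1` (1/Angstrom), so Mor24
#' evaluates at s = 23 and Mor16 at s = 15; the s = 0 term is defined as
#' `w_i w_j`. Weights are 1 (unweighted) or atomic mass relative to carbon.
#' Single-heavy-atom molecules have no pairs and return 0.
#'
#' @param graph a `molgraph` with coordinates (see [embed_molecule()]).
#' @param signal integer in 1..32.
#' @param weighting `"u"` (unweighted) or `"m"` (relative atomic mass).
#' @return numeric descriptor value.
#' @export
morse <- function(graph, signal, weighting = c("u", "m")) {
  stopifnot(inherits(graph, "molgraph"))
  weighting <- match.arg(weighting)
  if (!is.numeric(signal) || length(signal) != 1L ||
      signal < 1 || signal > 32) {
    stop("'signal' must be an integer in 1..32", call. = FALSE)
  }
  n <- n_atoms(graph)
  if (n == 1L) return(0)
  if (is.null(graph$coords)) {
    stop("graph has no 3D coordinates; call embed_molecule() first",
         call. = FALSE)
  }
  w <- if (weighting == "u") rep(1, n) else
    .element_row(graph$atoms$element)$mass / 12.011
  s <- as.integer(signal) - 1L
  total <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      r <- sqrt(sum((graph$coords[i, ] - graph$coords[j, ])^2))
      total <- total +
        w[i] * w[j] * (if (s == 0L) 1 else sin(s * r) / (s * r))
    }
  }
  total
}

#' Compute the six model descriptors for one molecule
#'
#' Parses the SMILES, embeds deterministic 3D coordinates and evaluates
#' RBN, MAXDP, Psi_i_0, SpMax4_Bh(e), Mor24u and Mor16m. Fixing the seed
#' fixes the geometry and hence the whole vector.
#'
#' @param smiles a SMILES string.
#' @param seed embedding seed passed to [embed_molecule()].
#' @param iterations force-field iterations for the embedding.
#' @return named numeric vector of the six descriptors.
#' @examples
#' compute_model_descriptors("C")   # methane: RBN, Mor24u, Mor16m all 0
#' @export
compute_model_descriptors <- function(smiles, seed = 1L, iterations = 200L) {
  g <- parse_smiles(smiles)
  g <- embed_molecule(g, seed = seed, iterations = iterations)
  out <- c(rbn(g), maxdp(g), psi_i_0(g), spmax_bh(g, 4L),
           morse(g, 24L, "u"), morse(g, 16L, "m"))
  names(out) <- model_descriptor_names()
  if (!all(is.finite(out))) {
    stop("non-finite descriptor value for '", smiles, "'", call. = FALSE)
  }
  out
}

#' Descriptor table for a set of molecules
#'
#' @param smiles character vector of SMILES strings.
#' @param ids component identifiers (default: the SMILES themselves).
#' @param seed,iterations embedding parameters, see
#'   [compute_model_descriptors()].
#' @return data.frame with `component_id`, `smiles` and one column per
#'   model descriptor.
#' @export
descriptor_table <- function(smiles, ids = smiles, seed = 1L,
                             iterations = 200L) {
  stopifnot(length(ids) == length(smiles), !anyDuplicated(ids))
  vals <- t(vapply(smiles, compute_model_descriptors,
                   numeric(6), seed = seed, iterations = iterations))
  out <- data.frame(component_id = as.character(ids),
                    smiles = as.character(smiles),
                    vals, row.names = NULL, check.names = FALSE)
  colnames(out)[-(1:2)] <- model_descriptor_names()
  out
}
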