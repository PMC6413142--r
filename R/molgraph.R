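# Hydrogen-suppressed molecular graphs parsed from SMILES.

# element -> (principal quantum number L, default valence, Sanderson
# electronegativity, atomic mass).  Carbon is the reference for the
# relative weighting schemes used by the Burden and 3D-MoRSE descriptors.
.ELEMENTS <- data.frame(
  symbol  = c("H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Br", "I"),
  L       = c(1L, 2L, 2L, 2L, 2L, 2L, 3L, 3L, 3L, 3L, 4L, 5L),
  valence = c(1, 3, 4, 3, 2, 1, 4, 3, 2, 1, 1, 1),
  en_sand = c(2.592, 2.275, 2.746, 3.194, 3.654, 4.000,
              2.138, 2.515, 2.957, 3.475, 3.219, 2.778),
  mass    = c(1.008, 10.811, 12.011, 14.007, 15.999, 18.998,
              28.086, 30.974, 32.066, 35.453, 79.904, 126.904),
  stringsAsFactors = FALSE
)

.element_row <- function(symbol) {
  i <- match(symbol, .ELEMENTS$symbol)
  if (anyNA(i)) {
    stop("unknown element symbol(s): ",
         paste(unique(symbol[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  .ELEMENTS[i, , drop = FALSE]
}

new_molgraph <- function(atoms, bonds, coords = NULL) {
  structure(list(atoms = atoms, bonds = bonds, coords = coords),
            class = "molgraph")
}

#' Number of heavy atoms in a molecular graph
#' @param graph a `molgraph` object.
#' @return integer atom count.
#' @export
n_atoms <- function(graph) nrow(graph$atoms)

#' Parse a SMILES string into a hydrogen-suppressed molecular graph
#'
#' Reads a neutral organic-subset SMILES (atoms `B C N O P S F Cl Br I`,
#' lowercase aromatic forms, brackets with explicit hydrogen counts,
#' branches, ring-closure digits and the bond symbols `- = # :`) and builds
#' the heavy-atom graph used by all descriptor calculations. Hydrogens are
#' never explicit atoms: each heavy atom stores its attached-H count,
#' completed to the element's default valence when the SMILES leaves it
#' implicit.
#'
#' @param smiles a single SMILES string.
#' @return a `molgraph`: list with `atoms` (data.frame `element`, `nH`,
#'   `L` the valence-shell principal quantum number, `aromatic`), `bonds`
#'   (data.frame `i`, `j`, `order` with aromatic = 1.5, `in_ring`) and
#'   `coords` (`NULL` until [embed_molecule()] is called).
#' @examples
#' g <- parse_smiles("CCCC")   # n-butane: 4 atoms, 3 single bonds
#' n_atoms(g)
#' @seealso [embed_molecule()], [compute_model_descriptors()]
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    stop("'smiles' must be a single non-empty string", call. = FALSE)
  }
  bad <- function(msg) {
    stop(sprintf("cannot parse SMILES '%s': %s", smiles, msg), call. = FALSE)
  }

  chars <- strsplit(smiles, "")[[1]]
  n <- length(chars)

  element  <- character(0)
  aromatic <- logical(0)
  nH_expl  <- integer(0)   # NA unless bracket atom fixed it
  bond_i <- integer(0); bond_j <- integer(0); bond_o <- numeric(0)

  prev <- NA_integer_          # atom index awaiting the next bond
  stack <- integer(0)          # branch return points
  pending <- NA_real_          # bond order set by an explicit symbol
  rings <- list()              # digit -> list(atom, order)

  add_atom <- function(sym, arom, nH) {
    element  <<- c(element, sym)
    aromatic <<- c(aromatic, arom)
    nH_expl  <<- c(nH_expl, nH)
    idx <- length(element)
    if (!is.na(prev)) {
      o <- pending
      if (is.na(o)) o <- if (arom && aromatic[prev]) 1.5 else 1
      bond_i <<- c(bond_i, prev); bond_j <<- c(bond_j, idx)
      bond_o <<- c(bond_o, o)
    }
    prev <<- idx
    pending <<- NA_real_
    idx
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending <- switch(ch, "-" = 1, "=" = 2, "#" = 3, ":" = 1.5,
                        "/" = 1, "\\" = 1)
      i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev)) bad("branch before any atom")
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) bad("unmatched ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (ch == "%") {
        if (i + 2L > n) bad("truncated %% ring closure")
        key <- paste0(chars[i + 1L], chars[i + 2L])
        i <- i + 3L
      } else {
        key <- ch
        i <- i + 1L
      }
      if (is.na(prev)) bad("ring closure before any atom")
      if (is.null(rings[[key]])) {
        rings[[key]] <- list(atom = prev, order = pending)
      } else {
        op <- rings[[key]]
        o <- if (!is.na(pending)) pending else op$order
        if (is.na(o)) o <- if (aromatic[prev] && aromatic[op$atom]) 1.5 else 1
        bond_i <- c(bond_i, op$atom); bond_j <- c(bond_j, prev)
        bond_o <- c(bond_o, o)
        rings[[key]] <- NULL
      }
      pending <- NA_real_
    } else if (ch == "[") {
      close <- which(chars == "]" & seq_len(n) > i)[1]
      if (is.na(close)) bad("unmatched '['")
      body <- paste(chars[(i + 1L):(close - 1L)], collapse = "")
      if (grepl("[+\\-]", body)) bad("charged species are not supported")
      m <- regmatches(body,
                      regexec("^([A-Z][a-z]?|[cnops])(H([0-9]?))?$", body))[[1]]
      if (length(m) == 0L) bad(sprintf("unsupported bracket atom '[%s]'", body))
      sym <- m[2]
      arom <- sym %in% c("c", "n", "o", "p", "s")
      if (arom) sym <- toupper(sym)
      nH <- if (nzchar(m[3])) { if (nzchar(m[4])) as.integer(m[4]) else 1L
      } else 0L
      add_atom(sym, arom, nH)
      i <- close + 1L
    } else if (grepl("[A-Za-z]", ch)) {
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        add_atom(two, FALSE, NA_integer_)
        i <- i + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        add_atom(ch, FALSE, NA_integer_)
        i <- i + 1L
      } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
        add_atom(toupper(ch), TRUE, NA_integer_)
        i <- i + 1L
      } else {
        bad(sprintf("unexpected character '%s' at position %d", ch, i))
      }
    } else {
      bad(sprintf("unexpected character '%s' at position %d", ch, i))
    }
  }
  if (length(stack) > 0L) bad("unmatched '('")
  if (length(rings) > 0L) bad("unclosed ring bond(s)")
  if (length(element) == 0L) bad("no atoms")

  info <- .element_row(element)
  # implicit H completes the default valence after heavy-atom bonds
  order_sum <- numeric(length(element))
  for (b in seq_along(bond_i)) {
    order_sum[bond_i[b]] <- order_sum[bond_i[b]] + bond_o[b]
    order_sum[bond_j[b]] <- order_sum[bond_j[b]] + bond_o[b]
  }
  nH <- ifelse(is.na(nH_expl),
               pmax(0L, as.integer(round(info$valence - order_sum))),
               nH_expl)

  atoms <- data.frame(element = element, nH = as.integer(nH), L = info$L,
                      aromatic = aromatic, stringsAsFactors = FALSE)
  bonds <- data.frame(i = bond_i, j = bond_j, order = bond_o,
                      in_ring = .ring_bonds(length(element), bond_i, bond_j))
  new_molgraph(atoms, bonds)
}

# a bond is in a ring iff its endpoints stay connected after removing it
.ring_bonds <- function(n_atoms, bi, bj) {
  nb <- length(bi)
  if (nb == 0L) return(logical(0))
  vapply(seq_len(nb), function(k) {
    reach <- logical(n_atoms)
    reach[bi[k]] <- TRUE
    repeat {
      grew <- FALSE
      for (b in seq_len(nb)[-k]) {
        if (reach[bi[b]] != reach[bj[b]]) {
          reach[bi[b]] <- reach[bj[b]] <- TRUE
          grew <- TRUE
        }
      }
      if (!grew) break
    }
    reach[bj[k]]
  }, logical(1))
}

# heavy-atom degree per atom
.degree <- function(graph) {
  d <- integer(n_atoms(graph))
  for (b in seq_len(nrow(graph$bonds))) {
    d[graph$bonds$i[b]] <- d[graph$bonds$i[b]] + 1L
    d[graph$bonds$j[b]] <- d[graph$bonds$j[b]] + 1L
  }
  d
}

# topological (shortest-path) distance matrix, unit bond lengths (BFS)
.topo_dist <- function(graph) {
  n <- n_atoms(graph)
  adj <- vector("list", n)
  for (b in seq_len(nrow(graph$bonds))) {
    i <- graph$bonds$i[b]; j <- graph$bonds$j[b]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    D[s, s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier) > 0L) {
      d <- d + 1
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[D[s, nxt] == Inf]
      D[s, nxt] <- d
      frontier <- nxt
    }
  }
  D
}

#' @export
print.molgraph <- function(x, ...) {
  nb <- nrow(x$bonds)
  cat(sprintf("<molgraph> %d heavy atom(s), %d bond(s)%s\n",
              n_atoms(x), nb,
              if (is.null(x$coords)) "" else ", 3D coordinates present"))
  comp <- table(x$atoms$element)
  cat("  formula (heavy): ",
      paste0(names(comp), ifelse(comp > 1, comp, ""), collapse = ""),
      "; attached H: ", sum(x$atoms$nH), "\n", sep = "")
  invisible(x)
}
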