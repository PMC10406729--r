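#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
NULL

# Conventional (abridged IUPAC) atomic weights for the elements that occur in
# small-molecule natural products. Values in daltons.
.atomic_weights <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Si = 28.085, P = 30.974, S = 32.06,
  Cl = 35.45, K = 39.098, Ca = 40.078, Se = 78.971, Br = 79.904, I = 126.904
)

#' Convert SMILES strings to an explicit-hydrogen SDF text block
#'
#' Thin wrapper around OpenBabel (via ChemmineOB). Hydrogens are made
#' explicit so that downstream fingerprinting operates on the
#' hydrogen-complete molecular graph. Molecules that fail to parse are
#' reported by an error naming the offending SMILES.
#'
#' @param smiles character vector of SMILES strings.
#' @param ids optional identifiers (defaults to `m1`, `m2`, ...).
#' @return character scalar of SDF (V2000) text, one block per molecule, in
#'   input order.
#' @keywords internal
smiles_to_sdf <- function(smiles, ids = NULL) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  ids <- ids %||% paste0("m", seq_along(smiles))
  if (anyDuplicated(ids)) abort("molecule ids must be unique")
  src <- paste(paste(smiles, ids), collapse = "\n")
  txt <- ChemmineOB::convertFormat(
    "SMI", "SDF", source = src,
    options = data.frame(names = "h", args = "", stringsAsFactors = FALSE)
  )
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  # first line of each SDF block is the molecule title
  starts <- c(1L, which(lines == "$$$$") + 1L)
  starts <- starts[starts <= length(lines)]
  got <- trimws(lines[starts])
  missing <- setdiff(ids, got)
  if (length(missing) > 0) {
    bad <- smiles[match(missing, ids)]
    abort(paste0(
      "failed to parse SMILES: ",
      paste(sprintf("'%s' (%s)", bad, missing), collapse = ", ")
    ))
  }
  txt
}

#' Parse SMILES into explicit-hydrogen molecular graphs
#'
#' Each molecule becomes a `mol_graph`: atoms (heavy atoms first, in SMILES
#' order, then hydrogens), bonds with orders as kekulized by OpenBabel, an
#' adjacency list, per-atom hydrogen counts, and ring membership flags
#' (an atom or bond is in a ring iff the bond is not a graph bridge).
#'
#' @param smiles character vector of SMILES.
#' @param ids optional identifiers.
#' @return a list of `mol_graph` objects (named by id); a single `mol_graph`
#'   if `smiles` has length 1.
#' @export
#' @examples
#' g <- parse_smiles("CCO")
#' g$elements
parse_smiles <- function(smiles, ids = NULL) {
  ids <- ids %||% paste0("m", seq_along(smiles))
  txt <- smiles_to_sdf(smiles, ids)
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  ends <- which(lines == "$$$$")
  starts <- c(1L, utils::head(ends, -1) + 1L)
  graphs <- vector("list", length(ends))
  for (i in seq_along(ends)) {
    block <- lines[starts[i]:ends[i]]
    graphs[[i]] <- .sdf_block_to_graph(block, smiles = NA_character_)
  }
  names(graphs) <- trimws(lines[starts])
  graphs <- graphs[ids]
  for (i in seq_along(graphs)) graphs[[i]]$smiles <- smiles[i]
  if (length(graphs) == 1) graphs[[1]] else graphs
}

# Parse one V2000 molfile block (explicit coordinates unused).
.sdf_block_to_graph <- function(block, smiles) {
  counts <- block[4]
  n_atoms <- as.integer(substr(counts, 1, 3))
  n_bonds <- as.integer(substr(counts, 4, 6))
  if (is.na(n_atoms) || n_atoms < 1) abort("malformed SDF block")
  atom_lines <- block[5:(4 + n_atoms)]
  elements <- trimws(substr(atom_lines, 32, 34))
  if (n_bonds > 0) {
    bond_lines <- block[(5 + n_atoms):(4 + n_atoms + n_bonds)]
    from <- as.integer(substr(bond_lines, 1, 3))
    to <- as.integer(substr(bond_lines, 4, 6))
    order <- as.integer(substr(bond_lines, 7, 9))
    # OpenBabel writes kekulized structures; treat any aromatic order-4
    # leftovers as order 1.5 would break integer hashing, so map to 1
    order[order == 4L] <- 1L
  } else {
    from <- to <- order <- integer(0)
  }
  adj <- vector("list", n_atoms)
  adj_order <- vector("list", n_atoms)
  for (k in seq_along(from)) {
    adj[[from[k]]] <- c(adj[[from[k]]], to[k])
    adj_order[[from[k]]] <- c(adj_order[[from[k]]], order[k])
    adj[[to[k]]] <- c(adj[[to[k]]], from[k])
    adj_order[[to[k]]] <- c(adj_order[[to[k]]], order[k])
  }
  is_h <- elements == "H"
  n_h <- vapply(adj, function(nb) sum(is_h[nb]), integer(1))
  ring_bond <- .ring_bonds(n_atoms, from, to)
  ring_atom <- rep(FALSE, n_atoms)
  if (any(ring_bond)) {
    ring_atom[unique(c(from[ring_bond], to[ring_bond]))] <- TRUE
  }
  structure(
    list(
      smiles = smiles, n_atoms = n_atoms,
      elements = elements, is_h = is_h, n_h = n_h,
      bonds = tibble(from = from, to = to, order = order, ring = ring_bond),
      adj = adj, adj_order = adj_order,
      ring_atom = ring_atom
    ),
    class = "mol_graph"
  )
}

# A bond is in a ring iff it is not a bridge of the molecular graph.
.ring_bonds <- function(n_atoms, from, to) {
  if (length(from) == 0) return(logical(0))
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  if (igraph::vcount(g) < n_atoms) {
    g <- igraph::add_vertices(g, n_atoms - igraph::vcount(g))
  }
  br <- igraph::bridges(g)
  res <- rep(TRUE, length(from))
  res[as.integer(br)] <- FALSE
  res
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf(
    "<mol_graph> %s: %d atoms (%d heavy), %d bonds\n",
    x$smiles %||% "?", x$n_atoms, sum(!x$is_h), nrow(x$bonds)
  ))
  invisible(x)
}

# Round half away from zero to `digits` decimals (MW convention; avoids the
# IEEE round-to-even surprises of base round() at .005 boundaries).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Molecular weight from a SMILES string
#'
#' Average (conventional atomic weight) molecular weight of the
#' hydrogen-complete molecule, rounded to two decimal places.
#'
#' @param smiles character vector of SMILES.
#' @return numeric vector of molecular weights in daltons.
#' @export
#' @examples
#' molecular_weight(c("O", "CCO")) # 18.02, 46.07
molecular_weight <- function(smiles) {
  graphs <- parse_smiles(smiles)
  if (inherits(graphs, "mol_graph")) graphs <- list(graphs)
  graphs <- unname(graphs)
  vapply(graphs, function(g) {
    w <- .atomic_weights[g$elements]
    if (anyNA(w)) {
      abort(paste0(
        "unsupported element(s) in '", g$smiles, "': ",
        paste(unique(g$elements[is.na(w)]), collapse = ", ")
      ))
    }
    round_half_up(sum(w), 2)
  }, numeric(1))
}

# Pyranose / furanose ring whose anomeric carbon carries an exocyclic oxygen.
.glycoside_smarts <- c(
  pyranose = "[OX2;!R][CX4]1[OX2][CX4][CX4][CX4][CX4]1",
  furanose = "[OX2;!R][CX4]1[OX2][CX4][CX4][CX4]1"
)

#' Flag glycosides by substructure match
#'
#' A molecule is flagged as a glycoside when it contains a six-membered
#' (pyranose) or five-membered (furanose) saturated ring with one ring
#' oxygen whose adjacent ring carbon (the anomeric centre) bears an
#' exocyclic oxygen — the acetal motif of O-glycosidic sugars. The SMARTS
#' patterns are fixed and shipped with the package; supply labels as data
#' if a different definition is required.
#'
#' @param smiles character vector of SMILES.
#' @return logical vector.
#' @export
#' @examples
#' glycoside_flag(c("C", "COC1OC(CO)C(O)C(O)C1O")) # FALSE, TRUE
glycoside_flag <- function(smiles) {
  txt <- smiles_to_sdf(smiles)
  sdf <- ChemmineR::read.SDFset(strsplit(txt, "\n", fixed = TRUE)[[1]])
  hits <- lapply(.glycoside_smarts, function(p) {
    suppressWarnings(ChemmineR::smartsSearchOB(sdf, p, uniqueMatches = TRUE))
  })
  out <- Reduce(`+`, hits) > 0
  unname(out)
}
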