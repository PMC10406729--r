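#' @importFrom purrr map map_int map_dbl map_lgl
NULL

FP_NBITS <- 6144L

.atomic_numbers <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Na = 11, Mg = 12, Si = 14,
  P = 15, S = 16, Cl = 17, K = 19, Ca = 20, Se = 34, Br = 35, I = 53
)

# Deterministic integer hash chain, exact in double precision:
# state < 2^31, state*1000003 + x < 2^53.
.hash_mix <- function(state, x) (state * 1000003 + x) %% 2147483647

.hash_seq <- function(xs, salt = 17) {
  state <- salt
  for (x in xs) state <- .hash_mix(state, x)
  state
}

#' Construct a fingerprint vector
#'
#' @param bits numeric vector of length 6144; 0/1 for `binary_truth`,
#'   values in \[0,1\] for `probability`.
#' @param kind `"binary_truth"` or `"probability"`.
#' @return a `fingerprint` object (numeric vector with a `kind` attribute).
#' @export
new_fingerprint <- function(bits, kind = c("binary_truth", "probability")) {
  kind <- match.arg(kind)
  bits <- as.numeric(bits)
  if (length(bits) != FP_NBITS) {
    abort(sprintf("fingerprint must have length %d, got %d", FP_NBITS, length(bits)))
  }
  if (kind == "binary_truth" && !all(bits %in% c(0, 1))) {
    abort("binary_truth fingerprint entries must be 0 or 1")
  }
  if (any(bits < 0 | bits > 1)) abort("fingerprint entries must lie in [0, 1]")
  structure(bits, kind = kind, class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf(
    "<fingerprint %s> %d bits, %s = %.4g\n",
    attr(x, "kind"), length(x),
    if (attr(x, "kind") == "binary_truth") "popcount" else "sum",
    sum(unclass(x))
  ))
  invisible(x)
}

#' Enumerate circular atom environments of radius 0--2
#'
#' Environments are centred on every heavy atom of the explicit-hydrogen
#' graph; hydrogens are full graph nodes (they shape every invariant and
#' appear inside environment balls) but are not centres themselves, so
#' each bit traces back to heavy-atom neighbourhoods.
#' The radius-0 identifier hashes the atom invariant (atomic
#' number, heavy degree, hydrogen count, ring membership); each iteration
#' rehashes the centre identifier with the sorted (bond order, neighbour
#' identifier) pairs. An environment is dropped when its atom ball did not
#' grow over the previous radius (the neighbourhood is saturated, so it
#' describes the same substructure).
#'
#' @param mol a `mol_graph` from [parse_smiles()].
#' @param max_radius maximum environment radius (default 2).
#' @return tibble with columns `center`, `radius`, `id` (environment hash),
#'   `bit` (1-based folded index), and list-column `atoms` (indices of all
#'   atoms in the environment ball).
#' @export
morgan_environments <- function(mol, max_radius = 2L) {
  stopifnot(inherits(mol, "mol_graph"))
  n <- mol$n_atoms
  z <- .atomic_numbers[mol$elements]
  z[is.na(z)] <- 0
  heavy_deg <- vapply(
    seq_len(n), function(a) sum(!mol$is_h[mol$adj[[a]]]), integer(1)
  )
  ids <- vapply(seq_len(n), function(a) {
    .hash_seq(c(z[a], heavy_deg[a], mol$n_h[a], as.integer(mol$ring_atom[a])))
  }, numeric(1))
  balls <- as.list(seq_len(n))

  centers <- which(!mol$is_h)
  if (length(centers) == 0) centers <- seq_len(n)
  out_center <- integer(0); out_radius <- integer(0)
  out_id <- numeric(0); out_atoms <- list()
  add <- function(a, r, id, ball) {
    out_center[[length(out_center) + 1]] <<- a
    out_radius[[length(out_radius) + 1]] <<- r
    out_id[[length(out_id) + 1]] <<- id
    out_atoms[[length(out_atoms) + 1]] <<- sort(ball)
  }
  for (a in centers) add(a, 0L, ids[a], balls[[a]])

  for (r in seq_len(max_radius)) {
    new_ids <- ids
    new_balls <- balls
    for (a in seq_len(n)) {
      nb <- mol$adj[[a]]
      if (length(nb) == 0) next
      ord <- mol$adj_order[[a]]
      key <- order(ord, ids[nb])
      new_ids[a] <- .hash_seq(
        c(ids[a], as.numeric(rbind(ord[key], ids[nb][key]))),
        salt = 31
      )
      new_balls[[a]] <- unique(c(balls[[a]], unlist(balls[nb])))
    }
    for (a in centers) {
      if (length(new_balls[[a]]) > length(balls[[a]])) {
        add(a, r, new_ids[a], new_balls[[a]])
      }
    }
    ids <- new_ids
    balls <- new_balls
  }
  tibble(
    center = out_center, radius = out_radius, id = out_id,
    bit = as.integer(out_id %% FP_NBITS) + 1L, atoms = out_atoms
  )
}

#' Morgan-style chemical fingerprint folded to 6144 bits
#'
#' Circular environments of radius 0, 1 and 2 are enumerated on the
#' hydrogen-explicit molecular graph and each distinct environment
#' identifier is hash-folded into one of 6144 buckets; the result is a
#' presence/absence bit vector.
#'
#' @param x a SMILES string or a `mol_graph`.
#' @return a `binary_truth` [new_fingerprint()] of length 6144.
#' @export
#' @examples
#' fp <- morgan_fingerprint("CCO")
#' sum(fp)
morgan_fingerprint <- function(x) {
  mol <- if (inherits(x, "mol_graph")) x else parse_smiles(x)
  env <- morgan_environments(mol)
  bits <- numeric(FP_NBITS)
  bits[unique(env$bit)] <- 1
  new_fingerprint(bits, "binary_truth")
}

#' Map fingerprint bits to the atoms that generated them
#'
#' For every environment that set a bit during fingerprinting, records the
#' atoms inside that environment (centre plus neighbours up to its radius).
#' A bit hit by several environments maps to their union.
#'
#' @param x a SMILES string or `mol_graph`.
#' @return tibble with columns `bit` (1-based index) and list-column
#'   `atoms` (sorted atom indices, hydrogens included).
#' @export
bit_atom_map <- function(x) {
  mol <- if (inherits(x, "mol_graph")) x else parse_smiles(x)
  env <- morgan_environments(mol)
  env |>
    dplyr::group_by(.data$bit) |>
    dplyr::summarise(
      atoms = list(sort(unique(unlist(.data$atoms)))), .groups = "drop"
    )
}

#' Build a class vocabulary
#'
#' @param names ordered character vector of unique class names (K >= 2).
#' @param glycoside_name auxiliary label reported for the glycoside flag.
#' @return a `class_vocab` character vector.
#' @export
class_vocabulary <- function(names, glycoside_name = "glycoside") {
  names <- as.character(names)
  if (length(names) < 2) abort("a class vocabulary needs at least 2 classes")
  if (anyDuplicated(names)) abort("class names must be unique")
  structure(names, glycoside_name = glycoside_name, class = "class_vocab")
}

#' Assemble molecule records with supervised targets
#'
#' Computes, for each structure, the 6144-bit fingerprint, the molecular
#' weight, the glycoside flag (overridable by a `glycoside` column), and
#' resolves the class label against the vocabulary.
#'
#' @param structures data frame with columns `id`, `smiles`, and `class`
#'   (class name or 1-based integer index); optional logical `glycoside`.
#' @param vocabulary a [class_vocabulary()] (or character vector of names).
#' @return tibble with columns `id`, `smiles`, `mw`, `class_label`
#'   (integer), `class_name`, `glycoside`, and list-column `fingerprint`.
#' @export
build_records <- function(structures, vocabulary) {
  structures <- as_tibble(structures)
  if (!all(c("id", "smiles", "class") %in% names(structures))) {
    abort("`structures` needs columns id, smiles, class")
  }
  if (anyDuplicated(structures$id)) {
    abort(paste0(
      "duplicate ids: ",
      paste(unique(structures$id[duplicated(structures$id)]), collapse = ", ")
    ))
  }
  vocab <- if (inherits(vocabulary, "class_vocab")) vocabulary
           else class_vocabulary(vocabulary)
  if (is.numeric(structures$class)) {
    label <- as.integer(structures$class)
  } else {
    label <- match(as.character(structures$class), vocab)
  }
  if (anyNA(label) || any(label < 1) || any(label > length(vocab))) {
    abort("class labels outside the vocabulary")
  }
  graphs <- parse_smiles(structures$smiles, ids = as.character(structures$id))
  if (inherits(graphs, "mol_graph")) graphs <- list(graphs)
  fps <- map(graphs, morgan_fingerprint)
  mws <- map_dbl(graphs, function(g) {
    round_half_up(sum(.atomic_weights[g$elements]), 2)
  })
  gly <- if ("glycoside" %in% names(structures)) {
    as.logical(structures$glycoside)
  } else {
    glycoside_flag(structures$smiles)
  }
  tibble(
    id = as.character(structures$id),
    smiles = structures$smiles,
    mw = mws,
    class_label = label,
    class_name = as.character(vocab)[label],
    glycoside = gly,
    fingerprint = unname(fps)
  )
}

#' @rdname build_records
#' @param id,smiles,class_label single-molecule fields.
#' @export
build_record <- function(id, smiles, class_label, vocabulary) {
  build_records(
    tibble(id = id, smiles = smiles, class = class_label), vocabulary
  )
}
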