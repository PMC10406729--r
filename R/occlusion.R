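#' Occlusion sensitivity of fingerprint predictions to individual peaks
#'
#' Each peak is removed from the list in turn, the reduced spectrum is
#' re-rasterized and re-predicted, and the change in the predicted
#' fingerprint probabilities (occluded minus full) is recorded. Any model
#' with a `predict(model, hsqc_image)` method returning a `fingerprint`,
#' `mw` and `glycoside_prob` can be probed (this is how the attribution
#' tests use a hand-built linear surrogate). Molecular-weight and
#' glycoside changes are reported alongside but only the fingerprint head
#' is attributed to atoms.
#'
#' @param model a trained `hsqc_model` (or any object with a compatible
#'   `predict` method).
#' @param pl a non-empty `peak_list`.
#' @param bounds a [spectrum_bounds()]; defaults to the model's stored
#'   bounds when available.
#' @param ... passed to [rasterize()].
#' @return an `occlusion_map`: list with `deltas` (peaks x 6144 matrix of
#'   signed probability changes) and `extras` tibble (`peak`, `mw_delta`,
#'   `glycoside_delta`).
#' @export
occlusion_deltas <- function(model, pl, bounds = NULL, ...) {
  if (nrow(pl) == 0) abort("cannot occlude an empty peak list")
  bounds <- bounds %||% model$bounds %||% spectrum_bounds()
  full <- stats::predict(model, rasterize(pl, bounds, ...))
  n <- nrow(pl)
  deltas <- matrix(0, n, length(full$fingerprint))
  mwd <- glyd <- numeric(n)
  for (i in seq_len(n)) {
    occ <- stats::predict(model, rasterize(remove_peak(pl, i), bounds, ...))
    deltas[i, ] <- as.numeric(occ$fingerprint) - as.numeric(full$fingerprint)
    mwd[i] <- occ$mw - full$mw
    glyd[i] <- occ$glycoside_prob - full$glycoside_prob
  }
  structure(
    list(
      deltas = deltas,
      extras = tibble(peak = seq_len(n), mw_delta = mwd, glycoside_delta = glyd)
    ),
    class = "occlusion_map"
  )
}

#' @export
print.occlusion_map <- function(x, ...) {
  cat(sprintf(
    "<occlusion_map> %d peaks x %d bits; max |delta| %.4g\n",
    nrow(x$deltas), ncol(x$deltas), max(abs(x$deltas))
  ))
  invisible(x)
}

#' Map occlusion deltas onto atoms of a candidate structure
#'
#' Each fingerprint bit's delta magnitude is shared equally among the
#' atoms of the environment(s) that set the bit ([bit_atom_map()]):
#' `score(peak, atom) = sum over bits b containing the atom of
#' |delta[peak, b]| / n_atoms(b)`. The per-peak total therefore equals the
#' total absolute delta over atom-mapped bits (conservation). Set
#' `signed = TRUE` to aggregate raw deltas instead of magnitudes.
#'
#' @param om an `occlusion_map`.
#' @param bam a [bit_atom_map()] tibble for the candidate structure.
#' @param n_atoms number of atoms (columns); inferred from `bam` when
#'   missing.
#' @param signed aggregate signed deltas instead of absolute values?
#' @return an `atom_attribution` matrix (peaks x atoms).
#' @export
atom_attribution <- function(om, bam, n_atoms = NULL, signed = FALSE) {
  stopifnot(inherits(om, "occlusion_map"))
  n_atoms <- n_atoms %||% max(unlist(bam$atoms))
  n_peaks <- nrow(om$deltas)
  scores <- matrix(0, n_peaks, n_atoms)
  d <- if (signed) om$deltas else abs(om$deltas)
  for (j in seq_len(nrow(bam))) {
    b <- bam$bit[j]
    atoms <- bam$atoms[[j]]
    share <- d[, b] / length(atoms)
    scores[, atoms] <- scores[, atoms] + share
  }
  structure(scores, class = c("atom_attribution", "matrix", "array"))
}

#' @rdname atom_attribution
#' @param x an `atom_attribution`.
#' @param ... unused.
#' @export
tidy.atom_attribution <- function(x, ...) {
  m <- unclass(x)
  tibble(
    peak = rep(seq_len(nrow(m)), times = ncol(m)),
    atom = rep(seq_len(ncol(m)), each = nrow(m)),
    score = as.vector(m)
  )
}
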