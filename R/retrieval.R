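# cosine without zero-vector checks (internal hot path)
.cosine_raw <- function(a, b) {
  sum(a * b) / sqrt(sum(a * a) * sum(b * b))
}

#' Cosine similarity between fingerprint vectors
#'
#' @param a,b numeric vectors of equal length (binary or probability
#'   fingerprints). A zero vector has no direction, so it is an error.
#' @return similarity in \[0, 1\] for non-negative inputs.
#' @export
#' @examples
#' fp_cosine(c(1, 1, 0, 0), c(1, 0, 1, 0)) # 0.5
fp_cosine <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) abort("fingerprint lengths differ")
  na <- sum(a * a); nb <- sum(b * b)
  if (na == 0 || nb == 0) abort("cosine of a zero vector is undefined")
  sum(a * b) / sqrt(na * nb)
}

#' Build a searchable reference database
#'
#' Computes a [build_records()] table for the structures and caches the
#' binary fingerprints as a dense matrix for batch cosine scoring.
#'
#' @param structures data frame with `id`, `smiles`, `class` (and optional
#'   `glycoside`) columns.
#' @param vocabulary a [class_vocabulary()].
#' @return a `reference_db`.
#' @export
build_reference_db <- function(structures, vocabulary) {
  records <- build_records(structures, vocabulary)
  fp <- do.call(rbind, lapply(records$fingerprint, unclass))
  rownames(fp) <- records$id
  structure(
    list(
      records = records, fp = fp, fp_norm = sqrt(rowSums(fp * fp)),
      vocabulary = if (inherits(vocabulary, "class_vocab")) vocabulary
                   else class_vocabulary(vocabulary)
    ),
    class = "reference_db"
  )
}

#' @rdname build_reference_db
#' @param records a precomputed [build_records()] tibble (used by the
#'   dataset helpers to avoid recomputing fingerprints).
#' @export
reference_db_from_records <- function(records, vocabulary) {
  if (anyDuplicated(records$id)) abort("duplicate record ids")
  fp <- do.call(rbind, lapply(records$fingerprint, unclass))
  rownames(fp) <- records$id
  structure(
    list(
      records = records, fp = fp, fp_norm = sqrt(rowSums(fp * fp)),
      vocabulary = if (inherits(vocabulary, "class_vocab")) vocabulary
                   else class_vocabulary(vocabulary)
    ),
    class = "reference_db"
  )
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf(
    "<reference_db> %d records, %d classes, %d-bit fingerprints\n",
    nrow(x$records), length(x$vocabulary), ncol(x$fp)
  ))
  invisible(x)
}

#' Save / load a reference database archive
#' @param db a `reference_db`.
#' @param path file path (`.rds`).
#' @export
write_reference_db <- function(db, path) {
  saveRDS(db, path)
  invisible(path)
}

#' @rdname write_reference_db
#' @export
read_reference_db <- function(path) {
  db <- readRDS(path)
  stopifnot(inherits(db, "reference_db"))
  db
}

#' Rank reference structures against a prediction
#'
#' Predicted fingerprint probabilities are scored directly against the
#' binary database fingerprints by cosine similarity (no binarization, so
#' ranking information in the probabilities is preserved; set
#' `binarize = TRUE` to threshold at 0.5 first). Optional pre-filters use
#' the other predicted properties: `mw_window` excludes records whose
#' molecular weight differs from the predicted one by more than that
#' percentage, and `class_filter` keeps only records of the predicted
#' (argmax) class. Survivors are sorted by cosine (descending), ties by
#' molecular-weight difference then id, making the ranking total and
#' reproducible.
#'
#' @param pred an `hsqc_prediction` (or a plain fingerprint vector, in
#'   which case the filters are unavailable).
#' @param db a `reference_db`.
#' @param k number of hits to return (all survivors if fewer).
#' @param mw_window optional molecular-weight window in percent.
#' @param class_filter restrict to the predicted class?
#' @param binarize threshold the predicted fingerprint at 0.5 first?
#' @return tibble of ranked hits: `rank`, `record_id`, `cosine`,
#'   `mw_delta`, `class_match`. Empty (zero-row) if every record is
#'   filtered out.
#' @export
search_db <- function(pred, db, k = 10, mw_window = NULL,
                      class_filter = FALSE, binarize = FALSE) {
  stopifnot(inherits(db, "reference_db"))
  if (nrow(db$records) == 0) abort("reference database is empty")
  if (k < 1) abort("k must be >= 1")
  if (inherits(pred, "hsqc_prediction") || (is.list(pred) && !is.null(pred$fingerprint))) {
    q <- as.numeric(pred$fingerprint)
    pred_mw <- pred$mw
    pred_class <- if (!is.null(pred$class_probs)) {
      which.max(pred$class_probs)
    } else NA_integer_
  } else {
    q <- as.numeric(pred)
    pred_mw <- NA_real_
    pred_class <- NA_integer_
  }
  if (binarize) q <- as.numeric(q >= 0.5)
  if (length(q) != ncol(db$fp)) abort("fingerprint length mismatch with database")
  qn <- sqrt(sum(q * q))
  if (qn == 0) abort("query fingerprint is a zero vector")

  keep <- rep(TRUE, nrow(db$records))
  if (!is.null(mw_window)) {
    if (is.na(pred_mw)) abort("mw_window filter requires a predicted MW")
    keep <- keep & (abs(db$records$mw - pred_mw) / pred_mw <= mw_window / 100)
  }
  if (isTRUE(class_filter)) {
    if (is.na(pred_class)) abort("class_filter requires predicted class probabilities")
    keep <- keep & (db$records$class_label == pred_class)
  }
  idx <- which(keep)
  if (length(idx) == 0) {
    return(tibble(
      rank = integer(0), record_id = character(0), cosine = numeric(0),
      mw_delta = numeric(0), class_match = logical(0)
    ))
  }
  cs <- as.vector(db$fp[idx, , drop = FALSE] %*% q) / (db$fp_norm[idx] * qn)
  mwd <- if (is.na(pred_mw)) rep(NA_real_, length(idx))
         else abs(db$records$mw[idx] - pred_mw)
  ids <- db$records$id[idx]
  # round the sort key so records whose cosines are equal in exact
  # arithmetic (identical folded fingerprints) actually tie and fall
  # through to the mw/id tie-breaks, instead of being ordered by
  # floating-point summation noise
  ord <- order(-round(cs, 12), if (all(is.na(mwd))) seq_along(idx) else mwd, ids)
  top <- utils::head(ord, min(k, length(ord)))
  tibble(
    rank = seq_along(top),
    record_id = ids[top],
    cosine = unname(cs[top]),
    mw_delta = unname(mwd[top]),
    class_match = if (is.na(pred_class)) rep(NA, length(top))
                  else db$records$class_label[idx][top] == pred_class
  )
}

# Maximum-cardinality bipartite matching (Kuhn's augmenting paths).
# adj: list over query peaks of compatible reference-peak indices.
.max_bipartite_matching <- function(adj, n_ref) {
  match_ref <- rep(0L, n_ref)
  try_augment <- function(u, visited) {
    for (v in adj[[u]]) {
      if (!visited[v]) {
        visited[v] <- TRUE
        if (match_ref[v] == 0L) {
          match_ref[v] <<- u
          return(list(ok = TRUE, visited = visited))
        }
        res <- try_augment(match_ref[v], visited)
        visited <- res$visited
        if (res$ok) {
          match_ref[v] <<- u
          return(list(ok = TRUE, visited = visited))
        }
      }
    }
    list(ok = FALSE, visited = visited)
  }
  matched <- 0L
  for (u in seq_along(adj)) {
    if (length(adj[[u]]) == 0) next
    res <- try_augment(u, rep(FALSE, n_ref))
    if (res$ok) matched <- matched + 1L
  }
  matched
}

#' Chemical-shift baseline matcher
#'
#' The non-learning baseline: query peaks are paired one-to-one with
#' reference peaks whenever both shift differences fall within tolerance
#' (0.5 ppm for 13C, 0.05 ppm for 1H; boundaries inclusive). The pairing
#' is an exact maximum-cardinality bipartite matching, and the score is
#' the Dice-style fraction `2 * matched / (n_query + n_ref)`. References
#' are ranked by score (descending), ties broken by id.
#'
#' @param query a `peak_list` (non-empty).
#' @param refs a named list of `peak_list`s, or a data frame with `id` and
#'   a `peaks` list-column.
#' @param k number of entries to return.
#' @param c_tol,h_tol shift tolerances in ppm.
#' @return tibble: `rank`, `record_id`, `score`, `n_matched`, `n_ref`.
#' @export
baseline_shift_match <- function(query, refs, k = 10,
                                 c_tol = 0.5, h_tol = 0.05) {
  if (nrow(query) == 0) abort("query peak list is empty")
  if (is.data.frame(refs)) {
    ref_ids <- as.character(refs$id)
    ref_pls <- refs$peaks
  } else {
    ref_ids <- names(refs) %||% as.character(seq_along(refs))
    ref_pls <- refs
  }
  nq <- nrow(query)
  scores <- numeric(length(ref_pls))
  matched <- integer(length(ref_pls))
  nr_all <- integer(length(ref_pls))
  for (r in seq_along(ref_pls)) {
    ref <- ref_pls[[r]]
    nr <- nrow(ref)
    nr_all[r] <- nr
    if (nr == 0) next
    adj <- lapply(seq_len(nq), function(i) {
      which(abs(ref$c_shift - query$c_shift[i]) <= c_tol &
              abs(ref$h_shift - query$h_shift[i]) <= h_tol)
    })
    m <- .max_bipartite_matching(adj, nr)
    matched[r] <- m
    scores[r] <- 2 * m / (nq + nr)
  }
  ord <- order(-scores, ref_ids)
  top <- utils::head(ord, min(k, length(ord)))
  tibble(
    rank = seq_along(top), record_id = ref_ids[top],
    score = scores[top], n_matched = matched[top], n_ref = nr_all[top]
  )
}
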