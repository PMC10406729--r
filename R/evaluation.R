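#' Classify a retrieved structure against the ground truth
#'
#' Compares binary fingerprints by cosine: `"identical"` when the cosine
#' reaches 1 (within 1e-9, absorbing floating error; note that distinct
#' molecules can collide to the same folded fingerprint and then count as
#' identified — the definition is fingerprint-level), `"similar"` when the
#' cosine is at least the annotation threshold (0.8, inclusive), else
#' `"neither"`.
#'
#' @param truth_fp,hit_fp binary fingerprint vectors.
#' @param similar_threshold annotation threshold (default 0.8).
#' @return one of `"identical"`, `"similar"`, `"neither"`.
#' @export
hit_status <- function(truth_fp, hit_fp, similar_threshold = 0.8) {
  cs <- fp_cosine(truth_fp, hit_fp)
  .status_from_cosine(cs, similar_threshold)
}

.status_from_cosine <- function(cs, similar_threshold = 0.8) {
  dplyr::case_when(
    cs >= 1 - 1e-9 ~ "identical",
    cs >= similar_threshold ~ "similar",
    TRUE ~ "neither"
  )
}

.check_cases <- function(cases) {
  if (!is.data.frame(cases) || nrow(cases) == 0) {
    abort("`cases` must be a non-empty data frame with a `hits` list-column")
  }
  if (!"hits" %in% names(cases)) abort("`cases` needs a `hits` list-column")
  invisible(cases)
}

#' Identification / annotation rate at k
#'
#' Fraction of query cases having at least one hit of the required status
#' among ranks 1..k. `"identical"` requires an exact fingerprint match
#' (identification); `"similar"` accepts identical or similar hits
#' (annotation) — identical implies similar.
#'
#' @param cases tibble with a `hits` list-column; each element is a
#'   rank-ordered tibble with a `status` column (from [hit_status()]).
#' @param k rank cutoff (>= 1).
#' @param status_required `"identical"` or `"similar"`.
#' @return fraction in \[0, 1\].
#' @export
rate_at_k <- function(cases, k, status_required = c("identical", "similar")) {
  .check_cases(cases)
  status_required <- match.arg(status_required)
  if (k < 1) abort("k must be >= 1")
  ok <- map_lgl(cases$hits, function(h) {
    s <- utils::head(h$status, k)
    if (status_required == "identical") any(s == "identical")
    else any(s %in% c("identical", "similar"))
  })
  mean(ok)
}

#' Precision at k
#'
#' Number of hits with status identical-or-similar among ranks 1..k,
#' divided by k (the denominator stays k even when the database holds
#' fewer relevant structures); macro-averaged over cases.
#'
#' @inheritParams rate_at_k
#' @return fraction in \[0, 1\].
#' @export
precision_at_k <- function(cases, k) {
  .check_cases(cases)
  if (k < 1) abort("k must be >= 1")
  mean(map_dbl(cases$hits, function(h) {
    sum(utils::head(h$status, k) %in% c("identical", "similar")) / k
  }))
}

#' Recall at k
#'
#' Correctly annotated structures in the top k divided by the number of
#' similar structures in the whole database (`n_relevant`, computed by
#' exhaustively scoring the truth fingerprint against every record). When
#' a case has no relevant structure at all and retrieves none, its recall
#' is 1 by convention. Macro-averaged over cases.
#'
#' @param cases tibble with `hits` list-column and integer column
#'   `n_relevant`.
#' @param k rank cutoff.
#' @return fraction in \[0, 1\].
#' @export
recall_at_k <- function(cases, k) {
  .check_cases(cases)
  if (!"n_relevant" %in% names(cases)) {
    abort("`cases` needs an `n_relevant` column for recall")
  }
  if (k < 1) abort("k must be >= 1")
  mean(purrr::map2_dbl(cases$hits, cases$n_relevant, function(h, nrel) {
    got <- sum(utils::head(h$status, k) %in% c("identical", "similar"))
    if (got > nrel) {
      abort("internal inconsistency: retrieved more relevant hits than exist")
    }
    if (nrel == 0) return(1)
    got / nrel
  }))
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2pr / (p + r)`; 0 when both are 0.
#'
#' @param precision,recall values in \[0, 1\] (vectorized).
#' @return F1 in \[0, 1\].
#' @export
f1_at_k <- function(precision, recall) {
  stopifnot(all(precision >= 0 & precision <= 1), all(recall >= 0 & recall <= 1))
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Build evaluation cases from predictions and a reference database
#'
#' For each query, ranks the whole database against the predicted
#' fingerprint with [search_db()], then labels every hit by comparing the
#' query's true binary fingerprint with the hit's database fingerprint
#' ([hit_status()]). `n_relevant` counts database records similar (or
#' identical) to the truth, scored exhaustively. Optionally the query's
#' own database entry (matched by id) is excluded from both the hit list
#' and the relevant count.
#'
#' @param predictions list of `hsqc_prediction`s.
#' @param truths [build_records()] tibble aligned with `predictions`
#'   (columns `id`, `fingerprint`).
#' @param db a `reference_db`.
#' @param exclude_self drop the query's own db record (by id)?
#' @param ... passed to [search_db()] (filters, binarize).
#' @return cases tibble: `query_id`, `n_relevant`, `hits` list-column
#'   (rank-ordered tibble with `record_id`, `cosine`, `status`).
#' @export
build_eval_cases <- function(predictions, truths, db,
                             exclude_self = FALSE, ...) {
  stopifnot(length(predictions) == nrow(truths))
  n_db <- nrow(db$records)
  out <- vector("list", length(predictions))
  for (i in seq_along(predictions)) {
    truth_fp <- as.numeric(truths$fingerprint[[i]])
    hits <- search_db(predictions[[i]], db, k = n_db, ...)
    tn <- sqrt(sum(truth_fp^2))
    truth_cos <- as.vector(db$fp %*% truth_fp) / (db$fp_norm * tn)
    names(truth_cos) <- db$records$id
    if (exclude_self) {
      hits <- hits[hits$record_id != truths$id[i], , drop = FALSE]
      hits$rank <- seq_len(nrow(hits))
      truth_cos <- truth_cos[names(truth_cos) != truths$id[i]]
    }
    status_all <- stats::setNames(.status_from_cosine(truth_cos),
                                  names(truth_cos))
    hits$status <- unname(status_all[hits$record_id])
    out[[i]] <- tibble(
      query_id = truths$id[i],
      n_relevant = sum(status_all %in% c("identical", "similar")),
      hits = list(hits)
    )
  }
  dplyr::bind_rows(out)
}

#' Benchmark metrics over a set of queries
#'
#' @param cases from [build_eval_cases()].
#' @param ks rank cutoffs.
#' @return tibble with one row per k: `identification_rate`,
#'   `annotation_rate`, `precision`, `recall`, `f1`, and `n_queries`.
#' @export
metrics_report <- function(cases, ks = c(1, 5, 10)) {
  .check_cases(cases)
  rows <- lapply(ks, function(k) {
    p <- precision_at_k(cases, k)
    r <- recall_at_k(cases, k)
    tibble(
      k = k,
      identification_rate = rate_at_k(cases, k, "identical"),
      annotation_rate = rate_at_k(cases, k, "similar"),
      precision = p, recall = r, f1 = f1_at_k(p, r),
      n_queries = nrow(cases)
    )
  })
  dplyr::bind_rows(rows)
}
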