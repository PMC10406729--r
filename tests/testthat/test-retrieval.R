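test_that("fingerprint cosine matches closed forms and rejects zero vectors", {
  expect_equal(fp_cosine(toy_fp(1:5), toy_fp(1:5)), 1.0)
  expect_equal(fp_cosine(toy_fp(1:3), toy_fp(4:6)), 0.0)
  expect_equal(fp_cosine(toy_fp(1:2), toy_fp(c(1, 3))), 0.5) # 1/(sqrt2*sqrt2)
  expect_error(fp_cosine(numeric(8), rep(1, 8)), "zero")
  expect_error(fp_cosine(toy_fp(1), toy_fp(1:2)[1:100]), "lengths")
})

toy_db <- function() {
  vocab <- class_vocabulary(c("aromatic", "aliphatic"))
  build_reference_db(
    tibble::tibble(
      id = c("benzene", "phenol", "toluene", "hexane", "cyclohexane"),
      smiles = c("c1ccccc1", "c1ccccc1O", "Cc1ccccc1", "CCCCCC", "C1CCCCC1"),
      class = c("aromatic", "aromatic", "aromatic", "aliphatic", "aliphatic")
    ),
    vocab
  )
}

test_that("a record's own fingerprint retrieves it at rank 1 with cosine 1", {
  db <- toy_db()
  for (i in c(1, 3, 5)) {
    hits <- search_db(list(fingerprint = db$records$fingerprint[[i]],
                           mw = db$records$mw[i]), db, k = 3)
    expect_equal(hits$record_id[1], db$records$id[i])
    expect_equal(hits$cosine[1], 1.0, tolerance = 1e-12)
    expect_true(all(diff(hits$cosine) <= 1e-12))
  }
})

test_that("k beyond the database size returns all survivors; empty db errors", {
  db <- toy_db()
  hits <- search_db(list(fingerprint = db$records$fingerprint[[1]], mw = 78),
                    db, k = 100)
  expect_equal(nrow(hits), 5)
  expect_equal(hits$rank, 1:5)
  expect_error(search_db(toy_fp(1:4), structure(
    list(records = tibble::tibble()), class = "reference_db"
  )), "empty")
})

test_that("search equals the brute-force oracle across filter combinations", {
  set.seed(11)
  vocab <- class_vocabulary(c("a", "b", "c"))
  pool <- c(
    "CCO", "CCCO", "CCCCO", "CC(C)O", "CCN", "CCC(=O)O", "CCOC", "CC(C)C",
    "c1ccccc1", "Cc1ccccc1", "c1ccccc1O", "c1ccccc1N", "CCc1ccccc1",
    "C1CCCCC1", "C1CCOCC1", "CC1CCCCC1", "OCC1OC(O)C(O)C(O)C1O",
    "CC(=O)OC", "CCCC", "CCCCC"
  )
  for (trial in 1:20) {
    n <- sample(5:20, 1)
    pick <- sample(seq_along(pool), n)
    db <- build_reference_db(
      tibble::tibble(
        id = sprintf("r%02d", seq_len(n)), smiles = pool[pick],
        class = sample(c("a", "b", "c"), n, TRUE)
      ),
      vocab
    )
    # a probability-vector query derived from a perturbed random record
    base <- as.numeric(db$records$fingerprint[[sample(n, 1)]])
    q <- pmin(pmax(base * runif(6144, 0.4, 1) + runif(6144, 0, 0.05), 0), 1)
    pred <- list(
      fingerprint = q, mw = sample(50:250, 1),
      class_probs = stats::setNames(as.vector(stats::rmultinom(1, 10, rep(1, 3)) / 10),
                                    c("a", "b", "c"))
    )
    k <- sample(1:8, 1)
    for (flags in list(list(NULL, FALSE), list(NULL, TRUE),
                       list(40, FALSE), list(40, TRUE))) {
      got <- search_db(pred, db, k = k, mw_window = flags[[1]],
                       class_filter = flags[[2]])
      want <- oracle_search(pred, db, k, mw_window = flags[[1]],
                            class_filter = flags[[2]])
      expect_equal(got$record_id, want)
    }
  }
})

test_that("widening the mw window never shrinks the survivor set", {
  db <- toy_db()
  pred <- list(fingerprint = as.numeric(db$records$fingerprint[[2]]),
               mw = 90, class_probs = c(aromatic = 1, aliphatic = 0))
  prev <- character(0)
  for (wdw in c(5, 15, 40, 100, 1000)) {
    hits <- search_db(pred, db, k = 10, mw_window = wdw)
    expect_true(all(prev %in% hits$record_id))
    prev <- hits$record_id
  }
})

test_that("filtering everything out returns an empty hit table", {
  db <- toy_db()
  pred <- list(fingerprint = as.numeric(db$records$fingerprint[[1]]),
               mw = 1e6)
  hits <- search_db(pred, db, k = 5, mw_window = 1)
  expect_equal(nrow(hits), 0)
})

test_that("reference databases round-trip with bit-identical fingerprints", {
  db <- toy_db()
  path <- tempfile(fileext = ".rds")
  write_reference_db(db, path)
  back <- read_reference_db(path)
  expect_identical(db$fp, back$fp)
  expect_identical(db$records$mw, back$records$mw)
  expect_error(
    build_reference_db(
      tibble::tibble(id = c("x", "x"), smiles = c("C", "CC"), class = "a"),
      class_vocabulary(c("a", "b"))
    ),
    "duplicate"
  )
})

test_that("baseline matcher scores an identical spectrum 1.0", {
  q <- peak_list(c(6.30, 6.19, 2.10), c(92.9, 97.8, 30.5))
  refs <- list(self = q, other = peak_list(c(1.0), c(10)))
  res <- baseline_shift_match(q, refs)
  expect_equal(res$record_id[1], "self")
  expect_equal(res$score[1], 1.0)
  expect_equal(res$n_matched[1], 3L)
  expect_error(baseline_shift_match(peak_list(), refs), "empty")
})

test_that("the shift tolerances are enforced exactly at the boundary", {
  q <- peak_list(6.30, 92.9)
  # |dH| = 0.06 > 0.05: no match even though carbon matches exactly
  expect_equal(
    baseline_shift_match(q, list(r = peak_list(6.36, 92.9)))$score, 0
  )
  # inclusive boundaries: |dH| = 0.05 and |dC| = 0.5 both match
  expect_equal(
    baseline_shift_match(q, list(r = peak_list(6.35, 93.4)))$score, 1
  )
  expect_equal(
    baseline_shift_match(q, list(r = peak_list(6.3501, 93.4)))$score, 0
  )
})

test_that("a 3-peak query with two pairable peaks scores 2*2/6", {
  q <- peak_list(c(6.30, 6.19, 2.00), c(92.9, 97.8, 30.0))
  r <- peak_list(c(6.31, 6.20, 9.50), c(93.0, 97.9, 190.0))
  res <- baseline_shift_match(q, list(ref = r))
  expect_equal(res$score, 2 * 2 / (3 + 3), tolerance = 1e-12)
  expect_equal(res$n_matched, 2L)
  expect_equal(oracle_max_matching(q, r), 2L)
})

test_that("matcher equals exhaustive maximum matching on clustered instances", {
  set.seed(23)
  for (trial in 1:60) {
    nq <- sample(1:4, 1)
    nr <- sample(1:4, 1)
    # cluster shifts tightly so that pairing conflicts actually occur
    q <- peak_list(3 + runif(nq, 0, 0.12), 60 + runif(nq, 0, 1.2))
    r <- peak_list(3 + runif(nr, 0, 0.12), 60 + runif(nr, 0, 1.2))
    got <- baseline_shift_match(q, list(x = r))
    expect_equal(got$n_matched, oracle_max_matching(q, r))
    expect_equal(got$score, 2 * got$n_matched / (nq + nr))
  }
})

test_that("matcher score is symmetric for equal-size peak lists", {
  set.seed(31)
  for (trial in 1:10) {
    n <- sample(2:5, 1)
    a <- peak_list(runif(n, 1, 9), runif(n, 10, 180))
    b <- peak_list(runif(n, 1, 9), runif(n, 10, 180))
    expect_equal(
      baseline_shift_match(a, list(x = b))$score,
      baseline_shift_match(b, list(x = a))$score
    )
  }
})
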