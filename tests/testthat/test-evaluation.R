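test_that("hit status thresholds are inclusive and identical implies similar", {
  a <- toy_fp(1:5)
  expect_equal(hit_status(a, a), "identical")
  # 4 shared of 5 vs 4 total: 4/sqrt(20) = 0.894 -> similar
  expect_equal(hit_status(a, toy_fp(1:4)), "similar")
  # 4 shared, both size 5: cosine exactly 0.8 -> similar (inclusive)
  expect_equal(hit_status(a, toy_fp(c(1:4, 9))), "similar")
  expect_equal(fp_cosine(a, toy_fp(c(1:4, 9))), 0.8)
  # cosine 0.5 -> neither
  expect_equal(hit_status(toy_fp(1:2), toy_fp(c(1, 3))), "neither")
  expect_error(hit_status(numeric(6144), a), "zero")
})

# a small constructed benchmark with known per-case hit statuses
constructed_cases <- function() {
  mk <- function(statuses, nrel) {
    tibble::tibble(
      query_id = "q", n_relevant = nrel,
      hits = list(tibble::tibble(
        rank = seq_along(statuses),
        record_id = paste0("r", seq_along(statuses)),
        status = statuses
      ))
    )
  }
  dplyr::bind_rows(
    mk(c("identical", "neither", "neither", "neither", "neither"), 1), # id @1
    mk(c("similar", "identical", "neither", "neither", "neither"), 2), # id @2
    mk(c("neither", "neither", "similar", "neither", "neither"), 1),   # sim @3
    mk(c("neither", "neither", "neither", "neither", "neither"), 0),   # nothing
    mk(c("similar", "similar", "similar", "neither", "neither"), 4)    # 3 sim
  )
}

test_that("identification and annotation rates match hand counts", {
  cases <- constructed_cases()
  expect_equal(rate_at_k(cases, 1, "identical"), 1 / 5)
  expect_equal(rate_at_k(cases, 2, "identical"), 2 / 5)
  expect_equal(rate_at_k(cases, 1, "similar"), 3 / 5)
  expect_equal(rate_at_k(cases, 5, "similar"), 4 / 5)
  # non-decreasing in k, identification <= annotation at every k
  for (k in 1:5) {
    expect_lte(rate_at_k(cases, k, "identical"), rate_at_k(cases, k, "similar"))
    if (k > 1) {
      expect_gte(rate_at_k(cases, k, "identical"),
                 rate_at_k(cases, k - 1, "identical"))
    }
  }
  # a hit at rank 3 counts at k = 5 but not k = 2
  late <- cases[3, ]
  expect_equal(rate_at_k(late, 2, "similar"), 0)
  expect_equal(rate_at_k(late, 5, "similar"), 1)
  expect_error(rate_at_k(cases[0, ], 1), "non-empty")
})

test_that("precision, recall and F1 match their closed forms", {
  cases <- constructed_cases()
  # precision@5 per case: 1/5, 2/5, 1/5, 0, 3/5 -> mean 7/25
  expect_equal(precision_at_k(cases, 5), 7 / 25)
  expect_equal(precision_at_k(cases[5, ], 5), 3 / 5)
  expect_equal(precision_at_k(cases[5, ], 3), 1.0)
  # recall@5 per case: 1, 1, 1, 1 (vacuous), 3/4
  expect_equal(recall_at_k(cases, 5), (4 + 3 / 4) / 5)
  expect_equal(recall_at_k(cases[5, ], 2), 2 / 4)
  expect_equal(f1_at_k(0.5, 0.5), 0.5)
  expect_equal(f1_at_k(1, 0), 0)
  expect_equal(f1_at_k(0.6, 0.5), 2 * 0.3 / 1.1)
  # precision*k and recall*n_relevant count the same numerator
  for (k in 1:5) {
    num_p <- precision_at_k(cases[5, ], k) * k
    num_r <- recall_at_k(cases[5, ], k) * cases$n_relevant[5]
    expect_equal(num_p, num_r)
  }
})

test_that("metrics_report equals a brute-force recomputation on a seeded benchmark", {
  set.seed(17)
  statuses <- c("identical", "similar", "neither")
  cases <- dplyr::bind_rows(lapply(1:12, function(i) {
    s <- sample(statuses, 8, TRUE, prob = c(0.15, 0.3, 0.55))
    tibble::tibble(
      query_id = paste0("q", i),
      n_relevant = sum(s != "neither") + sample(0:2, 1),
      hits = list(tibble::tibble(rank = 1:8, record_id = paste0("r", 1:8),
                                 status = s))
    )
  }))
  rep <- metrics_report(cases, ks = c(1, 3, 8))
  for (row in seq_len(nrow(rep))) {
    k <- rep$k[row]
    id_bf <- mean(sapply(cases$hits, function(h) any(h$status[1:k] == "identical")))
    an_bf <- mean(sapply(cases$hits, function(h) any(h$status[1:k] != "neither")))
    pr_bf <- mean(sapply(cases$hits, function(h) sum(h$status[1:k] != "neither") / k))
    rc_bf <- mean(mapply(function(h, nrel) {
      if (nrel == 0) 1 else sum(h$status[1:k] != "neither") / nrel
    }, cases$hits, cases$n_relevant))
    expect_equal(rep$identification_rate[row], id_bf)
    expect_equal(rep$annotation_rate[row], an_bf)
    expect_equal(rep$precision[row], pr_bf)
    expect_equal(rep$recall[row], rc_bf)
    expect_equal(rep$f1[row], f1_at_k(pr_bf, rc_bf))
  }
})

test_that("retrieving more relevant hits than exist is an internal error", {
  bad <- tibble::tibble(
    query_id = "q", n_relevant = 1,
    hits = list(tibble::tibble(rank = 1:2, record_id = c("a", "b"),
                               status = c("similar", "similar")))
  )
  expect_error(recall_at_k(bad, 2), "inconsistency")
})

test_that("build_eval_cases labels hits from truth-vs-db fingerprints", {
  vocab <- class_vocabulary(c("a", "b"))
  db <- build_reference_db(
    tibble::tibble(
      id = c("ethanol", "propanol", "benzene"),
      smiles = c("CCO", "CCCO", "c1ccccc1"),
      class = c("a", "a", "b")
    ),
    vocab
  )
  truths <- db$records[1, ]
  pred <- list(fingerprint = as.numeric(db$records$fingerprint[[1]]),
               mw = db$records$mw[1])
  cases <- build_eval_cases(list(pred), truths, db)
  expect_equal(cases$hits[[1]]$record_id[1], "ethanol")
  expect_equal(cases$hits[[1]]$status[1], "identical")
  expect_gte(cases$n_relevant, 1)
  # excluding the self record removes it from hits and the relevant count
  cases2 <- build_eval_cases(list(pred), truths, db, exclude_self = TRUE)
  expect_false("ethanol" %in% cases2$hits[[1]]$record_id)
  expect_equal(cases2$n_relevant, cases$n_relevant - 1)
})
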