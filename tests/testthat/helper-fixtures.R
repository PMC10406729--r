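# Shared fixtures: tiny peak lists, toy fingerprint vectors, brute-force
# oracles, and a hand-built linear surrogate "model" for attribution tests.

quercetin_a_ring_peaks <- function(edited = FALSE) {
  # the two A-ring CH cross-peaks of quercetin
  peak_list(h_shift = c(6.30, 6.19), c_shift = c(92.9, 97.8), edited = edited)
}

# Zero-padded binary fingerprint with the given bits set (1-based).
toy_fp <- function(bits) {
  v <- numeric(6144)
  v[bits] <- 1
  v
}

bundled_smiles <- function() {
  path <- system.file("extdata", "test_molecules.smi", package = "peakfinger")
  tab <- read.table(path, col.names = c("smiles", "id"))
  tab
}

# Brute-force search oracle: score every record, apply filters, full sort.
oracle_search <- function(pred, db, k, mw_window = NULL, class_filter = FALSE) {
  q <- as.numeric(pred$fingerprint)
  rows <- seq_len(nrow(db$records))
  cs <- vapply(rows, function(i) {
    v <- as.numeric(db$records$fingerprint[[i]])
    sum(q * v) / sqrt(sum(q^2) * sum(v^2))
  }, numeric(1))
  mwd <- abs(db$records$mw - pred$mw)
  keep <- rep(TRUE, length(rows))
  if (!is.null(mw_window)) {
    keep <- keep & (abs(db$records$mw - pred$mw) / pred$mw <= mw_window / 100)
  }
  if (class_filter) {
    keep <- keep & (db$records$class_label == which.max(pred$class_probs))
  }
  idx <- rows[keep]
  ord <- idx[order(-round(cs[idx], 12), mwd[idx], db$records$id[idx])]
  head(db$records$id[ord], min(k, length(ord)))
}

# Brute-force maximum matching: enumerate all injective pairings.
oracle_max_matching <- function(query, ref, c_tol = 0.5, h_tol = 0.05) {
  nq <- nrow(query)
  nr <- nrow(ref)
  compat <- outer(seq_len(nq), seq_len(nr), Vectorize(function(i, j) {
    abs(query$c_shift[i] - ref$c_shift[j]) <= c_tol &&
      abs(query$h_shift[i] - ref$h_shift[j]) <= h_tol
  }))
  best <- 0L
  recurse <- function(i, used, count) {
    if (count + (nq - i + 1) <= best) return() # prune
    if (i > nq) {
      best <<- max(best, count)
      return()
    }
    recurse(i + 1, used, count) # skip query peak i
    for (j in seq_len(nr)) {
      if (!used[j] && compat[i, j]) {
        used[j] <- TRUE
        recurse(i + 1, used, count + 1L)
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, nr), 0L)
  best
}

# A deterministic linear surrogate: fingerprint probability b is a
# sigmoid-squashed weighted sum of the image, with weights a fixed hash of
# (bit, pixel). Linear in the grid, so it respects every symmetry the
# rasterized image has.
make_linear_surrogate <- function() {
  structure(list(), class = "linear_fp_model")
}

predict.linear_fp_model <- function(object, image, ...) {
  px <- which(image$grid != 0)
  bits <- seq_len(6144)
  act <- numeric(6144)
  for (p in px) {
    w <- (((bits * 131 + p * 17) %% 101) - 50) / 50
    act <- act + image$grid[p] * w
  }
  list(
    fingerprint = new_fingerprint(stats::plogis(act), "probability"),
    class_probs = c(0.5, 0.5),
    mw = 100 + sum(image$grid),
    glycoside_prob = stats::plogis(sum(act) / 6144)
  )
}
registerS3method("predict", "linear_fp_model", predict.linear_fp_model,
                 envir = asNamespace("stats"))
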