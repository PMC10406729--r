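# small architecture shared by the model tests
tiny_cfg <- function(channels = 1, n_classes = 5) {
  model_config(
    channels = channels,
    conv_stack = tibble::tibble(filters = c(8, 16), kernel = c(5, 3),
                                stride = c(4, 2)),
    n_classes = n_classes
  )
}

tiny_dataset <- function(n, seed = 2, edited = FALSE) {
  ds <- make_dataset(
    simulator_config(n_molecules = n, seed = seed,
                     noise_sd_h = 0, noise_sd_c = 0),
    edited = edited
  )
  list(ds = ds, imgs = lapply(ds$examples$peaks, rasterize))
}

test_that("configs validate their invariants", {
  expect_error(model_config(channels = 3), "channels")
  expect_error(model_config(fingerprint_dim = 1024), "6144")
  expect_error(model_config(n_classes = 1), "n_classes")
  expect_error(model_config(loss_weights = c(fp = -1, class = 1, mw = 1, gly = 1)),
               "non-negative")
  expect_error(training_config(learning_rate = 0), "learning_rate")
  expect_error(training_config(dropout = 1), "dropout")
  expect_equal(model_config()$embedding_dim, 256L)
})

test_that("the model accepts its own channel count and rejects others", {
  m1 <- build_model(tiny_cfg(1), seed = 1)
  img1 <- rasterize(peak_list(5, 100))
  img2 <- rasterize(peak_list(5, 100, edited = TRUE))
  expect_s3_class(predict(m1, img1), "hsqc_prediction")
  expect_error(predict(m1, img2), "channel")
  m2 <- build_model(tiny_cfg(2), seed = 1)
  expect_s3_class(predict(m2, img2), "hsqc_prediction")
  expect_error(predict(m2, img1), "channel")
})

test_that("untrained predictions already satisfy the output contracts", {
  m <- build_model(tiny_cfg(), seed = 7)
  for (img in list(rasterize(peak_list(5, 100)), rasterize(peak_list()))) {
    p <- predict(m, img)
    expect_equal(sum(p$class_probs), 1, tolerance = 1e-5)
    expect_true(all(p$fingerprint >= 0 & p$fingerprint <= 1))
    expect_gt(p$mw, 0)
    expect_gte(p$glycoside_prob, 0)
    expect_lte(p$glycoside_prob, 1)
    expect_false(any(!is.finite(c(p$mw, p$glycoside_prob, p$class_probs,
                                  as.numeric(p$fingerprint)))))
  }
})

test_that("multitask loss matches its closed forms", {
  K <- 5
  vocab <- class_vocabulary(letters[1:K])
  truth <- build_record("eth", "CCO", "a", vocab)
  perfect <- list(
    fingerprint = as.numeric(truth$fingerprint[[1]]),
    class_probs = c(1, 0, 0, 0, 0), mw = truth$mw, glycoside_prob = 0
  )
  expect_lt(multitask_loss(perfect, truth), 1e-5)
  # doubling the molecular weight with weights (0,0,1,0) gives MAPE 100
  mw2 <- perfect
  mw2$mw <- 2 * truth$mw
  expect_equal(
    multitask_loss(mw2, truth, weights = c(fp = 0, class = 0, mw = 1, gly = 0)),
    100
  )
  # uniform class probabilities with weights (0,1,0,0) give ln K
  unif <- perfect
  unif$class_probs <- rep(1 / K, K)
  expect_equal(
    multitask_loss(unif, truth, weights = c(fp = 0, class = 1, mw = 0, gly = 0)),
    log(K)
  )
  expect_error(
    multitask_loss(perfect, list(fingerprint = truth$fingerprint[[1]],
                                 class_label = 1, mw = -5, glycoside = FALSE)),
    "> 0"
  )
})

test_that("single-weight losses decompose the multitask loss", {
  vocab <- class_vocabulary(letters[1:5])
  truth <- build_record("glc", "COC1OC(CO)C(O)C(O)C1O", "b", vocab)
  set.seed(5)
  pred <- list(
    fingerprint = runif(6144), class_probs = as.vector(
      prop.table(runif(5))),
    mw = 210, glycoside_prob = 0.7
  )
  total <- multitask_loss(pred, truth)
  parts <- sapply(c("fp", "class", "mw", "gly"), function(h) {
    w <- c(fp = 0, class = 0, mw = 0, gly = 0)
    w[h] <- 1
    multitask_loss(pred, truth, weights = w)
  })
  expect_equal(sum(parts), total)
})

test_that("training is reproducible bit-for-bit under a fixed seed", {
  td <- tiny_dataset(32)
  m <- build_model(tiny_cfg(), seed = 4)
  tc <- training_config(learning_rate = 1e-3, epochs = 2, seed = 9,
                        batch_size = 8)
  f1 <- train_model(m, td$imgs, td$ds$examples, tc)
  f2 <- train_model(m, td$imgs, td$ds$examples, tc)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("training reduces the loss on a small synthetic set", {
  td <- tiny_dataset(96, seed = 6)
  m <- build_model(tiny_cfg(), seed = 4)
  tc <- training_config(learning_rate = 1e-3, epochs = 10, seed = 9)
  fit <- train_model(m, td$imgs, td$ds$examples, tc)
  expect_lt(fit$history$loss[10], fit$history$loss[1])
  expect_true(fit$model$trained)
  # broom-style accessors
  expect_equal(nrow(tidy(fit)), 10)
  expect_equal(glance(fit)$epochs, 10)
})

test_that("training rejects empty datasets and channel mismatches", {
  m <- build_model(tiny_cfg(1), seed = 1)
  tc <- training_config(epochs = 1)
  expect_error(train_model(m, list(), tibble::tibble(), tc), "empty")
  td <- tiny_dataset(8, edited = TRUE)
  expect_error(train_model(m, td$imgs, td$ds$examples, tc), "channel")
})

test_that("two-channel models train on multiplicity-edited spectra", {
  td <- tiny_dataset(16, seed = 12, edited = TRUE)
  expect_equal(dim(td$imgs[[1]]$grid)[3], 2)
  m <- build_model(tiny_cfg(channels = 2), seed = 2)
  fit <- train_model(m, td$imgs, td$ds$examples,
                     training_config(learning_rate = 1e-3, epochs = 2,
                                     seed = 5, batch_size = 8))
  expect_equal(nrow(fit$history), 2)
  p <- predict(fit$model, td$imgs[[1]])
  expect_true(all(is.finite(as.numeric(p$fingerprint))))
})

test_that("inference is deterministic and batched prediction matches single", {
  td <- tiny_dataset(6)
  m <- build_model(tiny_cfg(), seed = 3)
  p1 <- predict(m, td$imgs[[1]])
  p2 <- predict(m, td$imgs[[1]])
  expect_identical(p1, p2)
  batch <- predict(m, td$imgs)
  expect_equal(as.numeric(batch[[1]]$fingerprint), as.numeric(p1$fingerprint))
  expect_equal(batch[[4]]$mw, predict(m, td$imgs[[4]])$mw)
})

test_that("checkpoints round-trip the model with its metadata", {
  m <- build_model(tiny_cfg(), seed = 3,
                   vocabulary = synthetic_class_vocabulary())
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  back <- load_model(path)
  expect_identical(m$params, back$params)
  expect_identical(as.character(m$vocabulary), as.character(back$vocabulary))
  img <- rasterize(peak_list(5, 100))
  expect_identical(predict(m, img), predict(back, img))
})
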