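#' Model architecture configuration
#'
#' The network maps a 128 x 128 HSQC image (1 channel for normal HSQC,
#' 2 for multiplicity-edited) through a stack of stride-2 convolutions —
#' each followed by batch normalization and ReLU — to a global max pooled
#' embedding, then through dropout to four fully connected heads:
#' fingerprint (6144 sigmoid units), class (softmax over K), molecular
#' weight (positive, exponential link), and glycoside (sigmoid).
#'
#' Because global max pooling is translation-invariant while chemical
#' shifts carry meaning in absolute position, two normalized coordinate
#' channels are appended to the input by default (`coord_channels`), which
#' lets pooled detectors be position-specific.
#'
#' @param channels 1 (normal HSQC) or 2 (multiplicity-edited).
#' @param conv_stack data frame with columns `filters`, `kernel`, `stride`
#'   (one row per stage). Default: 4 stages of 32/64/128/256 3x3 stride-2
#'   filters.
#' @param n_classes number of compound classes K (>= 2).
#' @param fingerprint_dim fingerprint width; fixed at 6144.
#' @param loss_weights named non-negative weights `fp`, `class`, `mw`,
#'   `gly` for the multi-task loss.
#' @param coord_channels append coordinate channels to the input?
#' @return a `model_config` list. `embedding_dim` (the pooled feature size)
#'   equals the last stage's filter count.
#' @export
model_config <- function(channels = 1,
                         conv_stack = NULL,
                         n_classes = 5,
                         fingerprint_dim = 6144,
                         loss_weights = c(fp = 1, class = 1, mw = 1, gly = 1),
                         coord_channels = TRUE) {
  if (!channels %in% 1:2) abort("channels must be 1 or 2")
  if (fingerprint_dim != FP_NBITS) {
    abort(sprintf("fingerprint_dim is fixed at %d", FP_NBITS))
  }
  if (n_classes < 2) abort("n_classes must be >= 2")
  conv_stack <- conv_stack %||%
    tibble(filters = c(32, 64, 128, 256), kernel = 3, stride = 2)
  conv_stack <- as_tibble(conv_stack)
  stopifnot(all(c("filters", "kernel", "stride") %in% names(conv_stack)))
  w <- loss_weights[c("fp", "class", "mw", "gly")]
  if (anyNA(w) || any(w < 0)) {
    abort("loss_weights must supply non-negative fp, class, mw, gly")
  }
  structure(
    list(
      channels = as.integer(channels), conv_stack = conv_stack,
      embedding_dim = as.integer(conv_stack$filters[nrow(conv_stack)]),
      n_classes = as.integer(n_classes), fingerprint_dim = FP_NBITS,
      loss_weights = w, coord_channels = isTRUE(coord_channels)
    ),
    class = "model_config"
  )
}

#' Training hyperparameters
#'
#' Defaults follow the reference setting for corpus-scale training (Adam,
#' learning rate 1e-5 with decay 1e-6, dropout 0.2, batch size 16). For
#' desk-scale synthetic runs (a few hundred molecules) raise the learning
#' rate to 1e-3, otherwise the loss barely moves within any reasonable
#' epoch budget.
#'
#' @param learning_rate Adam learning rate (> 0).
#' @param decay per-step learning-rate decay, `lr_t = lr / (1 + decay * t)`.
#' @param batch_size minibatch size (>= 1).
#' @param dropout dropout rate on the pooled embedding, in \[0, 1).
#' @param epochs number of epochs.
#' @param seed integer seed covering weight init is separate; this seed
#'   drives shuffling, the validation split and dropout.
#' @param val_fraction fraction of the training set held out for
#'   per-epoch validation (ignored when `val_idx` is passed to [train_model()]).
#' @return a `training_config` list.
#' @export
training_config <- function(learning_rate = 1e-5, decay = 1e-6,
                            batch_size = 16, dropout = 0.2, epochs = 10,
                            seed = 1, val_fraction = 0.1) {
  if (learning_rate <= 0) abort("learning_rate must be > 0")
  if (dropout < 0 || dropout >= 1) abort("dropout must be in [0, 1)")
  if (batch_size < 1) abort("batch_size must be >= 1")
  structure(
    list(
      learning_rate = learning_rate, decay = decay,
      batch_size = as.integer(batch_size), dropout = dropout,
      epochs = as.integer(epochs), seed = as.integer(seed),
      val_fraction = val_fraction
    ),
    class = "training_config"
  )
}

#' Build an (untrained) multi-task HSQC model
#'
#' @param cfg a [model_config()].
#' @param seed seed for weight initialization (He-normal conv weights,
#'   small-normal head weights; the molecular-weight head bias starts at
#'   `log(300)` so initial predictions sit in the typical small-molecule
#'   mass range).
#' @param vocabulary optional class vocabulary stored with the model.
#' @param bounds optional [spectrum_bounds()] stored with the model.
#' @return an `hsqc_model`.
#' @export
build_model <- function(cfg, seed = 42L, vocabulary = NULL, bounds = NULL) {
  stopifnot(inherits(cfg, "model_config"))
  cin0 <- cfg$channels + if (cfg$coord_channels) 2L else 0L
  H <- IMG_SIZE
  geoms <- list()
  params <- list()
  bn <- list()
  withr::with_seed(as.integer(seed), {
    cin <- cin0
    for (l in seq_len(nrow(cfg$conv_stack))) {
      k <- cfg$conv_stack$kernel[l]
      s <- cfg$conv_stack$stride[l]
      f <- cfg$conv_stack$filters[l]
      geoms[[l]] <- .conv_geom(H, H, k, s)
      fan_in <- k * k * cin
      params[[paste0("conv", l, ".W")]] <-
        matrix(stats::rnorm(fan_in * f, sd = sqrt(2 / fan_in)), fan_in, f)
      params[[paste0("conv", l, ".gamma")]] <- rep(1, f)
      params[[paste0("conv", l, ".beta")]] <- rep(0, f)
      bn[[paste0("conv", l, ".mean")]] <- rep(0, f)
      bn[[paste0("conv", l, ".var")]] <- rep(1, f)
      H <- geoms[[l]]$Hout
      cin <- f
    }
    E <- cfg$embedding_dim
    params$fp.W <- matrix(stats::rnorm(E * FP_NBITS, sd = 0.01), E, FP_NBITS)
    params$fp.b <- rep(0, FP_NBITS)
    params$class.W <- matrix(stats::rnorm(E * cfg$n_classes, sd = 0.01),
                             E, cfg$n_classes)
    params$class.b <- rep(0, cfg$n_classes)
    params$mw.W <- matrix(stats::rnorm(E, sd = 0.01), E, 1)
    params$mw.b <- log(300)
    params$gly.W <- matrix(stats::rnorm(E, sd = 0.01), E, 1)
    params$gly.b <- 0
  })
  structure(
    list(
      cfg = cfg, params = params, bn = bn, geoms = geoms,
      vocabulary = vocabulary, bounds = bounds %||% spectrum_bounds(),
      trained = FALSE
    ),
    class = "hsqc_model"
  )
}

#' @export
print.hsqc_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf(
    "<hsqc_model> %d-channel input, %d conv stages, %d classes, %s (%s params)\n",
    x$cfg$channels, length(x$geoms), x$cfg$n_classes,
    if (x$trained) "trained" else "untrained", format(np, big.mark = ",")
  ))
  invisible(x)
}

# Precompute dense target arrays once (tibble slicing is too slow for the
# inner loop).
.truth_arrays <- function(records) {
  list(
    Yfp = do.call(rbind, lapply(records$fingerprint, unclass)),
    class = as.integer(records$class_label),
    mw = as.numeric(records$mw),
    gly = as.logical(records$glycoside)
  )
}

.batch_truth <- function(truth, idx) {
  list(
    Yfp = truth$Yfp[idx, , drop = FALSE],
    class = truth$class[idx], mw = truth$mw[idx], gly = truth$gly[idx]
  )
}

#' Multi-task loss
#'
#' `w_fp * BCE(fingerprint) + w_class * CCE(class) + w_mw * MAPE(mw) +
#' w_gly * BCE(glycoside)`, each term mean-reduced;
#' `MAPE = 100 |mw_pred - mw_true| / mw_true`. Probabilities are clipped
#' at 1e-7 before the logs, so a perfect prediction scores ~0 (within
#' clipping tolerance) rather than exactly 0.
#'
#' @param pred an `hsqc_prediction` (or list with `fingerprint`,
#'   `class_probs`, `mw`, `glycoside_prob`).
#' @param truth a one-row record from [build_records()] (or list with
#'   `fingerprint`, `class_label`, `mw`, `glycoside`).
#' @param weights named weights `fp`, `class`, `mw`, `gly`; default all 1.
#' @return scalar loss.
#' @export
multitask_loss <- function(pred, truth,
                           weights = c(fp = 1, class = 1, mw = 1, gly = 1)) {
  if (is.data.frame(truth)) {
    stopifnot(nrow(truth) == 1)
    truth <- list(
      fingerprint = truth$fingerprint[[1]], class_label = truth$class_label,
      mw = truth$mw, glycoside = truth$glycoside
    )
  }
  if (truth$mw <= 0) abort("true molecular weight must be > 0")
  w <- weights[c("fp", "class", "mw", "gly")]
  if (anyNA(w)) abort("weights must name fp, class, mw, gly")
  p_fp <- .clip_prob(as.numeric(pred$fingerprint))
  y_fp <- as.numeric(truth$fingerprint)
  L_fp <- -mean(y_fp * log(p_fp) + (1 - y_fp) * log(1 - p_fp))
  L_cl <- -log(.clip_prob(pred$class_probs[truth$class_label]))
  L_mw <- 100 * abs(pred$mw - truth$mw) / truth$mw
  y_g <- as.numeric(truth$glycoside)
  p_g <- .clip_prob(pred$glycoside_prob)
  L_gl <- -(y_g * log(p_g) + (1 - y_g) * log(1 - p_g))
  unname(w[["fp"]] * L_fp + w[["class"]] * L_cl +
           w[["mw"]] * L_mw + w[["gly"]] * L_gl)
}

#' Train the multi-task network
#'
#' Minibatch Adam on the summed multi-task loss. Fully seeded: the
#' validation split, epoch shuffles and dropout masks all derive from
#' `tcfg$seed` (weight initialization is seeded in [build_model()]), so
#' identical calls give identical histories.
#'
#' @param model an `hsqc_model` from [build_model()].
#' @param images list of `hsqc_image` (or 128 x 128 x C arrays) whose
#'   channel count matches the model.
#' @param records target tibble from [build_records()], same length/order
#'   as `images`.
#' @param tcfg a [training_config()].
#' @param val_idx optional explicit validation indices (into `images`);
#'   when absent, a seeded `val_fraction` split is drawn.
#' @return an `hsqc_fit`: list with the trained `model` and a per-epoch
#'   `history` tibble (`epoch`, `loss`, `val_loss`, `val_mape`,
#'   `val_cosine`, `val_accuracy`).
#' @export
train_model <- function(model, images, records, tcfg, val_idx = NULL) {
  stopifnot(inherits(model, "hsqc_model"), inherits(tcfg, "training_config"))
  n <- length(images)
  if (n == 0) abort("training dataset is empty")
  if (nrow(records) != n) abort("images and records lengths differ")
  cfg <- model$cfg
  planes <- lapply(images, .image_planes, cfg = cfg) # validates channels
  w <- cfg$loss_weights
  set.seed(tcfg$seed)
  if (is.null(val_idx)) {
    n_val <- max(1L, round(tcfg$val_fraction * n))
    val_idx <- sort(sample(n, n_val))
  }
  train_idx <- setdiff(seq_len(n), val_idx)
  if (length(train_idx) == 0) abort("no training examples left after split")
  adam <- .adam_init(model$params)
  truth <- .truth_arrays(records)
  history <- vector("list", tcfg$epochs)
  for (ep in seq_len(tcfg$epochs)) {
    ord <- sample(train_idx)
    batches <- split(ord, ceiling(seq_along(ord) / tcfg$batch_size))
    tot <- 0
    for (bi in batches) {
      fw <- .net_forward(model, planes[bi], train = TRUE,
                         dropout = tcfg$dropout)
      hg <- .head_loss_grads(fw, .batch_truth(truth, bi), w)
      grads <- .net_backward(model, fw, hg)
      st <- .adam_step(model$params, grads, adam,
                       tcfg$learning_rate, tcfg$decay)
      model$params <- st$params
      adam <- st$state
      model <- .bn_update(model, fw)
      tot <- tot + hg$loss * length(bi)
    }
    val <- .evaluate_split(model, planes[val_idx], .batch_truth(truth, val_idx), w)
    history[[ep]] <- tibble(
      epoch = ep, loss = tot / length(train_idx),
      val_loss = val$loss, val_mape = val$mape,
      val_cosine = val$cosine, val_accuracy = val$accuracy
    )
  }
  model$trained <- TRUE
  structure(
    list(model = model, history = dplyr::bind_rows(history),
         val_idx = val_idx),
    class = "hsqc_fit"
  )
}

.evaluate_split <- function(model, planes, truth_all, w, batch_size = 64L) {
  n <- length(planes)
  losses <- mapes <- coss <- accs <- numeric(0)
  for (start in seq(1, n, by = batch_size)) {
    bi <- start:min(start + batch_size - 1, n)
    fw <- .net_forward(model, planes[bi], train = FALSE)
    truth <- .batch_truth(truth_all, bi)
    hg <- .head_loss_grads(fw, truth, w)
    losses <- c(losses, rep(hg$loss, length(bi)))
    mapes <- c(mapes, 100 * abs(fw$mw - truth$mw) / truth$mw)
    coss <- c(coss, vapply(seq_along(bi), function(j) {
      .cosine_raw(fw$fp[j, ], truth$Yfp[j, ])
    }, numeric(1)))
    accs <- c(accs, as.numeric(
      max.col(fw$class_probs, ties.method = "first") == truth$class
    ))
  }
  list(loss = mean(losses), mape = mean(mapes),
       cosine = mean(coss), accuracy = mean(accs))
}

#' @export
print.hsqc_fit <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  cat(sprintf(
    "<hsqc_fit> %d epochs; final loss %.4f, val loss %.4f, val MAPE %.2f%%, val cosine %.4f\n",
    nrow(x$history), h$loss, h$val_loss, h$val_mape, h$val_cosine
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname train_model
#' @param x an `hsqc_fit`.
#' @export
tidy.hsqc_fit <- function(x, ...) x$history

#' @rdname train_model
#' @export
glance.hsqc_fit <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  tibble(
    epochs = nrow(x$history), final_loss = h$loss,
    final_val_loss = h$val_loss, final_val_mape = h$val_mape,
    final_val_cosine = h$val_cosine, final_val_accuracy = h$val_accuracy,
    n_val = length(x$val_idx)
  )
}

#' Predict chemical properties from an HSQC image
#'
#' Inference is deterministic: dropout is off and batch normalization uses
#' its running statistics, so the same image always yields the same
#' prediction.
#'
#' @param object an `hsqc_model`.
#' @param image an `hsqc_image` (or 128 x 128 x C array), or a list of
#'   them for batched prediction.
#' @param ... unused.
#' @return an `hsqc_prediction` — list with `fingerprint` (probability
#'   [new_fingerprint()]), `class_probs` (simplex over K, named by the
#'   vocabulary when available), `mw` (> 0), `glycoside_prob` — or a list
#'   of them.
#' @export
predict.hsqc_model <- function(object, image, ...) {
  single <- !is.list(image) || inherits(image, "hsqc_image")
  imgs <- if (single) list(image) else image
  planes <- lapply(imgs, .image_planes, cfg = object$cfg)
  out <- vector("list", length(planes))
  for (start in seq(1, length(planes), by = 64)) {
    bi <- start:min(start + 63, length(planes))
    fw <- .net_forward(object, planes[bi], train = FALSE)
    for (j in seq_along(bi)) {
      cp <- fw$class_probs[j, ]
      if (!is.null(object$vocabulary)) {
        names(cp) <- as.character(object$vocabulary)
      }
      out[[bi[j]]] <- structure(
        list(
          fingerprint = new_fingerprint(fw$fp[j, ], "probability"),
          class_probs = cp,
          mw = fw$mw[j],
          glycoside_prob = fw$gly[j]
        ),
        class = "hsqc_prediction"
      )
    }
  }
  if (single) out[[1]] else out
}

#' @export
print.hsqc_prediction <- function(x, ...) {
  top <- which.max(x$class_probs)
  cat(sprintf(
    "<hsqc_prediction> MW %.1f Da, class %s (p=%.3f), P(glycoside)=%.3f, fp sum %.1f\n",
    x$mw,
    if (!is.null(names(x$class_probs))) names(x$class_probs)[top] else top,
    x$class_probs[top], x$glycoside_prob, sum(x$fingerprint)
  ))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is self-describing: it carries the weights, the full
#' architecture config, the class vocabulary and the spectrum bounds.
#'
#' @param model an `hsqc_model`.
#' @param path file path (`.rds`).
#' @return `path` (save) or the model (load).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "hsqc_model"))
  m
}
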