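# Optimizers and the training loop. The loss is mean squared error between
# the four sigmoid outputs and the target corners normalized to [0, 1] --
# the simplest regression loss consistent with a 4-neuron box head.

adam_defaults <- list(beta1 = 0.9, beta2 = 0.999, eps = 1e-8)

optimizer_init <- function(tc, params) {
  if (tc$optimizer == "adam")
    list(m = tree_zero(params), v = tree_zero(params), t = 0L)
  else
    list(vel = tree_zero(params))
}

optimizer_step <- function(tc, params, grads, state, lr) {
  # decoupled-from-loss L2: weight decay enters through the gradient
  if (tc$weight_decay > 0)
    grads <- tree_map(function(g, p) g + tc$weight_decay * p, grads, params)
  if (tc$optimizer == "adam") {
    b1 <- adam_defaults$beta1; b2 <- adam_defaults$beta2
    state$t <- state$t + 1L
    state$m <- tree_map(function(m, g) b1 * m + (1 - b1) * g, state$m, grads)
    state$v <- tree_map(function(v, g) b2 * v + (1 - b2) * g^2, state$v, grads)
    c1 <- 1 - b1^state$t
    c2 <- 1 - b2^state$t
    params <- tree_map(function(p, m, v)
      p - lr * (m / c1) / (sqrt(v / c2) + adam_defaults$eps),
      params, state$m, state$v)
  } else {
    state$vel <- tree_map(function(v, g) tc$momentum * v - lr * g,
                          state$vel, grads)
    params <- tree_map(`+`, params, state$vel)
  }
  list(params = params, state = state)
}

epoch_lr <- function(tc, epoch) {
  if (tc$lr_schedule == "constant") return(tc$learning_rate)
  tc$learning_rate * (1 - (epoch - 1) / tc$epochs)
}

# Resolve (image, target box) pairs from fundus_samples or bare lists.
detection_pairs <- function(samples, structure) {
  lapply(samples, function(sm) {
    if (inherits(sm, "fundus_sample")) {
      box <- if (structure == "od") sm$od_box else sm$oc_box
      list(image = sm$image, box = as_bbox(box))
    } else if (is.list(sm) && !is.null(sm$image) && !is.null(sm$box)) {
      list(image = sm$image, box = as_bbox(sm$box))
    } else {
      stop("each sample must be a fundus_sample or a list(image=, box=)",
           call. = FALSE)
    }
  })
}

# Mirroring a square image is a fixed permutation of the patch matrix:
# the patch-grid order reverses along one axis (row permutation) and the
# within-patch flatten order (channel fastest, then x, then y) reverses the
# matching coordinate (column permutation). Targets flip in [0,1] space.
flip_permutations <- function(config) {
  g <- config$image_size %/% config$patch_size
  p <- config$patch_size
  grid <- matrix(seq_len(g * g), g, g, byrow = TRUE)  # [gy, gx] -> patch row
  elem <- array(seq_len(3 * p * p), c(3, p, p))       # [c, x, y] -> column
  list(
    h = list(rows = as.vector(t(grid[, g:1])),
             cols = as.vector(elem[, p:1, ])),
    v = list(rows = as.vector(t(grid[g:1, ])),
             cols = as.vector(elem[, , p:1])))
}

flip_target_h <- function(t) c(1 - t[3], t[2], 1 - t[1], t[4])
flip_target_v <- function(t) c(t[1], 1 - t[4], t[3], 1 - t[2])

# Core loop shared by train_vit() and fine_tune_vit().
vit_fit <- function(params, patch_list, targets, config, tc, verbose = FALSE) {
  n <- length(patch_list)
  state <- optimizer_init(tc, params)
  perms <- if (tc$augment_flips) flip_permutations(config)
  history <- data.frame(epoch = integer(0), loss = numeric(0), lr = numeric(0))
  for (epoch in seq_len(tc$epochs)) {
    lr <- epoch_lr(tc, epoch)
    order_idx <- sample.int(n)
    epoch_loss <- 0
    for (start in seq(1, n, by = tc$batch_size)) {
      idx <- order_idx[start:min(start + tc$batch_size - 1, n)]
      grads <- NULL
      for (i in idx) {
        x <- patch_list[[i]]
        t_i <- targets[i, ]
        if (tc$augment_flips) {
          if (stats::runif(1) < 0.5) {
            x <- x[perms$h$rows, perms$h$cols]
            t_i <- flip_target_h(t_i)
          }
          if (stats::runif(1) < 0.5) {
            x <- x[perms$v$rows, perms$v$cols]
            t_i <- flip_target_v(t_i)
          }
        }
        fw <- vit_forward(params, config, x, train = TRUE)
        err <- fw$out - t_i
        epoch_loss <- epoch_loss + mean(err^2)
        g <- vit_backward(params, config, fw$cache, 2 * err / 4)
        grads <- if (is.null(grads)) g else tree_add(grads, g)
      }
      grads <- tree_scale(grads, 1 / length(idx))
      upd <- optimizer_step(tc, params, grads, state, lr)
      params <- upd$params
      state <- upd$state
    }
    history <- rbind(history, data.frame(epoch = epoch, loss = epoch_loss / n,
                                         lr = lr))
    if (verbose && (epoch %% 10 == 0 || epoch == 1))
      message(sprintf("epoch %4d  loss %.6f  lr %.5f",
                      epoch, epoch_loss / n, lr))
  }
  list(params = params, history = history)
}

#' Train a ViT bounding-box detector
#'
#' Trains one detector for one anatomical structure (optic disc or optic
#' cup; the pipeline uses two parallel single-object models). Images are
#' standardized per channel and cut into patches once up front; targets are
#' box corners normalized by the image side. Optimization follows the
#' configured protocol (Adam by default, weight decay 1e-4, linear
#' learning-rate decay); all randomness -- initialization, shuffling,
#' dropout -- derives from `tc$seed`, so a rerun with the same inputs gives
#' an identical loss history.
#'
#' @param samples list of `fundus_sample` objects (the box for `structure`
#'   is used) or of `list(image =, box =)` pairs. Images must already be at
#'   `config$image_size` (use [preprocess()] otherwise).
#' @param config a [vit_config()].
#' @param tc a [train_config()].
#' @param structure `"od"` or `"oc"`; which box to regress when samples are
#'   `fundus_sample`s.
#' @param log_file optional path; the per-epoch log (`epoch,loss,lr`) is
#'   written there as CSV.
#' @param verbose print progress every 10 epochs.
#' @return An object of class `"vit_detector"`: `params`, `config`,
#'   `train_config`, `structure` and the per-epoch `history` data frame.
#' @seealso [fine_tune_vit()], [predict_box()], [save_vit_model()]
#' @export
train_vit <- function(samples, config, tc, structure = c("od", "oc"),
                      log_file = NULL, verbose = FALSE) {
  structure_name <- match.arg(structure)
  stopifnot(inherits(config, "vit_config"), inherits(tc, "train_config"))
  if (length(samples) == 0) stop("empty training set", call. = FALSE)
  pairs <- detection_pairs(samples, structure_name)
  for (p in pairs) {
    d <- dim(p$image)
    if (d[1] != config$image_size || d[2] != config$image_size)
      stop("sample image is ", d[1], "x", d[2], " but the config expects ",
           config$image_size, "; preprocess() first", call. = FALSE)
  }
  patch_list <- lapply(pairs, function(p) vit_prepare(p$image, config))
  targets <- do.call(rbind, lapply(pairs, function(p)
    as.numeric(p$box) / config$image_size))
  fit <- with_seed(tc$seed, {
    params <- vit_init(config)
    vit_fit(params, patch_list, targets, config, tc, verbose)
  })
  if (!is.null(log_file))
    utils::write.csv(fit$history, log_file, row.names = FALSE, quote = FALSE)
  base::structure(
    list(params = fit$params, config = config, train_config = tc,
         structure = structure_name, history = fit$history),
    class = "vit_detector")
}

#' Continue training a detector (fine-tuning protocol)
#'
#' Continues optimization of an existing model; the reference protocol
#' switches to SGD with momentum at batch size 8 for this phase, which is
#' the default `tc` here. Passing an Adam config triggers a warning but is
#' honored as given. The new epochs are appended to the model's history
#' with a `phase` marker.
#'
#' @param model a `"vit_detector"` from [train_vit()].
#' @param samples as in [train_vit()].
#' @param tc a [train_config()]; default SGD+momentum, batch 8, 10 epochs,
#'   learning rate 1e-4.
#' @param verbose print progress.
#' @return The updated `"vit_detector"`.
#' @export
fine_tune_vit <- function(model, samples,
                          tc = train_config(optimizer = "sgd_momentum",
                                            learning_rate = 1e-4,
                                            batch_size = 8, epochs = 10),
                          verbose = FALSE) {
  stopifnot(inherits(model, "vit_detector"), inherits(tc, "train_config"))
  if (length(samples) == 0) stop("empty fine-tuning set", call. = FALSE)
  if (tc$optimizer == "adam")
    warning("fine-tuning protocol expects SGD with momentum; honoring the ",
            "Adam config as given", call. = FALSE)
  config <- model$config
  pairs <- detection_pairs(samples, model$structure %||% "od")
  patch_list <- lapply(pairs, function(p) vit_prepare(p$image, config))
  targets <- do.call(rbind, lapply(pairs, function(p)
    as.numeric(p$box) / config$image_size))
  fit <- with_seed(tc$seed, {
    vit_fit(model$params, patch_list, targets, config, tc, verbose)
  })
  old <- model$history
  if (!is.null(old) && nrow(old)) {
    if (is.null(old$phase)) old$phase <- "train"
    new <- fit$history
    new$epoch <- new$epoch + max(old$epoch)
    new$phase <- "fine_tune"
    model$history <- rbind(old, new)
  } else {
    fit$history$phase <- "fine_tune"
    model$history <- fit$history
  }
  model$params <- fit$params
  model$fine_tune_config <- tc
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a
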