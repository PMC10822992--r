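#' Cut an image into a sequence of flattened non-overlapping patches
#'
#' The square image is partitioned into `(S / patch_size)^2` patches,
#' ordered row-major over the patch grid (left to right, then top to
#' bottom). Each patch is flattened row-major with the channel index
#' fastest, giving `3 * patch_size^2` elements per row. The partition is
#' lossless: [reconstruct_patches()] inverts it exactly.
#'
#' @param image numeric array `S x S x 3`; `S` must be divisible by
#'   `patch_size`.
#' @param patch_size patch side in pixels.
#' @return Matrix `N x D` with `N = (S / patch_size)^2` and
#'   `D = 3 * patch_size^2`.
#' @examples
#' img <- array(stats::runif(224 * 224 * 3), c(224, 224, 3))
#' p <- extract_patches(img, 32)
#' dim(p)  # 49 x 3072
#' @export
extract_patches <- function(image, patch_size) {
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3)
    stop("extract_patches() needs an S x S x 3 array", call. = FALSE)
  if (d[1] != d[2]) stop("image must be square", call. = FALSE)
  s <- d[1]
  if (s %% patch_size != 0)
    stop("image side ", s, " is not divisible by patch size ", patch_size,
         call. = FALSE)
  g <- s %/% patch_size
  out <- matrix(0, g * g, 3 * patch_size^2)
  k <- 0
  for (gy in seq_len(g)) {
    ys <- ((gy - 1) * patch_size + 1):(gy * patch_size)
    for (gx in seq_len(g)) {
      xs <- ((gx - 1) * patch_size + 1):(gx * patch_size)
      k <- k + 1
      out[k, ] <- as.vector(aperm(image[ys, xs, , drop = FALSE], c(3, 2, 1)))
    }
  }
  out
}

#' @rdname extract_patches
#' @param patches matrix as returned by `extract_patches()`.
#' @param image_size side of the original image.
#' @export
reconstruct_patches <- function(patches, image_size, patch_size) {
  g <- image_size %/% patch_size
  stopifnot(nrow(patches) == g * g, ncol(patches) == 3 * patch_size^2)
  img <- array(0, c(image_size, image_size, 3))
  k <- 0
  for (gy in seq_len(g)) {
    ys <- ((gy - 1) * patch_size + 1):(gy * patch_size)
    for (gx in seq_len(g)) {
      xs <- ((gx - 1) * patch_size + 1):(gx * patch_size)
      k <- k + 1
      img[ys, xs, ] <- aperm(array(patches[k, ], c(3, patch_size, patch_size)),
                             c(3, 2, 1))
    }
  }
  img
}

#' Project patches and add learned positional embeddings
#'
#' `E = patches %*% W + b + pos`: each flattened patch is linearly projected
#' to the working dimension and a per-position embedding (indexed by the
#' patch's place in the grid order) is added, so identical patches at
#' different positions get distinct tokens.
#'
#' @param patches `N x D` matrix from [extract_patches()].
#' @param W projection matrix `D x projection_dim`.
#' @param b projection bias, length `projection_dim`.
#' @param pos positional table `N x projection_dim`.
#' @return `N x projection_dim` embedding matrix.
#' @export
encode_patches <- function(patches, W, b, pos) {
  if (ncol(patches) != nrow(W))
    stop("patch width ", ncol(patches), " does not match projection input ",
         nrow(W), call. = FALSE)
  if (!all(dim(pos) == c(nrow(patches), ncol(W))))
    stop("positional table must be ", nrow(patches), " x ", ncol(W),
         call. = FALSE)
  patches %*% W + matrix(b, nrow(patches), ncol(W), byrow = TRUE) + pos
}

glorot_uniform <- function(fan_in, fan_out) {
  l <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -l, l), fan_in, fan_out)
}

# Fresh parameter tree drawn from the current RNG stream.
vit_init <- function(config) {
  d <- config$projection_dim
  hidden <- config$transformer_units[1]
  blocks <- lapply(seq_len(config$transformer_layers), function(i) {
    list(ln1 = list(g = rep(1, d), b = rep(0, d)),
         attn = list(Wq = glorot_uniform(d, d), bq = rep(0, d),
                     Wk = glorot_uniform(d, d), bk = rep(0, d),
                     Wv = glorot_uniform(d, d), bv = rep(0, d),
                     Wo = glorot_uniform(d, d), bo = rep(0, d)),
         ln2 = list(g = rep(1, d), b = rep(0, d)),
         mlp = list(W1 = glorot_uniform(d, hidden), b1 = rep(0, hidden),
                    W2 = glorot_uniform(hidden, d), b2 = rep(0, d)))
  })
  dims <- c(config$num_patches * d, config$mlp_head_units, 4L)
  head <- lapply(seq_len(length(dims) - 1), function(i) {
    list(W = glorot_uniform(dims[i], dims[i + 1]), b = rep(0, dims[i + 1]))
  })
  list(proj = list(W = glorot_uniform(config$patch_elements, d), b = rep(0, d)),
       pos = matrix(stats::runif(config$num_patches * d, -0.05, 0.05),
                    config$num_patches, d),
       blocks = blocks,
       ln_out = list(g = rep(1, d), b = rep(0, d)),
       head = head)
}

# Full forward pass on one patch matrix; caches everything when training.
vit_forward <- function(params, config, patches, train = FALSE) {
  E <- encode_patches(patches, params$proj$W, params$proj$b, params$pos)
  blocks_cache <- vector("list", config$transformer_layers)
  for (l in seq_len(config$transformer_layers)) {
    bf <- block_forward(E, params$blocks[[l]], config$num_heads,
                        config$attention_dropout, config$mlp_dropout, train)
    E <- bf$out
    blocks_cache[[l]] <- bf$cache
  }
  lo <- ln_forward(E, params$ln_out$g, params$ln_out$b)
  f <- as.vector(lo$out)
  rep_mask <- drop_mask(length(f), config$representation_dropout, train)
  h <- f * rep_mask
  n_head <- length(params$head)
  head_cache <- vector("list", n_head)
  for (i in seq_len(n_head)) {
    hp <- params$head[[i]]
    z <- as.vector(h %*% hp$W) + hp$b
    if (i < n_head) {
      a <- gelu(z)
      m <- drop_mask(length(a), config$mlp_dropout, train)
      head_cache[[i]] <- list(input = h, z = z, mask = m)
      h <- a * m
    } else {
      head_cache[[i]] <- list(input = h, z = z)
      h <- z
    }
  }
  out <- sigmoid(h)
  list(out = out,
       cache = list(patches = patches, ln_out = lo, blocks = blocks_cache,
                    rep_mask = rep_mask, flat = f, head = head_cache,
                    logits = h, out = out))
}

# Backward pass from d(loss)/d(out); returns a gradient tree shaped like
# the parameter tree.
vit_backward <- function(params, config, cache, dout) {
  dz <- dout * cache$out * (1 - cache$out)
  n_head <- length(params$head)
  head_grads <- vector("list", n_head)
  for (i in rev(seq_len(n_head))) {
    hc <- cache$head[[i]]
    if (i < n_head) dz <- dz * hc$mask * gelu_grad(hc$z)
    head_grads[[i]] <- list(W = outer(hc$input, dz), b = dz)
    dz <- as.vector(params$head[[i]]$W %*% dz)
  }
  dflat <- dz * cache$rep_mask
  dH <- matrix(dflat, config$num_patches, config$projection_dim)
  lb <- ln_backward(dH, cache$ln_out, params$ln_out$g)
  dE <- lb$dx
  block_grads <- vector("list", config$transformer_layers)
  for (l in rev(seq_len(config$transformer_layers))) {
    bb <- block_backward(dE, cache$blocks[[l]], params$blocks[[l]],
                         config$num_heads)
    dE <- bb$dx
    block_grads[[l]] <- bb$grads
  }
  list(proj = list(W = t(cache$patches) %*% dE, b = colSums(dE)),
       pos = dE,
       blocks = block_grads,
       ln_out = list(g = lb$dg, b = lb$db),
       head = head_grads)
}

# Standardize a raw [0,1] image and cut it into patches for the network.
vit_prepare <- function(image, config) {
  d <- dim(image)
  if (is.null(d) || length(d) != 3 || d[3] != 3)
    stop("detector input must be an H x W x 3 array", call. = FALSE)
  image <- preprocess(image, size = config$image_size, normalize = TRUE)
  extract_patches(image, config$patch_size)
}

#' Predict a bounding box for one image
#'
#' Runs the detector forward (no dropout), reads the four sigmoid outputs as
#' `(x_min, y_min, x_max, y_max)` fractions of the image side, enforces
#' `min <= max` on each axis by sorting the pair, and rescales to pixel
#' coordinates of the original image. Images not already at the model's
#' input size are preprocessed (square resize + per-channel normalization)
#' first; box coordinates always refer to the image as passed in.
#'
#' @param image numeric `H x W x 3` array with intensities in `[0, 1]`.
#' @param model a `"vit_detector"` from [train_vit()] or [load_vit_model()].
#' @return A `bbox` in pixel coordinates of `image`.
#' @export
predict_box <- function(image, model) {
  if (!inherits(model, "vit_detector"))
    stop("model must be a 'vit_detector' (train_vit()/load_vit_model())",
         call. = FALSE)
  d <- dim(image)
  patches <- vit_prepare(image, model$config)
  out <- vit_forward(model$params, model$config, patches, train = FALSE)$out
  xs <- sort(c(out[1], out[3]))
  ys <- sort(c(out[2], out[4]))
  bbox(xs[1] * d[2], ys[1] * d[1], xs[2] * d[2], ys[2] * d[1])
}

#' Save / load a detector checkpoint
#'
#' Checkpoints are plain JSON (full numeric precision) embedding the model's
#' `vit_config`, so a checkpoint can never silently be used with a different
#' architecture: [load_vit_model()] rebuilds the config from the file and,
#' when `expected_config` is given, refuses to load on any mismatch.
#'
#' @param model a `"vit_detector"`.
#' @param path output/input JSON path.
#' @return `save_vit_model()`: `path` invisibly. `load_vit_model()`: the
#'   restored `"vit_detector"`.
#' @export
save_vit_model <- function(model, path) {
  stopifnot(inherits(model, "vit_detector"))
  payload <- list(
    format = "fundusvit_vit_checkpoint_v1",
    config = unclass(model$config),
    structure = model$structure,
    history = model$history,
    params = pack_params(model$params))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_vit_model
#' @param expected_config optional `vit_config` that the checkpoint must
#'   match exactly.
#' @export
load_vit_model <- function(path, expected_config = NULL) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(payload$format, "fundusvit_vit_checkpoint_v1"))
    stop("not a fundusvit ViT checkpoint: ", path, call. = FALSE)
  cf <- lapply(payload$config, unlist)
  config <- vit_config(image_size = cf$image_size, patch_size = cf$patch_size,
                       projection_dim = cf$projection_dim,
                       num_heads = cf$num_heads,
                       transformer_layers = cf$transformer_layers,
                       mlp_head_units = cf$mlp_head_units,
                       attention_dropout = cf$attention_dropout,
                       mlp_dropout = cf$mlp_dropout,
                       representation_dropout = cf$representation_dropout)
  if (!is.null(expected_config) && !identical(unclass(config),
                                              unclass(expected_config)))
    stop("checkpoint config does not match the expected config; refusing ",
         "to load", call. = FALSE)
  history <- NULL
  if (length(payload$history))
    history <- do.call(rbind, lapply(payload$history, as.data.frame))
  structure(list(params = unpack_params(payload$params),
                 config = config,
                 structure = unlist(payload$structure),
                 history = history,
                 train_config = NULL),
            class = "vit_detector")
}

# JSON-safe encoding of a parameter tree: each leaf becomes {dim, data}.
pack_params <- function(tree) {
  if (is.list(tree)) return(lapply(tree, pack_params))
  list(dim = if (is.null(dim(tree))) length(tree) else dim(tree),
       data = as.vector(tree))
}

unpack_params <- function(tree) {
  if (is.list(tree) && identical(sort(names(tree)), c("data", "dim"))) {
    dm <- as.integer(unlist(tree$dim))
    dat <- as.numeric(unlist(tree$data))
    if (length(dm) == 1) return(dat)
    return(array(dat, dm))
  }
  lapply(tree, unpack_params)
}

#' @export
print.vit_detector <- function(x, ...) {
  cat(sprintf("<vit_detector>%s  %dpx input, %d blocks, dim %d\n",
              if (!is.null(x$structure)) paste0(" [", x$structure, "]") else "",
              x$config$image_size, x$config$transformer_layers,
              x$config$projection_dim))
  if (!is.null(x$history) && nrow(x$history))
    cat(sprintf("  trained %d epochs, final loss %.6f\n",
                max(x$history$epoch), x$history$loss[nrow(x$history)]))
  invisible(x)
}
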