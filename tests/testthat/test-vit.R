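test_that("config derivation matches the patch arithmetic", {
  cfg <- vit_config()  # reference scale: 224 px, patch 32
  expect_identical(cfg$num_patches, 49L)
  expect_identical(cfg$patch_elements, 3072L)
  expect_identical(cfg$transformer_units, c(128L, 64L))
  cfg2 <- vit_config(image_size = 64, patch_size = 32)
  expect_identical(cfg2$num_patches, 4L)
  expect_error(vit_config(image_size = 224, patch_size = 30), "divisible")
  expect_error(vit_config(projection_dim = 30, num_heads = 4), "multiple")
})

test_that("patch extraction is a lossless partition", {
  set.seed(9)
  img <- array(stats::runif(48 * 48 * 3), c(48, 48, 3))
  p <- extract_patches(img, 16)
  expect_identical(dim(p), c(9L, 768L))
  expect_equal(sum(p), sum(img))  # conservation
  expect_equal(reconstruct_patches(p, 48, 16), img)
  expect_error(extract_patches(img, 13), "divisible")
  # patch-grid row order: second patch is the top row, second column block
  expect_equal(p[2, ],
               as.vector(aperm(img[1:16, 17:32, , drop = FALSE], c(3, 2, 1))))
})

test_that("patch encoding projects and injects position", {
  set.seed(10)
  patches <- matrix(stats::rnorm(4 * 12), 4, 12)
  W0 <- matrix(0, 12, 5)
  pos0 <- matrix(0, 4, 5)
  expect_equal(encode_patches(patches, W0, rep(0, 5), pos0),
               matrix(0, 4, 5))
  # identical patches, distinct positions -> distinct rows
  same <- matrix(rep(patches[1, ], 4), 4, byrow = TRUE)
  pos <- matrix(stats::rnorm(20), 4, 5)
  enc <- encode_patches(same, W0, rep(0, 5), pos)
  expect_equal(enc, pos)
  expect_gt(min(dist(enc)), 0)
  # one-hot projection selects a patch element
  Wsel <- matrix(0, 12, 5); Wsel[3, 2] <- 1
  enc2 <- encode_patches(patches, Wsel, rep(0, 5), pos0)
  expect_equal(enc2[, 2], patches[, 3])
  expect_equal(enc2[, -2], matrix(0, 4, 4))
  expect_error(encode_patches(patches, matrix(0, 11, 5), rep(0, 5), pos0),
               "does not match")
})

test_that("transformer block reduces to the identity when weights are zeroed", {
  set.seed(11)
  x <- matrix(stats::rnorm(6 * 8), 6, 8)
  expect_equal(transformer_block(x, zero_block_params(8), num_heads = 2), x)
})

test_that("transformer block is permutation-equivariant", {
  set.seed(12)
  for (rep in 1:5) {
    x <- matrix(stats::rnorm(5 * 8), 5, 8)
    bp <- random_block_params(8)
    perm <- sample(5)
    out <- transformer_block(x, bp, num_heads = 2)
    out_perm <- transformer_block(x[perm, ], bp, num_heads = 2)
    expect_equal(out_perm, out[perm, ], tolerance = 1e-10)
  }
})

test_that("single-head attention matches a brute-force softmax oracle", {
  set.seed(13)
  x <- matrix(stats::rnorm(3 * 4), 3, 4)
  ap <- random_block_params(4)$attn
  got <- fundusvit:::mha_forward(x, ap, num_heads = 1)$out
  # explicit loops, no shared code with the implementation
  Q <- x %*% ap$Wq + matrix(ap$bq, 3, 4, byrow = TRUE)
  K <- x %*% ap$Wk + matrix(ap$bk, 3, 4, byrow = TRUE)
  V <- x %*% ap$Wv + matrix(ap$bv, 3, 4, byrow = TRUE)
  O <- matrix(0, 3, 4)
  for (i in 1:3) {
    s <- numeric(3)
    for (j in 1:3) s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(4)
    w <- exp(s) / sum(exp(s))
    for (j in 1:3) O[i, ] <- O[i, ] + w[j] * V[j, ]
  }
  want <- O %*% ap$Wo + matrix(ap$bo, 3, 4, byrow = TRUE)
  expect_equal(got, want, tolerance = 1e-12)
  # zero query/key weights -> uniform attention -> rows average V
  ap0 <- ap
  ap0$Wq[] <- 0; ap0$bq[] <- 0; ap0$Wk[] <- 0; ap0$bk[] <- 0
  ap0$Wo <- diag(4); ap0$bo[] <- 0
  unif <- fundusvit:::mha_forward(x, ap0, num_heads = 1)$out
  expect_equal(unif, matrix(colMeans(V), 3, 4, byrow = TRUE),
               tolerance = 1e-12)
  expect_error(fundusvit:::mha_forward(x, ap, num_heads = 3), "divide")
})

test_that("backpropagation matches finite differences", {
  cfg <- vit_config(image_size = 8, patch_size = 4, projection_dim = 8,
                    num_heads = 2, transformer_layers = 1,
                    mlp_head_units = c(6), attention_dropout = 0,
                    mlp_dropout = 0, representation_dropout = 0)
  set.seed(42)
  params <- fundusvit:::vit_init(cfg)
  img <- array(stats::runif(8 * 8 * 3), c(8, 8, 3))
  patches <- fundusvit:::vit_prepare(img, cfg)
  target <- c(0.2, 0.3, 0.7, 0.8)
  loss_fn <- function(p)
    mean((fundusvit:::vit_forward(p, cfg, patches)$out - target)^2)
  fw <- fundusvit:::vit_forward(params, cfg, patches, train = TRUE)
  grads <- fundusvit:::vit_backward(params, cfg, fw$cache,
                                    2 * (fw$out - target) / 4)
  get_leaf <- function(tree, path) {
    for (k in path) tree <- tree[[k]]
    tree
  }
  set_leaf <- function(tree, path, val) {
    if (length(path) == 1) { tree[[path[[1]]]] <- val; return(tree) }
    tree[[path[[1]]]] <- set_leaf(tree[[path[[1]]]], path[-1], val)
    tree
  }
  paths <- list(c("proj", "W"), "pos", list("blocks", 1, "attn", "Wq"),
                list("blocks", 1, "attn", "Wo"), list("blocks", 1, "ln1", "g"),
                list("blocks", 1, "mlp", "W1"), c("ln_out", "g"),
                c("head", 1, "W"), c("head", 2, "b"))
  eps <- 1e-6
  for (pth in paths) {
    pth <- as.list(pth)
    leaf <- get_leaf(params, pth)
    g_an <- get_leaf(grads, pth)
    for (j in sample(length(leaf), min(3, length(leaf)))) {
      lp <- leaf; lp[j] <- lp[j] + eps
      lm <- leaf; lm[j] <- lm[j] - eps
      g_num <- (loss_fn(set_leaf(params, pth, lp)) -
                  loss_fn(set_leaf(params, pth, lm))) / (2 * eps)
      expect_lt(abs(g_num - g_an[j]) / max(abs(g_num), abs(g_an[j]), 1e-8),
                1e-4)
    }
  }
})

test_that("training overfits a single sample and is seed-deterministic", {
  cfg <- tiny_vit_config(projection_dim = 16, mlp_head_units = c(16))
  ds <- generate_fundus_dataset(tiny_synth_config(), n = 1, seed = 5)
  tc <- train_config(epochs = 300, batch_size = 1, weight_decay = 0, seed = 2)
  m1 <- train_vit(ds$samples, cfg, tc, structure = "od")
  expect_lt(utils::tail(m1$history$loss, 1), 1e-3)
  m2 <- train_vit(ds$samples, cfg, tc, structure = "od")
  expect_identical(m1$history, m2$history)
  expect_equal(m1$params, m2$params)
  expect_error(train_vit(list(), cfg, tc), "empty")
})

test_that("smoothed loss history is non-increasing on separable data", {
  cfg <- tiny_vit_config(image_size = 32, patch_size = 16,
                         projection_dim = 16, mlp_head_units = c(16))
  ds <- generate_fundus_dataset(tiny_synth_config(image_size = 32),
                                n = 30, seed = 6)
  tc <- train_config(epochs = 60, batch_size = 8, seed = 3)
  m <- train_vit(ds$samples, cfg, tc, structure = "od")
  smooth <- stats::filter(m$history$loss, rep(1 / 10, 10), sides = 1)
  smooth <- smooth[!is.na(smooth)]
  expect_true(all(diff(smooth) <= 1e-4))
})

test_that("predict_box enforces corner ordering and pixel scaling", {
  cfg <- tiny_vit_config()
  set.seed(20)
  params <- fundusvit:::vit_init(cfg)
  # force the final layer to emit fixed logits
  nh <- length(params$head)
  params$head[[nh]]$W[] <- 0
  model <- structure(list(params = params, config = cfg, structure = "od",
                          history = NULL),
                     class = "vit_detector")
  img <- array(stats::runif(16 * 16 * 3), c(16, 16, 3))
  # sigmoid(large) ~ 1, sigmoid(-large) ~ 0 -> full-image box
  model$params$head[[nh]]$b <- c(-30, -30, 30, 30)
  full <- predict_box(img, model)
  expect_equal(as.numeric(full), c(0, 0, 16, 16), tolerance = 1e-9)
  # out-of-order pair (0.5, .5, .25, .75): x pair is sorted
  model$params$head[[nh]]$b <- stats::qlogis(c(0.5, 0.5, 0.25, 0.75))
  b <- predict_box(img, model)
  expect_equal(as.numeric(b), c(0.25 * 16, 0.5 * 16, 0.5 * 16, 0.75 * 16),
               tolerance = 1e-9)
  expect_error(predict_box(img, "not a model"), "vit_detector")
})

test_that("fine-tuning honours its protocol and a zero learning rate", {
  cfg <- tiny_vit_config(projection_dim = 16, mlp_head_units = c(16))
  ds <- generate_fundus_dataset(tiny_synth_config(), n = 6, seed = 8)
  tc <- train_config(epochs = 20, batch_size = 2, seed = 4)
  m <- train_vit(ds$samples, cfg, tc, structure = "od")
  # learning rate ~0 leaves parameters unchanged
  frozen <- fine_tune_vit(m, ds$samples,
                          tc = train_config(optimizer = "sgd_momentum",
                                            learning_rate = 1e-30,
                                            weight_decay = 0,
                                            batch_size = 8, epochs = 3))
  expect_equal(frozen$params, m$params, tolerance = 1e-12)
  expect_identical(unique(frozen$history$phase), c("train", "fine_tune"))
  # adam in the fine-tune slot warns but is honoured
  expect_warning(
    fine_tune_vit(m, ds$samples,
                  tc = train_config(optimizer = "adam", epochs = 1,
                                    batch_size = 8)),
    "SGD")
})

test_that("checkpoints round-trip and refuse a mismatched config", {
  cfg <- tiny_vit_config(projection_dim = 16, mlp_head_units = c(16))
  ds <- generate_fundus_dataset(tiny_synth_config(), n = 2, seed = 9)
  m <- train_vit(ds$samples, cfg,
                 train_config(epochs = 3, batch_size = 2, seed = 1),
                 structure = "oc")
  path <- withr::local_tempfile(fileext = ".json")
  save_vit_model(m, path)
  m2 <- load_vit_model(path)
  expect_equal(m2$params, m$params, tolerance = 1e-14)
  expect_identical(m2$structure, "oc")
  expect_identical(unclass(m2$config), unclass(m$config))
  img <- ds$samples[[1]]$image
  expect_equal(as.numeric(predict_box(img, m2)),
               as.numeric(predict_box(img, m)), tolerance = 1e-12)
  expect_error(load_vit_model(path, expected_config = tiny_vit_config(
    projection_dim = 8)), "refusing")
  junk <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(a = 1), junk)
  expect_error(load_vit_model(junk), "checkpoint")
})

test_that("preprocess forces a square output and normalizes channels", {
  set.seed(30)
  img <- array(stats::runif(30 * 20 * 3), c(30, 20, 3))
  out <- preprocess(img, size = 24)
  expect_identical(dim(out), c(24L, 24L, 3L))
  for (ch in 1:3) {
    expect_lt(abs(mean(out[, , ch])), 1e-10)
    expect_equal(stats::sd(out[, , ch]), 1, tolerance = 1e-8)
  }
  # constant image maps to all zeros (mean subtraction, no sd blow-up)
  const <- array(0.37, c(24, 24, 3))
  expect_equal(preprocess(const, size = 24), array(0, c(24, 24, 3)))
  # 2:1 input still becomes square: aspect is not preserved
  wide <- array(stats::runif(10 * 20 * 3), c(10, 20, 3))
  expect_identical(dim(preprocess(wide, size = 16)), c(16L, 16L, 3L))
  expect_error(preprocess(matrix(0, 5, 5)), "RGB")
})
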