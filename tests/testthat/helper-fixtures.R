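# Shared fixtures: all built in code at test time.

# Random valid boxes inside a grid_size x grid_size canvas.
random_boxes <- function(n, grid_size = 100, integer_coords = FALSE) {
  draw <- function() {
    xs <- sort(stats::runif(2, 0, grid_size))
    ys <- sort(stats::runif(2, 0, grid_size))
    if (integer_coords) {
      xs <- sort(sample(0:grid_size, 2, replace = TRUE))
      ys <- sort(sample(0:grid_size, 2, replace = TRUE))
    }
    bbox(xs[1], ys[1], xs[2], ys[2])
  }
  lapply(seq_len(n), function(i) draw())
}

# Tiny deterministic ViT config for fast structural tests (dropout off).
tiny_vit_config <- function(...) {
  defaults <- list(image_size = 16, patch_size = 8, projection_dim = 8,
                   num_heads = 2, transformer_layers = 1,
                   mlp_head_units = c(8),
                   attention_dropout = 0, mlp_dropout = 0,
                   representation_dropout = 0)
  do.call(vit_config, utils::modifyList(defaults, list(...)))
}

tiny_synth_config <- function(...) {
  defaults <- list(image_size = 16, vessel_count = 1, noise_sd = 0.02)
  do.call(synthetic_config, utils::modifyList(defaults, list(...)))
}

# Zeroed transformer-block parameters (LN gains 1, everything else 0):
# both residual branches contribute nothing.
zero_block_params <- function(d, hidden = 2 * d) {
  z <- function(r, c) matrix(0, r, c)
  list(ln1 = list(g = rep(1, d), b = rep(0, d)),
       attn = list(Wq = z(d, d), bq = rep(0, d), Wk = z(d, d), bk = rep(0, d),
                   Wv = z(d, d), bv = rep(0, d), Wo = z(d, d), bo = rep(0, d)),
       ln2 = list(g = rep(1, d), b = rep(0, d)),
       mlp = list(W1 = z(d, hidden), b1 = rep(0, hidden),
                  W2 = z(hidden, d), b2 = rep(0, d)))
}

# Random block parameters drawn from the current RNG.
random_block_params <- function(d, hidden = 2 * d, scale = 0.3) {
  r <- function(rr, cc) matrix(stats::rnorm(rr * cc, sd = scale), rr, cc)
  list(ln1 = list(g = stats::runif(d, 0.5, 1.5), b = stats::rnorm(d, sd = 0.1)),
       attn = list(Wq = r(d, d), bq = stats::rnorm(d, sd = 0.1),
                   Wk = r(d, d), bk = stats::rnorm(d, sd = 0.1),
                   Wv = r(d, d), bv = stats::rnorm(d, sd = 0.1),
                   Wo = r(d, d), bo = stats::rnorm(d, sd = 0.1)),
       ln2 = list(g = stats::runif(d, 0.5, 1.5), b = stats::rnorm(d, sd = 0.1)),
       mlp = list(W1 = r(d, hidden), b1 = stats::rnorm(hidden, sd = 0.1),
                  W2 = r(hidden, d), b2 = stats::rnorm(d, sd = 0.1)))
}
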