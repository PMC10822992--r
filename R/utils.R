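# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's
# random-number state afterwards. All package randomness funnels through
# this so no function perturbs global state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

# Recursively apply f over the numeric leaves of parallel nested lists with
# identical shape (parameter trees, gradient trees, optimizer state).
tree_map <- function(f, ...) {
  trees <- list(...)
  first <- trees[[1]]
  if (is.list(first)) {
    out <- vector("list", length(first))
    names(out) <- names(first)
    for (i in seq_along(first))
      out[[i]] <- do.call(tree_map, c(list(f), lapply(trees, `[[`, i)))
    out
  } else {
    do.call(f, trees)
  }
}

tree_zero <- function(tree) tree_map(function(x) x * 0, tree)

tree_add <- function(a, b) tree_map(`+`, a, b)

tree_scale <- function(tree, k) tree_map(function(x) x * k, tree)
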