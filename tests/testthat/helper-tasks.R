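# Task factories used across test files.

make_task <- function(x, y, w = 15, id = "t") {
  chain_task(id, anchors(x = x, y = y, w = w))
}

# Random task with unique (x, y) anchors, built directly from base RNG
# draws (independent of the package's planted-chain generator).
random_task <- function(n, seed, coord = 4000, w = 15, id = NULL) {
  if (is.null(id)) id <- sprintf("rnd%d", seed)
  set.seed(seed)
  lo <- w - 1L
  xy <- unique(cbind(sample(lo:coord, 2 * n, replace = TRUE),
                     sample(lo:coord, 2 * n, replace = TRUE)))
  xy <- xy[seq_len(min(n, nrow(xy))), , drop = FALSE]
  chain_task(id, anchors(x = xy[, 1], y = xy[, 2], w = w))
}

default_params <- function(...) chaining_params(...)

# The crafted three-anchor instance: exact chaining routes A0 -> A2 for a
# score of 30; with H = 1 only A1 is examined from A2, giving ~19.843.
crafted_three_anchor_task <- function() {
  make_task(x = c(100, 150, 200), y = c(100, 101, 200), w = 15, id = "craft3")
}
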