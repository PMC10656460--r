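# Chaining DP engines: hand-evaluated instances, the brute-force oracle,
# bounded-lookback behaviour and the sub-partitioned inner loop.

test_that("transition_score matches hand arithmetic and eligibility", {
  p <- chaining_params(gap_scale = 0.01)
  a <- function(x, y, w = 15) list(x = x, y = y, w = w)

  # colinear: d = 0, full span gain
  expect_equal(transition_score(a(100, 100), a(200, 200), p, 15), 15.0)

  # d = 10: beta = 0.01*15*10 + 0.5*log2(10)
  s <- transition_score(a(100, 100), a(130, 120), p, 15)
  expect_equal(s, 15 - (0.01 * 15 * 10 + 0.5 * log2(10)), tolerance = 1e-12)
  expect_equal(s, 11.839, tolerance = 1e-3)

  # eligibility predicate
  expect_identical(transition_score(a(100, 100), a(150, 100), p, 15), -Inf)
  expect_identical(transition_score(a(100, 100), a(100, 150), p, 15), -Inf)
  expect_identical(transition_score(a(100, 100), a(99, 120), p, 15), -Inf)
  p2 <- chaining_params(max_dist_x = 40)
  expect_identical(transition_score(a(100, 100), a(150, 150), p2, 15), -Inf)
  p3 <- chaining_params(bandwidth = 5)
  expect_identical(transition_score(a(100, 100), a(130, 120), p3, 15), -Inf)
})

test_that("chain_scores base cases and worked instances", {
  p <- chaining_params(H = Inf)
  expect_equal(chain_scores(make_task(integer(0), integer(0)), p)$f,
               numeric(0))

  one <- chain_scores(make_task(50, 50), p)
  expect_equal(one$f, 15)
  expect_identical(one$parent, NA_integer_)
  expect_identical(one$trip_count, 0L)

  two <- chain_scores(make_task(c(100, 200), c(100, 200)), p)
  expect_equal(two$f, c(15, 30))
  expect_identical(two$parent, c(NA_integer_, 1L))

  # crafted three-anchor task: exact goes through A0, H=1 is stuck on A1
  t3 <- crafted_three_anchor_task()
  exact <- chain_scores(t3, p)
  expect_equal(exact$f[3], 30)
  h1 <- chain_scores(t3, chaining_params(H = 1))
  expect_equal(h1$f, c(15, 15, 15 + 15 - (0.01 * 15 * 49 + 0.5 * log2(49))),
               tolerance = 1e-9)
  expect_equal(h1$f[3], 19.843, tolerance = 1e-3)
})

test_that("unbounded chain_scores equals the brute-force oracle", {
  p <- default_params(H = Inf)
  for (seed in 1:120) {
    t <- random_task(n = sample(2:128, 1), seed = seed)
    expect_identical(max(chain_scores(t, p)$f), brute_force_best_score(t, p),
                     label = sprintf("seed %d", seed))
  }
})

test_that("f is monotone in H and converges at H >= n-1", {
  p <- default_params()
  hs <- c(1, 4, 16, 64, 512)
  for (seed in c(5, 17, 31, 99)) {
    t <- random_task(n = 120, seed = seed, coord = 3000)
    exact <- chain_scores(t, chaining_params(H = Inf))
    prev <- NULL
    for (h in hs) {
      cur <- chain_scores(t, chaining_params(H = h))$f
      if (!is.null(prev)) {
        expect_true(all(cur >= prev - 1e-12),
                    label = sprintf("H %g >= previous (seed %d)", h, seed))
      }
      prev <- cur
    }
    conv <- chain_scores(t, chaining_params(H = 119))
    expect_identical(conv$f, exact$f)
    expect_identical(conv$parent, exact$parent)
    expect_identical(conv$trip_count, exact$trip_count)
  }
})

test_that("trip counts respect the lookback window", {
  t <- random_task(n = 90, seed = 8, coord = 2500)
  n <- nrow(t$anchors)
  for (h in c(1, 7, 64, Inf)) {
    dp <- chain_scores(t, chaining_params(H = h, max_dist_x = 800))
    i <- seq_len(n)
    expect_true(all(dp$trip_count <= pmin(i - 1, h)))
    expect_true(all(dp$f >= t$anchors$w))
    expect_true(all(is.na(dp$parent) | dp$parent < i))
  }
  # unbounded: trip_count is exactly the max_dist_x window width
  p <- chaining_params(H = Inf, max_dist_x = 800)
  dp <- chain_scores(t, p)
  x <- t$anchors$x
  st <- vapply(seq_len(n), function(i) {
    min(which(x[i] - x <= 800))             # linear-scan reference
  }, integer(1))
  expect_identical(dp$trip_count, pmax(0L, seq_len(n) - 1L - (st - 1L)))
})

test_that("sub-partitioned engine reproduces chain_scores for any P", {
  t <- random_task(n = 200, seed = 77, coord = 6000)
  for (H in c(16, 64)) {
    ref <- chain_scores(t, chaining_params(H = H))
    for (P in c(1, 2, 8, 64, 1024)) {
      sub <- chain_scores_subpartitioned(t, chaining_params(H = H, P = P))
      expect_identical(sub$f, ref$f, label = sprintf("f H=%d P=%d", H, P))
      expect_identical(sub$parent, ref$parent)
      expect_identical(sub$trip_count, ref$trip_count)
      expect_identical(sub$subparts, as.integer(ceiling(sub$trip_count / P)))
    }
  }
  expect_error(chain_scores_subpartitioned(t, chaining_params(H = Inf)),
               "finite H")
  empty <- chain_scores_subpartitioned(make_task(integer(0), integer(0)),
                                       chaining_params(H = 8))
  expect_identical(empty$subparts, integer(0))
})

test_that("backtracking extracts disjoint, filtered chains", {
  p <- chaining_params(H = Inf, min_score = 0, min_cnt = 1)

  # two colinear anchors -> one chain covering both
  t <- make_task(c(100, 200), c(100, 200))
  chains <- backtrack_chains(t, chain_scores(t, p), p)
  expect_length(chains, 1)
  expect_identical(chains[[1]]$anchor_indices, c(1L, 2L))
  expect_equal(chains[[1]]$score, 30)

  # min_score filter empties the output
  ph <- chaining_params(H = Inf, min_score = 1000, min_cnt = 1)
  expect_length(backtrack_chains(t, chain_scores(t, ph), ph), 0)

  # two planted, well-separated colinear chains -> two disjoint chains
  xa <- seq(100, 100 + 15 * 9, by = 15)
  t2 <- make_task(c(xa, xa + 30000), c(xa, xa + 40000), id = "two")
  dp2 <- chain_scores(t2, p)
  ch2 <- backtrack_chains(t2, dp2, p)
  expect_length(ch2, 2)
  idx <- sort(unlist(lapply(ch2, `[[`, "anchor_indices")))
  expect_identical(idx, seq_len(20))        # both plants fully recovered
  expect_equal(ch2[[1]]$n_anchors, 10)
  expect_equal(ch2[[2]]$n_anchors, 10)

  # property: disjointness + filters hold on random tasks
  pf <- chaining_params(H = Inf, min_score = 20, min_cnt = 2)
  for (seed in c(3, 14, 60)) {
    tr <- random_task(n = 100, seed = seed, coord = 3000)
    chains <- backtrack_chains(tr, chain_scores(tr, pf), pf)
    all_idx <- unlist(lapply(chains, `[[`, "anchor_indices"))
    expect_identical(anyDuplicated(all_idx), 0L)
    for (ch in chains) {
      expect_gte(ch$score, 20)
      expect_gte(ch$n_anchors, 2)
      expect_true(all(diff(ch$anchor_indices) > 0))
    }
    scores <- vapply(chains, `[[`, numeric(1), "score")
    expect_false(is.unsorted(rev(scores)))
  }
})
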