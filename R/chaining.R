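# Co-linear anchor chaining.
#
# The DP follows the chaining recurrence of minimizer-based long-read
# mappers: f[i] = max(w_i, max_j f[j] + alpha(j,i) - beta(j,i)) over
# eligible predecessors j < i, with
#   alpha = min(query advance, reference advance, w_i)
#   beta  = gap_scale * mean_span * d + 0.5 * log2(d),  beta(0) = 0
# where d = |query advance - reference advance|. Three engines share the
# recurrence: the exact DP (predecessor window bounded only by max_dist_x,
# located by binary search), the bounded-lookback DP that examines at most
# H predecessors per anchor (the fixed "maximum loop trip count" of a
# hardware pipeline), and a sub-partitioned variant that walks the same H
# candidates in slices of at most P, carrying a running maximum across
# slices -- the restructure that lets fixed-bound hardware loops reach
# large H without a proportional resource blow-up.

#' Chaining parameters
#'
#' @param max_dist_x maximum reference gap (bases) to a predecessor.
#' @param max_dist_y maximum query gap (bases) to a predecessor.
#' @param bandwidth ceiling on `|d|`, the difference between query and
#'   reference advances (bases).
#' @param gap_scale per-base gap cost factor (dimensionless).
#' @param H maximum inner-loop trip count: the number of predecessors
#'   examined per anchor. `Inf` means unbounded (exact chaining). The
#'   default 512 is the largest bound the sub-partitioned accelerator
#'   design reaches on mid-size FPGAs; 1024 is reachable on larger parts.
#' @param P sub-partition size: predecessors processed per slice of the
#'   restructured inner loop.
#' @param min_score minimum chain score to report from backtracking.
#' @param min_cnt minimum anchors per reported chain.
#' @return An object of class `chaining_params`.
#' @export
chaining_params <- function(max_dist_x = 5000, max_dist_y = 5000,
                            bandwidth = 500, gap_scale = 0.01,
                            H = 512, P = 64,
                            min_score = 40, min_cnt = 3) {
  if (!(length(H) == 1 && is.numeric(H) && !is.na(H) &&
        (is.infinite(H) || (H >= 1 && H == floor(H))))) {
    stop_field("H", "must be an integer >= 1 or Inf (unbounded)")
  }
  structure(list(
    max_dist_x = check_number(max_dist_x, "max_dist_x", min = 0),
    max_dist_y = check_number(max_dist_y, "max_dist_y", min = 0),
    bandwidth = check_number(bandwidth, "bandwidth", min = 0),
    gap_scale = check_number(gap_scale, "gap_scale", min = 0),
    H = as.numeric(H),
    P = check_count(P, "P", min = 1),
    min_score = check_number(min_score, "min_score"),
    min_cnt = check_count(min_cnt, "min_cnt", min = 1)
  ), class = "chaining_params")
}

task_mean_span <- function(task) {
  w <- task$anchors$w
  if (length(w) == 0) return(1L)
  max(1L, as.integer(round(mean(w))))
}

#' Score of chaining anchor `a_i` onto predecessor `a_j`
#'
#' Returns `-Inf` (ineligible) unless `a_j` strictly precedes `a_i` on both
#' axes within the gap and bandwidth ceilings; otherwise the gain
#' `alpha - beta` of extending a chain ending at `a_j` by `a_i`.
#'
#' @param a_j,a_i anchors as `list(x=, y=, w=)` or single-row data frames.
#' @param params a [chaining_params()].
#' @param mean_span mean anchor span of the task (bases), scales the
#'   linear part of the gap cost.
#' @return A numeric score, or `-Inf` when the pair is ineligible.
#' @examples
#' p <- chaining_params(gap_scale = 0.01)
#' transition_score(list(x = 100, y = 100, w = 15),
#'                  list(x = 200, y = 200, w = 15), p, mean_span = 15)
#' @export
transition_score <- function(a_j, a_i, params, mean_span) {
  dx <- a_i$x - a_j$x
  dy <- a_i$y - a_j$y
  if (dx <= 0 || dy <= 0 || dx > params$max_dist_x || dy > params$max_dist_y) {
    return(-Inf)
  }
  d <- abs(dy - dx)
  if (d > params$bandwidth) return(-Inf)
  alpha <- min(dy, dx, a_i$w)
  beta <- if (d == 0) 0 else params$gap_scale * mean_span * d + 0.5 * log2(d)
  alpha - beta
}

empty_dp_result <- function() {
  structure(list(f = numeric(0), parent = integer(0),
                 trip_count = integer(0), subparts = NULL,
                 mean_span = 1L),
            class = "dp_result")
}

# First eligible predecessor index per anchor: smallest st with
# x_i - x_st <= max_dist_x, found by binary search over the sorted x.
start_index <- function(x, max_dist_x) {
  findInterval(x - max_dist_x - 0.5, x) + 1L
}

#' Chaining scores by dynamic programming
#'
#' Computes per-anchor best chain scores `f`, best-predecessor pointers and
#' inner-loop trip counts. For each anchor `i` the candidate predecessors
#' are `j = i-1` down to `max(st_i, i - H)`, where `st_i` is the first
#' index within `max_dist_x` on the reference (binary search) and `H` is
#' the trip-count bound (`Inf` examines the whole window). Ties between
#' equally scoring predecessors keep the nearest one (first met scanning
#' `j` downward). `parent[i]` is `NA` when no predecessor improves on the
#' anchor's own span.
#'
#' @param task a [chain_task()].
#' @param params a [chaining_params()]; `params$H` selects bounded or
#'   unbounded lookback.
#' @return A `dp_result`: list with numeric `f`, integer `parent` (NA =
#'   chain start), integer `trip_count`, and `mean_span` used by the gap
#'   cost.
#' @examples
#' t <- chain_task("ex", anchors(x = c(100, 200), y = c(100, 200), w = 15))
#' chain_scores(t, chaining_params(H = Inf))$f
#' @export
chain_scores <- function(task, params) {
  a <- task$anchors
  n <- nrow(a)
  if (n == 0) return(empty_dp_result())
  x <- as.numeric(a$x); y <- as.numeric(a$y); w <- as.numeric(a$w)
  mean_span <- task_mean_span(task)
  H <- params$H
  st <- start_index(x, params$max_dist_x)
  f <- w
  parent <- rep(NA_integer_, n)
  trip <- integer(n)
  for (i in seq_len(n)[-1]) {
    lo <- st[i]
    if (is.finite(H)) lo <- max(lo, i - as.integer(H))
    if (lo > i - 1L) next
    js <- (i - 1L):lo                       # descending: nearest first
    trip[i] <- length(js)
    best <- candidate_best(x, y, w, f, js, i, params, mean_span)
    if (best$score > w[i]) {
      f[i] <- best$score
      parent[i] <- best$j
    }
  }
  structure(list(f = f, parent = parent, trip_count = trip, subparts = NULL,
                 mean_span = mean_span),
            class = "dp_result")
}

# Vectorised evaluation of the recurrence over candidate set `js`
# (descending). Returns the best f[j] + score and its j; ties keep the
# first (nearest) candidate via which.max on the descending order.
candidate_best <- function(x, y, w, f, js, i, params, mean_span) {
  dx <- x[i] - x[js]
  dy <- y[i] - y[js]
  d <- abs(dy - dx)
  ok <- dx > 0 & dy > 0 & dx <= params$max_dist_x & dy <= params$max_dist_y &
    d <= params$bandwidth
  if (!any(ok)) return(list(score = -Inf, j = NA_integer_))
  alpha <- pmin(dy, dx, w[i])
  beta <- ifelse(d == 0, 0, params$gap_scale * mean_span * d + 0.5 * log2(d))
  sc <- f[js] + (alpha - beta)
  sc[!ok] <- -Inf
  b <- which.max(sc)
  list(score = sc[b], j = js[b])
}

#' Chaining scores via the sub-partitioned inner loop
#'
#' Identical `f`, `parent` and `trip_count` to [chain_scores()] at the same
#' finite `H`, but each anchor's candidate range is processed in
#' consecutive sub-partitions of at most `params$P` candidates (descending
#' `j`), with a partial running maximum carried across sub-partitions --
#' the loop structure of the fixed-bound hardware pipeline. Also records
#' the number of sub-partitions executed per anchor (`subparts`), the
#' quantity the hardware time model counts.
#'
#' @inheritParams chain_scores
#' @return A `dp_result` with an additional integer vector `subparts`.
#' @export
chain_scores_subpartitioned <- function(task, params) {
  if (!is.finite(params$H)) {
    stop("chain_scores_subpartitioned requires finite H: ",
         "the sub-partitioned engine models fixed-bound hardware loops")
  }
  a <- task$anchors
  n <- nrow(a)
  if (n == 0) {
    res <- empty_dp_result()
    res$subparts <- integer(0)
    return(res)
  }
  x <- as.numeric(a$x); y <- as.numeric(a$y); w <- as.numeric(a$w)
  mean_span <- task_mean_span(task)
  H <- as.integer(params$H); P <- params$P
  st <- start_index(x, params$max_dist_x)
  f <- w
  parent <- rep(NA_integer_, n)
  trip <- integer(n)
  subparts <- integer(n)
  for (i in seq_len(n)[-1]) {
    lo <- max(st[i], i - H)
    if (lo > i - 1L) next
    js <- (i - 1L):lo
    trip[i] <- length(js)
    nsp <- as.integer(ceiling(length(js) / P))
    subparts[i] <- nsp
    run_score <- -Inf
    run_j <- NA_integer_
    for (s in seq_len(nsp)) {
      slice <- js[((s - 1L) * P + 1L):min(s * P, length(js))]
      best <- candidate_best(x, y, w, f, slice, i, params, mean_span)
      if (best$score > run_score) {         # strict: earlier slice wins ties
        run_score <- best$score
        run_j <- best$j
      }
    }
    if (run_score > w[i]) {
      f[i] <- run_score
      parent[i] <- run_j
    }
  }
  structure(list(f = f, parent = parent, trip_count = trip,
                 subparts = subparts, mean_span = mean_span),
            class = "dp_result")
}

#' Backtrack chains from a DP result
#'
#' Visits anchors in descending `f` (ties: lower index first). From each
#' unused anchor it follows parent pointers while the predecessor is
#' unused, collecting indices and marking them used. When the walk hits an
#' anchor already claimed by a higher-scoring chain, the truncated chain's
#' score is `f[terminal] - f[collision]`, avoiding double-counting of the
#' shared prefix; chains reaching a start anchor score `f[terminal]`.
#' Chains failing `min_score`/`min_cnt` are dropped (their anchors stay
#' consumed). Returned chains are anchor-disjoint, sorted by score
#' descending with ties broken by terminal index ascending.
#'
#' @param task the [chain_task()] the DP was computed from.
#' @param dp the `dp_result` from [chain_scores()] or
#'   [chain_scores_subpartitioned()].
#' @param params a [chaining_params()] supplying `min_score` and `min_cnt`.
#' @return A list of chains: `list(anchor_indices =, score =, n_anchors =)`
#'   with 1-based, strictly increasing anchor indices.
#' @export
backtrack_chains <- function(task, dp, params) {
  n <- length(dp$f)
  if (n == 0) return(list())
  ord <- order(-dp$f, seq_len(n))
  used <- logical(n)
  out <- list()
  for (t in ord) {
    if (used[t]) next
    idx <- integer(0)
    cur <- t
    base <- 0
    repeat {
      idx <- c(cur, idx)
      used[cur] <- TRUE
      p <- dp$parent[cur]
      if (is.na(p)) break
      if (used[p]) { base <- dp$f[p]; break }
      cur <- p
    }
    score <- dp$f[t] - base
    if (score >= params$min_score && length(idx) >= params$min_cnt) {
      out[[length(out) + 1L]] <- list(anchor_indices = idx, score = score,
                                      n_anchors = length(idx), terminal = t)
    }
  }
  if (length(out) == 0) return(list())
  sc <- vapply(out, `[[`, numeric(1), "score")
  term <- vapply(out, `[[`, integer(1), "terminal")
  out <- out[order(-sc, term)]
  lapply(out, function(ch) ch[c("anchor_indices", "score", "n_anchors")])
}

#' Brute-force best chain score (test oracle)
#'
#' Plain quadratic evaluation of the chaining recurrence with the
#' candidate set equal to ALL `j < i` passing eligibility -- no start-index
#' binary search, no trip-count bound. Used to validate that those are
#' pure optimisations when `H = Inf`. Quadratic: keep `n` small.
#'
#' @inheritParams chain_scores
#' @return The best `f` over all anchors, or `NA` for an empty task.
#' @export
brute_force_best_score <- function(task, params) {
  a <- task$anchors
  n <- nrow(a)
  if (n == 0) return(NA_real_)
  w <- as.numeric(a$w)
  mean_span <- max(1, round(mean(w)))
  x <- as.numeric(a$x); y <- as.numeric(a$y)
  f <- w
  for (i in seq_len(n)) {
    if (i == 1L) next
    js <- seq_len(i - 1L)                 # every predecessor, ascending
    dx <- x[i] - x[js]
    dy <- y[i] - y[js]
    d <- abs(dy - dx)
    gain <- pmin(dx, dy, w[i]) -
      ifelse(d == 0, 0, params$gap_scale * mean_span * d + 0.5 * log2(d))
    gain[!(dx > 0 & dy > 0 & dx <= params$max_dist_x &
             dy <= params$max_dist_y & d <= params$bandwidth)] <- -Inf
    f[i] <- max(w[i], f[js] + gain)
  }
  max(f)
}
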