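# Anchors and chaining tasks.
#
# An anchor is one exact seed match between a query (read) and a reference,
# stored by the 0-based inclusive END positions of the matching span on the
# reference (x) and the query (y) together with the span length w.  A
# chaining task is the sorted anchor set of one read/strand: the unit both
# of the chaining DP and of hardware/software scheduling.

#' Construct an anchor table
#'
#' Builds and validates a data frame of anchors. Positions are 0-based
#' inclusive end coordinates of the matching span; `w` is the span in bases.
#'
#' @param x integer vector, reference end positions (0-based, inclusive).
#' @param y integer vector, query end positions (0-based, inclusive).
#' @param w integer vector (or scalar), span of each match in bases.
#' @return A `data.frame` with integer columns `x`, `y`, `w`, sorted
#'   lexicographically by `(x, y)`.
#' @examples
#' anchors(x = c(14, 29), y = c(14, 29), w = 15)
#' @export
anchors <- function(x = integer(), y = integer(), w = integer()) {
  n <- length(x)
  if (length(y) != n) stop_field("y", "length must match x")
  w <- rep_len(as.integer(w), n)
  x <- as.integer(x); y <- as.integer(y)
  a <- data.frame(x = x, y = y, w = w)
  validate_anchors(a)
  a[order(a$x, a$y), , drop = FALSE]
}

validate_anchors <- function(a) {
  if (!all(c("x", "y", "w") %in% names(a))) {
    stop_field("anchors", "must have columns x, y, w")
  }
  if (nrow(a) == 0) return(invisible(a))
  if (any(a$x < 0)) stop_field("x", "must be >= 0")
  if (any(a$y < 0)) stop_field("y", "must be >= 0")
  if (any(a$w < 1)) stop_field("w", "must be >= 1")
  if (any(a$w > a$x + 1) || any(a$w > a$y + 1)) {
    stop_field("w", "span must fit before its end position (w <= x+1, w <= y+1)")
  }
  invisible(a)
}

#' Construct a chaining task
#'
#' A chaining task holds the anchors of one read/strand, sorted
#' lexicographically by `(x, y)` with duplicate `(x, y)` pairs removed.
#'
#' @param task_id character scalar identifying the task.
#' @param anchors anchor `data.frame` as built by [anchors()].
#' @param query_length optional query length in bases (`NA` if unknown).
#' @param strand `"+"` or `"-"`.
#' @return An object of class `chain_task`.
#' @export
chain_task <- function(task_id, anchors, query_length = NA_integer_,
                       strand = "+") {
  if (length(task_id) != 1 || !nzchar(as.character(task_id))) {
    stop_field("task_id", "must be a non-empty string")
  }
  if (!strand %in% c("+", "-")) stop_field("strand", "must be '+' or '-'")
  validate_anchors(anchors)
  a <- anchors[order(anchors$x, anchors$y), , drop = FALSE]
  a <- a[!duplicated(a[c("x", "y")]), , drop = FALSE]
  rownames(a) <- NULL
  structure(
    list(task_id = as.character(task_id), anchors = a,
         query_length = as.integer(query_length), strand = strand),
    class = "chain_task")
}

#' @export
print.chain_task <- function(x, ...) {
  cat(sprintf("<chain_task '%s'> %d anchors, strand %s\n",
              x$task_id, nrow(x$anchors), x$strand))
  invisible(x)
}

#' @export
format.chain_task <- function(x, ...) {
  sprintf("chain_task '%s' (%d anchors)", x$task_id, nrow(x$anchors))
}

#' Configuration for the synthetic task generator
#'
#' Describes a batch of synthetic chaining tasks: each task carries one or
#' more planted co-linear chains (consecutive anchors advancing on both axes
#' by roughly `span_k` bases) plus uniformly scattered noise anchors.
#' Defaults emulate anchor sets from noisy long reads of a few tens of
#' kilobases seeded with k = 15 minimizers: tasks of 64-256 anchors, two
#' planted chains, 35% noise.
#'
#' @param n_tasks number of tasks to generate.
#' @param anchors_per_task total anchors per task; a scalar or a
#'   `c(min, max)` range sampled uniformly per task.
#' @param planted_chains_per_task number of planted co-linear chains.
#' @param noise_fraction fraction of each task's anchors that are uniform
#'   noise, in `[0, 1]`.
#' @param span_k anchor span in bases (the seed k-mer size).
#' @param coord_range coordinate range (bases) over which anchors fall.
#' @param step_jitter maximum +/- jitter (bases) on each planted step.
#' @param seed integer RNG seed; the generator is fully deterministic
#'   given the configuration.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_tasks = 100,
                             anchors_per_task = c(64, 256),
                             planted_chains_per_task = 2,
                             noise_fraction = 0.35,
                             span_k = 15,
                             coord_range = 20000,
                             step_jitter = 5,
                             seed = 1L) {
  cfg <- list(
    n_tasks = check_count(n_tasks, "n_tasks"),
    anchors_per_task = anchors_per_task,
    planted_chains_per_task = check_count(planted_chains_per_task,
                                          "planted_chains_per_task"),
    noise_fraction = check_number(noise_fraction, "noise_fraction", 0, 1),
    span_k = check_count(span_k, "span_k", min = 1),
    coord_range = check_count(coord_range, "coord_range", min = 1),
    step_jitter = check_count(step_jitter, "step_jitter"),
    seed = check_count(seed, "seed", min = -.Machine$integer.max))
  apt <- cfg$anchors_per_task
  if (!is.numeric(apt) || !length(apt) %in% c(1, 2) || any(is.na(apt)) ||
      any(apt != floor(apt)) || any(apt < 0)) {
    stop_field("anchors_per_task", "must be one count or a c(min, max) range")
  }
  if (length(apt) == 2 && apt[1] > apt[2]) {
    stop_field("anchors_per_task", "range min must not exceed max")
  }
  cfg$anchors_per_task <- as.integer(apt)
  if (cfg$coord_range < cfg$span_k) {
    stop_field("coord_range", "must be at least span_k")
  }
  structure(cfg, class = "generator_config")
}

#' Generate synthetic chaining tasks
#'
#' Produces `cfg$n_tasks` chaining tasks. Each task contains its planted
#' chains' anchors -- consecutive anchors advancing on both reference and
#' query by `span_k` plus an independent jitter in
#' `[-step_jitter, step_jitter]` on each axis (clamped so both coordinates
#' advance strictly) -- plus noise anchors scattered uniformly over the
#' coordinate range. Anchors are sorted by `(x, y)` and duplicate positions
#' are re-drawn, preserving the strict-uniqueness task invariant. Output is
#' fully deterministic given `cfg` (including `cfg$seed`).
#'
#' @param cfg a [generator_config()].
#' @return A list of [chain_task()] objects.
#' @examples
#' tasks <- generate_tasks(generator_config(n_tasks = 2, seed = 7))
#' tasks[[1]]
#' @export
generate_tasks <- function(cfg) {
  if (!inherits(cfg, "generator_config")) cfg <- do.call(generator_config, cfg)
  with_local_seed(cfg$seed, {
    lapply(seq_len(cfg$n_tasks), function(t) generate_one_task(cfg, t))
  })
}

generate_one_task <- function(cfg, index) {
  apt <- cfg$anchors_per_task
  total <- if (length(apt) == 2) {
    as.integer(sample(seq(apt[1], apt[2]), 1))
  } else apt
  n_noise <- as.integer(round(cfg$noise_fraction * total))
  n_plant <- total - n_noise
  k <- cfg$span_k
  lo <- k - 1L                      # smallest legal end coordinate for span k

  xs <- integer(0); ys <- integer(0)
  nchain <- cfg$planted_chains_per_task
  if (nchain > 0 && n_plant > 0) {
    sizes <- rep(n_plant %/% nchain, nchain)
    extra <- n_plant %% nchain
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    sizes <- sizes[sizes > 0]
    for (m in sizes) {
      extent <- m * (k + cfg$step_jitter)  # upper bound on chain extent
      x0 <- lo + sample.int(max(1L, cfg$coord_range - lo - extent), 1)
      y0 <- lo + sample.int(max(1L, cfg$coord_range - lo - extent), 1)
      dx <- pmax(1L, k + sample.int(2L * cfg$step_jitter + 1L, m - 1,
                                    replace = TRUE) - cfg$step_jitter - 1L)
      dy <- pmax(1L, k + sample.int(2L * cfg$step_jitter + 1L, m - 1,
                                    replace = TRUE) - cfg$step_jitter - 1L)
      xs <- c(xs, x0 + cumsum(c(0L, dx)))
      ys <- c(ys, y0 + cumsum(c(0L, dy)))
    }
  }

  key <- function(x, y) x * (cfg$coord_range + 2) + y
  seen <- key(xs, ys)
  if (n_noise > 0) {
    draw <- function(n) {
      cbind(lo + sample.int(cfg$coord_range - lo + 1L, n, replace = TRUE) - 1L,
            lo + sample.int(cfg$coord_range - lo + 1L, n, replace = TRUE) - 1L)
    }
    need <- n_noise
    while (need > 0) {               # collisions with existing anchors re-drawn
      cand <- draw(need)
      kk <- key(cand[, 1], cand[, 2])
      ok <- !(kk %in% seen) & !duplicated(kk)
      xs <- c(xs, cand[ok, 1]); ys <- c(ys, cand[ok, 2])
      seen <- c(seen, kk[ok])
      need <- need - sum(ok)
    }
  }

  chain_task(task_id = sprintf("task%04d", index),
             anchors = anchors(x = xs, y = ys, w = k),
             query_length = if (length(ys)) max(ys) + 1L else NA_integer_)
}

ANCHOR_TSV_HEADER <- c("task_id", "x", "y", "w", "strand")

#' Write chaining tasks to the anchor TSV dialect
#'
#' One row per anchor with header `task_id  x  y  w  strand`
#' (tab-separated); integer coordinates, strand in `{+, -}`.
#'
#' @param tasks list of [chain_task()] objects.
#' @param destination file path or connection.
#' @seealso [read_anchor_table()]
#' @export
write_anchor_table <- function(tasks, destination) {
  rows <- lapply(tasks, function(t) {
    if (nrow(t$anchors) == 0) return(NULL)
    data.frame(task_id = t$task_id, t$anchors, strand = t$strand)
  })
  tab <- do.call(rbind, c(list(data.frame(task_id = character(), x = integer(),
                                          y = integer(), w = integer(),
                                          strand = character())), rows))
  utils::write.table(tab, destination, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(NULL)
}

#' Read chaining tasks from the anchor TSV dialect
#'
#' Parses the format written by [write_anchor_table()]. Rows are grouped by
#' `task_id` preserving the file order of first appearance; anchors within
#' each task are sorted by `(x, y)`. Malformed rows (wrong column count,
#' non-integer coordinates, `w < 1`) raise an error naming the line number.
#'
#' @param source file path or connection.
#' @return A list of [chain_task()] objects.
#' @export
read_anchor_table <- function(source) {
  lines <- readLines(source)
  if (length(lines) == 0) stop("anchor table is empty (missing header)")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header, ANCHOR_TSV_HEADER)) {
    stop(sprintf("line 1: expected header '%s'",
                 paste(ANCHOR_TSV_HEADER, collapse = "\\t")))
  }
  body <- lines[-1]
  body_no <- which(nzchar(body))
  if (length(body_no) == 0) return(list())
  parts <- strsplit(body[body_no], "\t", fixed = TRUE)
  task_id <- character(length(body_no))
  x <- integer(length(body_no)); y <- integer(length(body_no))
  w <- integer(length(body_no)); strand <- character(length(body_no))
  for (i in seq_along(body_no)) {
    ln <- body_no[i] + 1L
    p <- parts[[i]]
    if (length(p) != 5) {
      stop(sprintf("line %d: expected 5 tab-separated fields, got %d",
                   ln, length(p)))
    }
    xi <- suppressWarnings(as.integer(p[2]))
    yi <- suppressWarnings(as.integer(p[3]))
    wi <- suppressWarnings(as.integer(p[4]))
    if (is.na(xi) || is.na(yi) || is.na(wi)) {
      stop(sprintf("line %d: x, y, w must be integers", ln))
    }
    if (wi < 1) stop(sprintf("line %d: w must be >= 1", ln))
    if (!p[5] %in% c("+", "-")) {
      stop(sprintf("line %d: strand must be '+' or '-'", ln))
    }
    task_id[i] <- p[1]; x[i] <- xi; y[i] <- yi; w[i] <- wi; strand[i] <- p[5]
  }
  ids <- unique(task_id)                     # order of first appearance
  lapply(ids, function(id) {
    sel <- task_id == id
    chain_task(task_id = id,
               anchors = anchors(x = x[sel], y = y[sel], w = w[sel]),
               strand = strand[sel][1])
  })
}
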