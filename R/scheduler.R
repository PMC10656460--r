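# Discrete-event simulation of prediction-based CPU/accelerator task
# placement.
#
# Y software threads each work through an ordered list of items
# (pre-work, chaining task, post-work). At a chaining item the thread
# predicts the task's hardware time T_hw and software time T_sw. If
# T_sw <= T_hw the task runs in place on the thread. Otherwise the thread
# looks for one of the N hardware kernels whose predicted wait plus T_hw
# is still below T_sw; if one qualifies the task joins that kernel's FIFO
# access queue (the thread blocks until the kernel completes it --
# downstream mapping stages need the chain scores), else it falls back to
# software. N is typically much smaller than Y, so the per-kernel wait
# accounting is what keeps a few kernels from becoming a bottleneck for
# many threads.

#' Kernel state for placement decisions
#'
#' Snapshot of one hardware kernel as seen by the scheduler: when its
#' current task will finish, and the predicted durations of tasks queued
#' behind it (FIFO, arrival order).
#'
#' @param busy_until simulation time (ms) at which the currently running
#'   task completes (<= now for an idle kernel).
#' @param queue numeric vector of predicted durations (ms) of queued,
#'   not-yet-started tasks, in arrival order.
#' @param kernel_index identifying index.
#' @return An object of class `kernel_state`.
#' @export
kernel_state <- function(busy_until = 0, queue = numeric(0),
                         kernel_index = 1L) {
  structure(list(kernel_index = as.integer(kernel_index),
                 busy_until = as.numeric(busy_until),
                 queue = as.numeric(queue)),
            class = "kernel_state")
}

#' Predicted wait to access a kernel
#'
#' Remaining service of the running task plus the predicted durations of
#' everything already queued: `max(0, busy_until - now) + sum(queue)`.
#'
#' @param state a [kernel_state()].
#' @param now current simulation time (ms).
#' @return Predicted wait in ms.
#' @examples
#' kernel_wait(kernel_state(busy_until = 13, queue = c(2, 4)), now = 10)  # 9
#' @export
kernel_wait <- function(state, now) {
  max(0, state$busy_until - now) + sum(state$queue)
}

#' Decide hardware/software placement for one chaining task
#'
#' If `t_sw <= t_hw` the task stays in software on the issuing thread.
#' Otherwise, among kernels whose `kernel_wait + t_hw < t_sw`, the one
#' with the smallest predicted wait is chosen (ties: lowest index); if no
#' kernel qualifies the task falls back to software.
#'
#' @param t_hw,t_sw predicted hardware / software times (ms).
#' @param kernels list of [kernel_state()] objects (may be empty).
#' @param now current simulation time (ms).
#' @return A `placement`: `list(kind = "SOFTWARE"|"HARDWARE",
#'   kernel_index =, t_hw_pred =, t_sw_pred =, t_wait_pred =)`.
#' @export
decide_placement <- function(t_hw, t_sw, kernels, now) {
  software <- list(kind = "SOFTWARE", kernel_index = NA_integer_,
                   t_hw_pred = t_hw, t_sw_pred = t_sw,
                   t_wait_pred = NA_real_)
  if (t_sw <= t_hw || length(kernels) == 0) return(software)
  waits <- vapply(kernels, kernel_wait, numeric(1), now = now)
  ok <- which(waits + t_hw < t_sw)
  if (length(ok) == 0) return(software)
  pick <- ok[which.min(waits[ok])]        # which.min ties -> lowest index
  list(kind = "HARDWARE", kernel_index = pick,
       t_hw_pred = t_hw, t_sw_pred = t_sw, t_wait_pred = waits[pick])
}

#' Simulation configuration
#'
#' @param Y software thread count (>= 1); default 8, a typical mapping
#'   run's CPU thread count.
#' @param N hardware kernel count (>= 0, usually < Y); default 1, the
#'   single-kernel accelerator configuration.
#' @param coeffs [perf_coeffs()] used for both prediction and ground
#'   truth.
#' @param truth_model `"exact"` (true time = predicted time) or `"noisy"`
#'   (true time = predicted * (1 + rnorm(sd = truth_sigma)), clamped >= 0,
#'   seeded).
#' @param truth_sigma multiplicative noise sd for `truth_model = "noisy"`.
#' @param pre_ms,post_ms non-chaining work (ms) before/after each task,
#'   standing in for seeding, alignment and output stages.
#' @param seed RNG seed for the noisy truth model.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(Y = 8, N = 1, coeffs = perf_coeffs(),
                       truth_model = c("exact", "noisy"),
                       truth_sigma = 0.1, pre_ms = 0, post_ms = 0,
                       seed = 1L) {
  structure(list(
    Y = check_count(Y, "Y", min = 1),
    N = check_count(N, "N", min = 0),
    coeffs = coeffs,
    truth_model = match.arg(truth_model),
    truth_sigma = check_number(truth_sigma, "truth_sigma", min = 0),
    pre_ms = check_number(pre_ms, "pre_ms", min = 0),
    post_ms = check_number(post_ms, "post_ms", min = 0),
    seed = check_count(seed, "seed", min = -.Machine$integer.max)
  ), class = "sim_config")
}

# Per-task feature/prediction records from chain tasks or a precomputed
# data frame (columns task_id, n, total_subparts, sum_trip_count).
task_records <- function(tasks, cfg, params) {
  if (is.data.frame(tasks)) {
    need <- c("task_id", "n", "total_subparts", "sum_trip_count")
    miss <- setdiff(need, names(tasks))
    if (length(miss) > 0) {
      stop("task records lack column(s): ", paste(miss, collapse = ", "))
    }
    rec <- tasks[need]
  } else {
    H <- if (is.finite(params$H)) params$H else 512
    rec <- do.call(rbind, lapply(tasks, function(t) {
      hwf <- hw_features(t, H = H, P = params$P)
      swf <- sw_features(t, params)
      data.frame(task_id = t$task_id, n = hwf$n,
                 total_subparts = hwf$total_subparts,
                 sum_trip_count = swf$sum_trip_count)
    }))
  }
  rec$t_hw_pred <- vapply(seq_len(nrow(rec)), function(i) {
    predict_hw(list(n = rec$n[i], total_subparts = rec$total_subparts[i]),
               cfg$coeffs)
  }, numeric(1))
  rec$t_sw_pred <- vapply(rec$sum_trip_count, function(s) {
    predict_sw(list(sum_trip_count = s), cfg$coeffs)
  }, numeric(1))
  rec
}

#' Simulate prediction-based hardware/software task placement
#'
#' Event-driven simulation of the placement policy over a workload of
#' chaining tasks. Tasks are dealt round-robin to `cfg$Y` thread work
#' lists; each thread processes its items in order (pre-work, placement
#' decision, chaining, post-work). Software tasks advance the thread by
#' the true software time; hardware tasks are appended to the chosen
#' kernel's FIFO queue and the thread blocks until the kernel -- which
#' serves its queue one task at a time in arrival order -- completes
#' them. Simultaneous decisions are ordered by (time, thread index).
#' Fully deterministic given the configuration and seed.
#'
#' @param tasks list of [chain_task()] objects, or a precomputed record
#'   `data.frame` with columns `task_id`, `n`, `total_subparts`,
#'   `sum_trip_count`.
#' @param cfg a [sim_config()].
#' @param params a [chaining_params()] (used to derive features when raw
#'   tasks are given; `H` must match the hardware bound being modelled).
#' @return A `sim_result`: list with `makespan` (ms), `placements` (one
#'   row per task: placement kind, kernel, predictions, true elapsed
#'   chaining time), `kernel_log` (per hardware execution: enqueue, start,
#'   end), `kernel_busy`, `kernel_utilization`, `n_hardware`,
#'   `n_software`, `thread_finish`.
#' @export
simulate_schedule <- function(tasks, cfg, params = chaining_params()) {
  rec <- task_records(tasks, cfg, params)
  nt <- nrow(rec)
  rec$true_hw <- rec$t_hw_pred
  rec$true_sw <- rec$t_sw_pred
  if (cfg$truth_model == "noisy" && nt > 0) {
    noise <- with_local_seed(cfg$seed, {
      matrix(stats::rnorm(2L * nt, 0, cfg$truth_sigma), ncol = 2)
    })
    rec$true_hw <- pmax(0, rec$true_hw * (1 + noise[, 1]))
    rec$true_sw <- pmax(0, rec$true_sw * (1 + noise[, 2]))
  }

  # Round-robin deal onto Y work lists, preserving order within a thread.
  thread_of <- ((seq_len(nt) - 1L) %% cfg$Y) + 1L
  work <- split(seq_len(nt), factor(thread_of, levels = seq_len(cfg$Y)))

  thread_time <- numeric(cfg$Y)
  next_item <- rep(1L, cfg$Y)
  # Kernel bookkeeping: committed executions with known start/end times.
  k_free <- numeric(cfg$N)                  # end of last committed task
  k_log <- vector("list", cfg$N)
  placements <- data.frame(
    task_id = rec$task_id, placement = NA_character_,
    kernel = NA_integer_, t_sw_pred = rec$t_sw_pred,
    t_hw_pred = rec$t_hw_pred, t_wait_pred = NA_real_,
    decision_time = NA_real_, true_elapsed = NA_real_,
    stringsAsFactors = FALSE)

  kernel_view <- function(now) {
    lapply(seq_len(cfg$N), function(ki) {
      log <- k_log[[ki]]
      busy <- 0
      queue <- numeric(0)
      if (!is.null(log)) {
        running <- log$start <= now & log$end > now
        if (any(running)) busy <- max(log$end[running])
        queued <- log$start > now
        queue <- log$pred[queued]           # arrival order preserved
      }
      kernel_state(busy_until = busy, queue = queue, kernel_index = ki)
    })
  }

  repeat {
    pending <- which(next_item <= lengths(work))
    if (length(pending) == 0) break
    # Earliest next decision; ties broken by thread index.
    th <- pending[which.min(thread_time[pending])]
    task <- work[[th]][next_item[th]]
    next_item[th] <- next_item[th] + 1L
    now <- thread_time[th] + cfg$pre_ms
    pl <- decide_placement(rec$t_hw_pred[task], rec$t_sw_pred[task],
                           kernel_view(now), now)
    placements$placement[task] <- pl$kind
    placements$t_wait_pred[task] <- pl$t_wait_pred
    placements$decision_time[task] <- now
    if (pl$kind == "SOFTWARE") {
      done <- now + rec$true_sw[task]
      placements$true_elapsed[task] <- rec$true_sw[task]
    } else {
      ki <- pl$kernel_index
      placements$kernel[task] <- ki
      start <- max(now, k_free[ki])         # FIFO: behind all committed work
      end <- start + rec$true_hw[task]
      k_free[ki] <- end
      entry <- data.frame(task = task, enqueue = now, start = start,
                          end = end, pred = rec$t_hw_pred[task])
      k_log[[ki]] <- rbind(k_log[[ki]], entry)
      done <- end                            # issuing thread blocks
      placements$true_elapsed[task] <- end - now
    }
    thread_time[th] <- done + cfg$post_ms
  }

  makespan <- if (cfg$Y > 0) max(thread_time) else 0
  kernel_log <- do.call(rbind, c(
    list(data.frame(kernel = integer(0), task = integer(0),
                    task_id = character(0), enqueue = numeric(0),
                    start = numeric(0), end = numeric(0), pred = numeric(0))),
    lapply(seq_len(cfg$N), function(ki) {
      log <- k_log[[ki]]
      if (is.null(log)) return(NULL)
      data.frame(kernel = ki, task = log$task,
                 task_id = rec$task_id[log$task], enqueue = log$enqueue,
                 start = log$start, end = log$end, pred = log$pred)
    })))
  busy <- vapply(seq_len(cfg$N), function(ki) {
    log <- k_log[[ki]]
    if (is.null(log)) 0 else sum(log$end - log$start)
  }, numeric(1))
  structure(list(
    makespan = makespan,
    placements = placements,
    kernel_log = kernel_log,
    kernel_busy = busy,
    kernel_utilization = if (makespan > 0) busy / makespan else busy,
    n_hardware = sum(placements$placement == "HARDWARE"),
    n_software = sum(placements$placement == "SOFTWARE"),
    thread_finish = thread_time
  ), class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %d tasks (%d hardware, %d software), makespan %.3f ms\n",
              nrow(x$placements), x$n_hardware, x$n_software, x$makespan))
  if (length(x$kernel_utilization) > 0) {
    cat(sprintf("  kernel utilization: %s\n",
                paste(sprintf("%.1f%%", 100 * x$kernel_utilization),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Write a simulation report TSV
#'
#' One row per task (`task_id`, `placement`, `t_sw_pred`, `t_hw_pred`,
#' `t_wait_pred`, `true_elapsed`) followed by a `#`-commented summary
#' block (makespan, hardware fraction, per-kernel utilization).
#'
#' @param result a `sim_result` from [simulate_schedule()].
#' @param path file path.
#' @export
write_sim_report <- function(result, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  cols <- c("task_id", "placement", "t_sw_pred", "t_hw_pred",
            "t_wait_pred", "true_elapsed")
  utils::write.table(result$placements[cols], con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  nt <- nrow(result$placements)
  writeLines(c(
    sprintf("# makespan_ms\t%.6f", result$makespan),
    sprintf("# hw_fraction\t%.6f",
            if (nt > 0) result$n_hardware / nt else 0),
    sprintf("# kernel_utilization\t%s",
            paste(sprintf("%.6f", result$kernel_utilization),
                  collapse = ","))), con)
  invisible(NULL)
}
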