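# Placement policy and discrete-event simulation.

# Precomputed task records with controllable predicted times:
# t_sw = K2 * sum_trip_count + C2, t_hw = E * total_subparts + C1 under
# unit-free test coefficients (K1 = 0) so both are easy to set exactly.
test_coeffs <- function() {
  perf_coeffs(K1 = 0, E = 1, C1 = 0, K2 = 1, C2 = 0)
}

records <- function(t_hw, t_sw, ids = NULL) {
  n <- length(t_hw)
  data.frame(task_id = ids %||% sprintf("r%03d", seq_len(n)),
             n = 0L, total_subparts = t_hw, sum_trip_count = t_sw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_records <- function(n, seed) {
  set.seed(seed)
  # mixture of small (software-leaning) and large (hardware-leaning) tasks
  sw <- round(stats::rlnorm(n, meanlog = 1, sdlog = 1.2), 3)
  hw <- round(sw * stats::runif(n, 0.3, 1.5), 3)
  records(hw, sw)
}

test_that("kernel_wait adds remaining service and queued predictions", {
  expect_equal(kernel_wait(kernel_state(0, numeric(0)), now = 10), 0)
  expect_equal(kernel_wait(kernel_state(13, numeric(0)), now = 10), 3)
  expect_equal(kernel_wait(kernel_state(13, c(2, 4)), now = 10), 9)
  expect_equal(kernel_wait(kernel_state(5, c(1)), now = 10), 1)  # idle now
})

test_that("decide_placement enumerates the policy branches", {
  idle <- list(kernel_state(0, numeric(0), 1))

  # T_software <= T_hardware stays on the thread
  expect_equal(decide_placement(7, 5, idle, 0)$kind, "SOFTWARE")
  expect_equal(decide_placement(5, 5, idle, 0)$kind, "SOFTWARE")

  # forced offload to an idle kernel
  p <- decide_placement(2, 10, idle, 0)
  expect_equal(p$kind, "HARDWARE")
  expect_equal(p$kernel_index, 1L)
  expect_equal(p$t_wait_pred, 0)

  # both kernels too backed up: waits 5 and 9 give totals 8 and 12 >= 7
  busy <- list(kernel_state(5, numeric(0), 1), kernel_state(9, numeric(0), 2))
  expect_equal(decide_placement(3, 7, busy, 0)$kind, "SOFTWARE")

  # qualifying kernels: minimal wait wins, ties to the lowest index
  k3 <- list(kernel_state(6, numeric(0), 1), kernel_state(2, numeric(0), 2))
  p3 <- decide_placement(3, 20, k3, 0)
  expect_equal(p3$kernel_index, 2L)
  expect_equal(p3$t_wait_pred, 2)
  tie <- list(kernel_state(4, numeric(0), 1), kernel_state(4, numeric(0), 2))
  expect_equal(decide_placement(3, 20, tie, 0)$kernel_index, 1L)

  # no kernels at all
  expect_equal(decide_placement(1, 100, list(), 0)$kind, "SOFTWARE")
})

test_that("N = 0 reduces to the analytic per-thread sum", {
  rec <- random_records(37, seed = 21)
  cfg <- sim_config(Y = 4, N = 0, coeffs = test_coeffs(),
                    pre_ms = 0.5, post_ms = 0.25)
  res <- simulate_schedule(rec, cfg)
  expect_true(all(res$placements$placement == "SOFTWARE"))
  thread <- ((seq_len(nrow(rec)) - 1L) %% 4) + 1L
  want <- vapply(1:4, function(th) {
    sum(0.5 + rec$sum_trip_count[thread == th] + 0.25)
  }, numeric(1))
  expect_equal(res$thread_finish, want)
  expect_equal(res$makespan, max(want))
})

test_that("single offloaded task traces by hand", {
  rec <- records(t_hw = 2, t_sw = 10)
  cfg <- sim_config(Y = 1, N = 1, coeffs = test_coeffs(),
                    pre_ms = 1, post_ms = 0.5)
  res <- simulate_schedule(rec, cfg)
  expect_equal(res$placements$placement, "HARDWARE")
  expect_equal(res$placements$t_wait_pred, 0)
  expect_equal(res$makespan, 1 + 2 + 0.5)
  expect_equal(res$kernel_log$start, 1)
  expect_equal(res$kernel_log$end, 3)
  expect_equal(res$kernel_busy, 2)
})

test_that("exact predictions give hardware dominance over N = 0", {
  rec <- random_records(200, seed = 42)
  base <- simulate_schedule(rec, sim_config(Y = 8, N = 0,
                                            coeffs = test_coeffs()))
  acc <- simulate_schedule(rec, sim_config(Y = 8, N = 1,
                                           coeffs = test_coeffs()))
  expect_gt(acc$n_hardware, 0)              # the policy does offload
  expect_lte(acc$makespan, base$makespan)

  # every hardware placement beat its software prediction at decision time
  hw <- acc$placements[acc$placements$placement == "HARDWARE", ]
  expect_true(all(hw$t_wait_pred + hw$t_hw_pred < hw$t_sw_pred))

  # and with exact truth, elapsed chaining time never exceeds software time
  expect_true(all(hw$true_elapsed <= hw$t_sw_pred + 1e-9))
})

test_that("kernels serve their queues FIFO without overlap", {
  rec <- random_records(150, seed = 7)
  res <- simulate_schedule(rec, sim_config(Y = 6, N = 2,
                                           coeffs = test_coeffs()))
  log <- res$kernel_log
  expect_gt(nrow(log), 0)
  for (ki in unique(log$kernel)) {
    l <- log[log$kernel == ki, ]
    expect_false(is.unsorted(l$enqueue))    # logged in arrival order
    expect_true(all(diff(order(l$enqueue)) > 0))
    expect_true(all(l$start >= l$enqueue))
    if (nrow(l) > 1) {
      expect_true(all(l$start[-1] >= l$end[-nrow(l)]))  # single occupancy
    }
  }
  # conservation: each task placed exactly once
  expect_equal(res$n_hardware + res$n_software, nrow(rec))
  expect_equal(sort(log$task_id),
               sort(res$placements$task_id[res$placements$placement ==
                                             "HARDWARE"]))
})

test_that("simulation is deterministic given config and seed", {
  rec <- random_records(80, seed = 3)
  cfg <- sim_config(Y = 8, N = 2, coeffs = test_coeffs(),
                    truth_model = "noisy", truth_sigma = 0.2, seed = 11)
  expect_identical(simulate_schedule(rec, cfg), simulate_schedule(rec, cfg))
  cfg2 <- cfg; cfg2$seed <- 12L
  expect_false(identical(simulate_schedule(rec, cfg),
                         simulate_schedule(rec, cfg2)))
})

test_that("noisy truth stays non-negative and changes only true times", {
  rec <- random_records(50, seed = 5)
  cfg_e <- sim_config(Y = 4, N = 1, coeffs = test_coeffs())
  cfg_n <- sim_config(Y = 4, N = 1, coeffs = test_coeffs(),
                      truth_model = "noisy", truth_sigma = 0.3, seed = 2)
  exact <- simulate_schedule(rec, cfg_e)
  noisy <- simulate_schedule(rec, cfg_n)
  expect_true(all(noisy$placements$true_elapsed >= 0))
  expect_equal(noisy$placements$t_sw_pred, exact$placements$t_sw_pred)
  expect_equal(noisy$placements$t_hw_pred, exact$placements$t_hw_pred)
})

test_that("simulation report writes rows plus a summary footer", {
  rec <- random_records(12, seed = 9)
  res <- simulate_schedule(rec, sim_config(Y = 2, N = 1,
                                           coeffs = test_coeffs()))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sim_report(res, path)
  lines <- readLines(path)
  expect_equal(sum(!startsWith(lines, "#")), 13)  # header + 12 tasks
  expect_true(any(grepl("^# makespan_ms\t", lines)))
  expect_true(any(grepl("^# hw_fraction\t", lines)))
})
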