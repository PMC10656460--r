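# Per-task runtime predictors for the hardware/software split decision.
#
# Hardware time for a chaining task is modelled as per-task data transfer
# plus pipelined kernel execution:
#
#   T_hw = K1 * n + (II * T_clock) * total_subparts + C1
#
# where n is the anchor count, total_subparts the number of inner-loop
# sub-partitions the fixed-bound pipeline executes for the task, II the
# pipeline initiation interval (cycles per sub-partition) and T_clock the
# clock period. Software time scales with the inner-loop iterations the
# CPU actually performs:
#
#   T_sw = K2 * sum_i trip_count_i + C2
#
# Only the product E = II * T_clock is identifiable from timing data, so E
# is fit and stored as one ms-per-subpartition coefficient; II and T_clock
# are kept as configuration metadata. Fitted intercepts may come out
# negative; predictions are clamped at zero.

#' Performance-model coefficients
#'
#' @param K1 data-transfer time per anchor (ms/anchor).
#' @param E combined execution-time coefficient `II * T_clock`
#'   (ms per sub-partition). If `NULL`, computed from `II` and `T_clock`.
#' @param C1 fixed hardware overhead per task (ms).
#' @param K2 software time per inner-loop iteration (ms/iteration).
#' @param C2 fixed software overhead per task (ms).
#' @param II pipeline initiation interval (cycles per sub-partition);
#'   metadata once `E` is given.
#' @param T_clock clock period (ms per cycle); default corresponds to a
#'   200 MHz accelerator clock.
#' @param residual_rms_hw,residual_rms_sw residual RMS of the fits that
#'   produced the coefficients (`NA` for hand-set values).
#' @return An object of class `perf_coeffs`.
#' @details Defaults are order-of-magnitude plausible for a PCIe-attached
#'   accelerator (sub-microsecond per-anchor transfer, ~50 us fixed DMA
#'   latency, a few ns per software inner-loop iteration); real
#'   deployments refit them from measured timings with [fit_coeffs()].
#' @export
perf_coeffs <- function(K1 = 2e-6, E = NULL, C1 = 0.05,
                        K2 = 5e-6, C2 = 0.002,
                        II = 2, T_clock = 5e-6,
                        residual_rms_hw = NA_real_,
                        residual_rms_sw = NA_real_) {
  II <- check_number(II, "II", min = 0)
  T_clock <- check_number(T_clock, "T_clock", min = 0)
  if (is.null(E)) E <- II * T_clock
  structure(list(K1 = as.numeric(K1), E = as.numeric(E), C1 = as.numeric(C1),
                 K2 = as.numeric(K2), C2 = as.numeric(C2),
                 II = II, T_clock = T_clock,
                 residual_rms_hw = residual_rms_hw,
                 residual_rms_sw = residual_rms_sw),
            class = "perf_coeffs")
}

#' @export
print.perf_coeffs <- function(x, ...) {
  cat("<perf_coeffs>\n")
  cat(sprintf("  hardware: K1 = %.4g ms/anchor, E = II*T_clock = %.4g ms/subpart, C1 = %.4g ms\n",
              x$K1, x$E, x$C1))
  cat(sprintf("  software: K2 = %.4g ms/iter, C2 = %.4g ms\n", x$K2, x$C2))
  invisible(x)
}

#' Hardware execution features of a chaining task
#'
#' `n` is the anchor count and `total_subparts` the number of inner-loop
#' sub-partitions a fixed-bound pipeline executes:
#' `sum over anchors i (0-based) of ceil(min(i, H) / P)`. The hardware
#' loop iterates the full `min(i, H)` lookback -- it cannot binary-search
#' the start index the way software does.
#'
#' @param task a [chain_task()], or an anchor count.
#' @param H finite trip-count bound.
#' @param P sub-partition size.
#' @return A list `(n =, total_subparts =)`.
#' @examples
#' hw_features(5, H = 512, P = 64)   # total_subparts = 4
#' @export
hw_features <- function(task, H, P) {
  n <- if (inherits(task, "chain_task")) nrow(task$anchors) else
    check_count(task, "task")
  if (!is.finite(H)) stop_field("H", "must be finite for hardware features")
  H <- check_count(H, "H", min = 1)
  P <- check_count(P, "P", min = 1)
  i <- seq_len(n) - 1L
  list(n = n, total_subparts = as.integer(sum(ceiling(pmin(i, H) / P))))
}

#' Software execution features of a chaining task
#'
#' The software path runs the exact DP, so its cost driver is the total
#' number of inner-loop iterations `sum_i trip_count_i` of
#' [chain_scores()] with unbounded `H`.
#'
#' @param task a [chain_task()], or a precomputed `dp_result`.
#' @param params a [chaining_params()] (its `H` is ignored; software is
#'   exact).
#' @return A list `(sum_trip_count =)`.
#' @export
sw_features <- function(task, params = chaining_params()) {
  dp <- if (inherits(task, "dp_result")) task else {
    p <- params; p$H <- Inf
    chain_scores(task, p)
  }
  list(sum_trip_count = sum(dp$trip_count))
}

#' Predict hardware chaining time for a task
#'
#' `max(0, K1 * n + E * total_subparts + C1)`: per-task data transfer,
#' pipelined kernel execution, fixed overhead.
#'
#' @param feat features from [hw_features()].
#' @param coeffs a [perf_coeffs()].
#' @return Predicted time in ms (non-negative).
#' @export
predict_hw <- function(feat, coeffs) {
  max(0, coeffs$K1 * feat$n + coeffs$E * feat$total_subparts + coeffs$C1)
}

#' Predict software chaining time for a task
#'
#' `max(0, K2 * sum_trip_count + C2)`.
#'
#' @param feat features from [sw_features()].
#' @param coeffs a [perf_coeffs()].
#' @return Predicted time in ms (non-negative).
#' @export
predict_sw <- function(feat, coeffs) {
  max(0, coeffs$K2 * feat$sum_trip_count + coeffs$C2)
}

#' Fit predictor coefficients by ordinary least squares
#'
#' Fits the hardware model (`observed_hw_ms ~ n + total_subparts`,
#' estimating `K1`, `E`, `C1`) or the software model
#' (`observed_sw_ms ~ sum_trip_count`, estimating `K2`, `C2`) to a
#' timing-sample table. Mirrors the one-time calibration run against
#' measured task timings.
#'
#' @param samples `data.frame` of timing samples with columns `n`,
#'   `total_subparts`, `observed_hw_ms` (hardware fit) and/or
#'   `sum_trip_count`, `observed_sw_ms` (software fit).
#' @param which `"hardware"` or `"software"`.
#' @param coeffs optional existing [perf_coeffs()] to update; fitted
#'   values overwrite the corresponding side.
#' @return A [perf_coeffs()] with the fitted side replaced and its
#'   residual RMS recorded.
#' @details Requires at least two more samples than free parameters (5 for
#'   hardware, 4 for software) and non-collinear features; otherwise a
#'   fitting error is raised.
#' @export
fit_coeffs <- function(samples, which = c("hardware", "software"),
                       coeffs = perf_coeffs()) {
  which <- match.arg(which)
  if (which == "hardware") {
    need <- c("n", "total_subparts", "observed_hw_ms")
    p <- 3L
  } else {
    need <- c("sum_trip_count", "observed_sw_ms")
    p <- 2L
  }
  miss <- setdiff(need, names(samples))
  if (length(miss) > 0) {
    stop("timing samples lack column(s): ", paste(miss, collapse = ", "))
  }
  ok <- stats::complete.cases(samples[need])
  samples <- samples[ok, , drop = FALSE]
  if (nrow(samples) < p + 2L) {
    stop(sprintf("under-determined fit: %d usable samples for %d parameters (need >= %d)",
                 nrow(samples), p, p + 2L))
  }
  if (any(samples[[need[length(need)]]] < 0)) {
    stop("observed times must be >= 0")
  }
  fml <- if (which == "hardware") {
    observed_hw_ms ~ n + total_subparts
  } else {
    observed_sw_ms ~ sum_trip_count
  }
  fit <- stats::lm(fml, data = samples)
  cf <- stats::coef(fit)
  if (anyNA(cf)) stop("collinear features: coefficients not identifiable")
  rms <- sqrt(mean(stats::residuals(fit)^2))
  if (which == "hardware") {
    coeffs$K1 <- unname(cf["n"])
    coeffs$E <- unname(cf["total_subparts"])
    coeffs$C1 <- unname(cf["(Intercept)"])
    # keep II as metadata; re-derive the clock period implied by the fit
    if (coeffs$II > 0 && coeffs$E > 0) coeffs$T_clock <- coeffs$E / coeffs$II
    coeffs$residual_rms_hw <- rms
  } else {
    coeffs$K2 <- unname(cf["sum_trip_count"])
    coeffs$C2 <- unname(cf["(Intercept)"])
    coeffs$residual_rms_sw <- rms
  }
  coeffs
}

#' Generate synthetic timing samples from a known ground-truth model
#'
#' Draws feature vectors and produces observed times from a ground-truth
#' [perf_coeffs()] plus multiplicative Gaussian noise
#' (`observed = truth * (1 + rnorm(sd = noise_sd))`, clamped at 0).
#' Deterministic calibration data for tests and examples; a wall-clock
#' sampler ([time_software_chaining()]) exists for real calibration.
#'
#' @param n_samples number of samples.
#' @param truth ground-truth [perf_coeffs()].
#' @param noise_sd multiplicative noise standard deviation (0 = noise-free).
#' @param seed RNG seed.
#' @param n_range,subpart_rate,trip_rate feature-generation knobs: anchor
#'   counts are uniform over `n_range`; `total_subparts` and
#'   `sum_trip_count` scale with `n` by these factors (jittered).
#' @return A timing-sample `data.frame` with columns `task_id`, `n`,
#'   `total_subparts`, `sum_trip_count`, `observed_hw_ms`,
#'   `observed_sw_ms`.
#' @export
simulate_timing_samples <- function(n_samples, truth = perf_coeffs(),
                                    noise_sd = 0, seed = 1L,
                                    n_range = c(50, 5000),
                                    subpart_rate = 2, trip_rate = 60) {
  n_samples <- check_count(n_samples, "n_samples", min = 1)
  with_local_seed(seed, {
    n <- sample(seq(n_range[1], n_range[2]), n_samples, replace = TRUE)
    subparts <- round(subpart_rate * n * stats::runif(n_samples, 0.5, 1.5))
    trips <- round(trip_rate * n * stats::runif(n_samples, 0.5, 1.5))
    hw <- truth$K1 * n + truth$E * subparts + truth$C1
    sw <- truth$K2 * trips + truth$C2
    if (noise_sd > 0) {
      hw <- pmax(0, hw * (1 + stats::rnorm(n_samples, 0, noise_sd)))
      sw <- pmax(0, sw * (1 + stats::rnorm(n_samples, 0, noise_sd)))
    }
    data.frame(task_id = sprintf("s%05d", seq_len(n_samples)),
               n = n, total_subparts = subparts, sum_trip_count = trips,
               observed_hw_ms = hw, observed_sw_ms = sw)
  })
}

#' Measure software chaining wall-clock time for calibration
#'
#' Runs [chain_scores()] on each task and records elapsed wall-clock time,
#' yielding real `observed_sw_ms` samples for [fit_coeffs()]. Hardware
#' columns are left `NA` (no accelerator in this environment).
#'
#' @param tasks list of [chain_task()] objects.
#' @param params a [chaining_params()].
#' @return A timing-sample `data.frame`.
#' @export
time_software_chaining <- function(tasks, params = chaining_params()) {
  p <- params; p$H <- Inf
  rows <- lapply(tasks, function(t) {
    el <- system.time(dp <- chain_scores(t, p))[["elapsed"]] * 1000
    hwf <- hw_features(t, H = if (is.finite(params$H)) params$H else 512,
                       P = params$P)
    data.frame(task_id = t$task_id, n = hwf$n,
               total_subparts = hwf$total_subparts,
               sum_trip_count = sum(dp$trip_count),
               observed_hw_ms = NA_real_, observed_sw_ms = el)
  })
  do.call(rbind, rows)
}

#' Write / read timing-sample tables
#'
#' Tab-separated with columns `task_id`, `n`, `total_subparts`,
#' `sum_trip_count`, `observed_hw_ms`, `observed_sw_ms`; an empty field is
#' a missing observation.
#'
#' @param samples timing-sample `data.frame`.
#' @param path file path.
#' @export
write_timing_table <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(NULL)
}

#' @rdname write_timing_table
#' @export
read_timing_table <- function(path) {
  utils::read.delim(path, na.strings = "", stringsAsFactors = FALSE)
}

#' Write / read a coefficients file
#'
#' Flat key-value text: `K1`, `E`, `C1`, `K2`, `C2`, `II`, `T_clock`,
#' `residual_rms_hw`, `residual_rms_sw`, one `key<TAB>value` per line.
#'
#' @param coeffs a [perf_coeffs()].
#' @param path file path.
#' @export
write_coeffs <- function(coeffs, path) {
  keys <- c("K1", "E", "C1", "K2", "C2", "II", "T_clock",
            "residual_rms_hw", "residual_rms_sw")
  writeLines(sprintf("%s\t%.17g", keys,
                     vapply(keys, function(k) as.numeric(coeffs[[k]]),
                            numeric(1))),
             path)
  invisible(NULL)
}

#' @rdname write_coeffs
#' @export
read_coeffs <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines[nzchar(lines)], "\t", fixed = TRUE)
  vals <- stats::setNames(vapply(parts, function(p) {
    if (p[2] == "NA") NA_real_ else as.numeric(p[2])
  }, numeric(1)),
                          vapply(parts, `[[`, character(1), 1))
  perf_coeffs(K1 = vals[["K1"]], E = vals[["E"]], C1 = vals[["C1"]],
              K2 = vals[["K2"]], C2 = vals[["C2"]],
              II = vals[["II"]], T_clock = vals[["T_clock"]],
              residual_rms_hw = vals[["residual_rms_hw"]],
              residual_rms_sw = vals[["residual_rms_sw"]])
}
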