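---
title: "Bounded-lookback chaining and prediction-based accelerator scheduling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bounded-lookback chaining and prediction-based accelerator scheduling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chainaccel)
```

## The model

### Anchors and the chaining recurrence

An anchor records one exact seed match: the 0-based *inclusive end*
positions of the matching span on the reference (`x`) and the query (`y`),
plus the span `w`. A chaining task is the `(x, y)`-sorted, deduplicated
anchor set of one read/strand. For anchor `i` with candidate predecessor
`j` the DP contribution is

$$f(i) = \max\Big(w_i,\; \max_j f(j) + \alpha(j,i) - \beta(j,i)\Big)$$

with $\alpha = \min(y_i - y_j,\; x_i - x_j,\; w_i)$ and, writing
$d = |(y_i - y_j) - (x_i - x_j)|$,
$\beta = \texttt{gap\_scale}\cdot\bar w\cdot d + \tfrac12\log_2 d$
($\beta(0) = 0$ by definition; the log term is undefined at zero). A
predecessor is eligible only if it strictly precedes on both axes, within
`max_dist_x` / `max_dist_y`, and $d \le$ `bandwidth`. This is the standard
chaining recurrence of minimizer-based long-read mappers; the accelerator
work this package models changes *how* the inner maximum is evaluated, not
the recurrence itself, so the recurrence had to be pinned down here
explicitly.

Assumptions worth naming: $\bar w$ is the per-task arithmetic mean span
(rounded, floored at 1) — the recurrence needs *some* per-task scale for
the linear gap term and the source material does not specify one; strand
is handled entirely at anchor-extraction time by flipping reverse-strand
read coordinates, so the DP itself is single-cased.

### Three engines, one answer

* `chain_scores(H = Inf)` — exact: for each anchor, predecessors from
  `i−1` down to the first index within `max_dist_x`, found by binary
  search over the sorted `x`.
* `chain_scores(H = h)` — bounded lookback: at most `H` predecessors are
  examined (`trip_count[i] = i − max(st_i, i−H)`), the fixed "maximum
  inner-loop trip count" of a hardware pipeline. Too small an `H` silently
  truncates chains.
* `chain_scores_subpartitioned()` — the same bounded candidate range
  walked in consecutive slices of at most `P` candidates with a running
  maximum carried across slices. This mirrors the restructured hardware
  inner loop that makes large `H` affordable in logic resources; by
  construction (and by test) it is bit-for-bit identical to the flat
  bounded loop, and it additionally reports the number of sub-partitions
  executed per anchor — the unit of the hardware time model.

Tie-breaks are deterministic everywhere: among equal-scoring predecessors
the *nearest* wins (first met scanning `j` downward — for the
sub-partitioned engine, the earliest slice, enforced by a strict `>` on
the carried maximum); `parent[i]` is set only when a predecessor strictly
beats `w_i`, so an exact tie with the anchor's own span starts a new chain.

Backtracking visits anchors in descending `f`, follows parents while
unclaimed, and scores a truncated chain as `f(terminal) − f(collision)` so
a shared prefix is never counted twice. Chains failing
`min_score`/`min_cnt` are dropped but their anchors stay consumed, keeping
output chains anchor-disjoint.

### Runtime predictors

Per-task hardware and software chaining times are modelled as

$$T_{hw} = K_1 n + (II \cdot T_{clock})\,\text{total\_subparts} + C_1,
\qquad
T_{sw} = K_2 \sum_i \text{trip\_count}_i + C_2 .$$

`total_subparts` $= \sum_i \lceil \min(i, H)/P \rceil$ uses the full
`min(i, H)` lookback, not the binary-searched window: a fixed-bound
pipeline cannot skip ahead, while software can, which is exactly why the
two cost drivers differ. The $K_1 n$ term models per-task data transfer —
tasks are shipped to the device one at a time, so transfer cost is linear
in the task's anchor count with no bulk-transfer mode. Only the product
$E = II \cdot T_{clock}$ is identifiable from timing data, so `fit_coeffs()`
estimates $(K_1, E, C_1)$ and $(K_2, C_2)$ by ordinary least squares and
stores `II`/`T_clock` as metadata. Fitted intercepts may be negative;
predictions clamp at zero.

Tests calibrate against synthetic timing samples from a known ground-truth
model plus multiplicative Gaussian noise — deterministic, and the
generating coefficients are the oracle. `time_software_chaining()` exists
for real wall-clock calibration of the software side; no hardware exists
in this environment to time.

### The placement policy and its simulator

`simulate_schedule()` is a discrete-event model of the execution flow:
`Y` threads (default 8, a typical mapping run) each own a round-robin
share of the tasks; `N` hardware kernels (default 1) each own a FIFO
access queue. At a chaining task the thread predicts $T_{hw}$ and
$T_{sw}$; if $T_{sw} \le T_{hw}$ the task runs in software on the same
thread; otherwise the thread searches for a kernel with
$T_{wait} + T_{hw} < T_{sw}$, where $T_{wait}$ is the kernel's remaining
service plus the predicted durations of everything already queued, and
queues the task there (minimal-wait kernel, ties to the lowest index — the
natural greedy refinement of "a kernel where the total time is less than
$T_{sw}$"); if none qualifies, software.

Design choices the source flow diagram leaves open, resolved here:
offload is *blocking* (the issuing thread waits for its result — the
downstream mapping stages need the chain scores), simultaneous events are
ordered by (time, thread index), and the wait estimate ignores tasks other
threads may enqueue after the decision instant — FIFO guarantees later
arrivals cannot delay earlier ones, which is also why, under exact
predictions, every offloaded task's wait-plus-service provably stays below
its software time and the accelerated makespan can never exceed the
software-only one (acceptance criterion 6). Per-task `pre_ms`/`post_ms`
stand in for the seeding/alignment/output stages the simulator does not
model.

## The synthetic world

`generator_config()` defaults describe one fixed stated world: tasks of
64–256 anchors, two planted co-linear chains (consecutive anchors
advancing by `span_k = 15` ± jitter 5 on each axis), 35% uniform noise
over a 20 kb coordinate range — a caricature of minimizer anchor sets from
noisy reads of a few tens of kilobases against a local reference window.
These values were chosen once, before any acceptance outcome was seen, and
are not tuned. What the generator does *not* emulate: repeat-induced
anchor clumps, coverage-dependent anchor density, chimeric reads,
homopolymer artefacts. A green concordance test therefore establishes the
*mechanism* (bounded H truncates chains; sub-partitioning is lossless; the
ordering over H) — not any end-to-end mapping accuracy number, which would
require a full mapper, a reference genome and read simulation.

On the seeded 500-task acceptance batch the bounded engine at H = 64
keeps 98.8% of top chains identical to exact chaining (mean score ratio
0.99992) while H = 512 and H = 1024 are exact on every task — the
chain-level echo of "H = 64 degrades accuracy; larger H restores it".
These numbers are recomputed by the test suite, not quoted from anywhere.

## Numerical choices

* Scores are doubles; the DP and the brute-force oracle accumulate
  `f[j] + (alpha - beta)` in the same association order so exact equality
  between them is meaningful.
* `beta(0) = 0` is defined explicitly; eligibility is strict (`x_j < x_i`,
  `y_j < y_i`), preventing zero-advance self-stacking.
* Minimizer keys are exact doubles (canonical 2-bit encoding, `k ≤ 26`);
  window ties go to the leftmost position; sequences with fewer than
  `wmin` k-mers have no complete window and yield no minimizers.
* Monotonicity assertions in tests use a `1e-12` slack where two
  *different* computations are compared, and exact identity where the same
  arithmetic path is required to agree (`H ≥ n−1` convergence,
  sub-partition invariance, determinism re-runs).
* All randomness flows through per-call seeds and a local RNG scope that
  restores the caller's `.Random.seed`.

## Limitations

* Chain-level concordance does not quantify end-to-end mapping accuracy;
  the link is qualitative by design.
* The time predictors assume transfer cost linear in `n` alone and ignore
  PCIe contention and DMA batching; `perf_coeffs()` defaults are
  order-of-magnitude engineering values, not measured constants — refit
  them for any real deployment.
* The scheduler models blocking offload only; a polling/work-stealing
  thread model would need a different dominance argument.
* Seeding implements plain canonical minimizers: no occurrence filtering
  of repetitive seeds, no homopolymer compression, no FASTQ qualities.
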