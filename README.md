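# chainaccel

Co-linear anchor chaining for long-read sequence mapping, with the
bounded-lookback dynamic-programming variants used by fixed-trip-count
hardware accelerators, linear-regression predictors of per-task chaining
time, and a discrete-event simulator of prediction-based CPU/accelerator
task placement.

## The problem

Minimizer-based long-read mappers spend a large share of their runtime in
*chaining*: given anchors (exact seed matches, each an end position `x` on
the reference, `y` on the query, and a span `w`), select a high-scoring
co-linear subset by the dynamic program

    f(i) = max( w_i ,  max_{j < i, eligible} f(j) + α(j,i) − β(j,i) )

with `α = min(y_i−y_j, x_i−x_j, w_i)` and gap cost
`β = gap_scale · mean_span · d + ½·log₂ d` for `d = |(y_i−y_j)−(x_i−x_j)|`
(`β(0) = 0`), a predecessor being eligible when it strictly precedes the
anchor on both axes within `max_dist` and bandwidth ceilings.

Hardware pipelines cannot scan an unbounded predecessor window: they fix a
**maximum inner-loop trip count H**. A small H (e.g. 64) silently truncates
chains and degrades mapping accuracy; raising H naively blows up the logic
footprint. Restructuring the inner loop into **sub-partitions of size P**
(a running maximum carried across slices) makes H = 512–1024 feasible while
provably returning the same scores as the flat bounded loop. Whether a task
should go to the accelerator at all is decided per task from two linear
time predictors,

    T_hw = K1·n + (II·T_clock)·total_subparts + C1        (transfer + execution)
    T_sw = K2·Σᵢ trip_countᵢ + C2

and a task is offloaded only to a kernel whose predicted queue wait keeps
`T_wait + T_hw < T_sw`; otherwise it runs on the issuing CPU thread.

`chainaccel` implements all of this at desk scale: exact, bounded and
sub-partitioned chaining engines with a brute-force oracle, a planted-chain
synthetic task generator, minimizer seeding from FASTA, OLS calibration of
the predictors, a deterministic discrete-event simulator of the placement
policy (Y threads, N ≪ Y kernels with FIFO access queues), and chain-level
concordance analysis between bounded and exact chaining. It is aimed at
people studying accelerator offloading of sequence-mapping kernels without
needing the hardware on their desk.

## Worked example

```r
library(chainaccel)

tasks <- generate_tasks(generator_config(n_tasks = 100, seed = 42))
tasks[[1]]
#> <chain_task 'task0001'> 112 anchors, strand +

params <- chaining_params(H = 64)              # bounded-lookback engine
dp     <- chain_scores(tasks[[1]], params)
chains <- backtrack_chains(tasks[[1]], dp, params)
cat(sprintf("top chain: score %.2f over %d anchors\n",
            chains[[1]]$score, chains[[1]]$n_anchors))
#> top chain: score 428.33 over 38 anchors

# How much does the trip-count bound cost, chain-level?
rows <- do.call(rbind, lapply(tasks, compare_bounded,
                              params = chaining_params(),
                              H_list = c(16, 64, 512)))
aggregate_concordance(rows)
#>     H n_tasks mean_score_ratio frac_identical_top_chain frac_ratio_one
#> 1  16     100        0.9994699                     0.94           0.94
#> 2  64     100        0.9997003                     0.98           0.98
#> 3 512     100        1.0000000                     1.00           1.00

# Prediction-based placement: 8 threads sharing one hardware kernel
sim <- simulate_schedule(tasks, sim_config(Y = 8, N = 1,
                                           coeffs = perf_coeffs(),
                                           seed = 1), chaining_params())
sim
#> <sim_result> 100 tasks (9 hardware, 91 software), makespan 0.560 ms
#>   kernel utilization: 88.9%
```

Reading: at H = 16 only 94% of tasks keep their exact top chain and the
mean best-score ratio is 0.99947; H = 512 is indistinguishable from exact
chaining on this workload. In the simulation the policy offloads the 9
largest tasks (where predicted hardware time, including queue wait, beats
software time) and keeps the single kernel ~89% busy.

A command-line front end covers the same pipeline:

```sh
chainaccel generate --config n_tasks=100 --seed 42 --out anchors.tsv
chainaccel chain --anchors anchors.tsv --engine subpart -H 512 -P 64 --out chains.tsv
chainaccel compare --anchors anchors.tsv -H 64,512,1024 --out concordance.tsv
chainaccel fit --timings timings.tsv --which both --out coeffs.txt
chainaccel simulate --anchors anchors.tsv --threads 8 --kernels 1 --seed 1 --report sim.tsv
chainaccel seed --ref ref.fa --reads reads.fa -k 15 -w 10 --out seeded.tsv
```

(the script installs under `exec/chainaccel` in the package library; run it
via `Rscript` or add it to `PATH`).

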