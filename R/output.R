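# Chain output: TSV and PAF writers.

#' Write chains as a TSV table
#'
#' Columns: `task_id`, `chain_rank`, `score`, `n_anchors`, `first_x`,
#' `last_x`, `first_y`, `last_y`, `anchor_indices` (comma-separated,
#' 1-based into the task's sorted anchor table).
#'
#' @param chains_by_task named list: for each task, the chain list from
#'   [backtrack_chains()].
#' @param tasks the corresponding list of [chain_task()] objects.
#' @param path file path or connection.
#' @export
write_chain_table <- function(chains_by_task, tasks, path) {
  names(tasks) <- vapply(tasks, `[[`, character(1), "task_id")
  rows <- list()
  for (id in names(chains_by_task)) {
    chains <- chains_by_task[[id]]
    a <- tasks[[id]]$anchors
    for (r in seq_along(chains)) {
      ch <- chains[[r]]
      idx <- ch$anchor_indices
      rows[[length(rows) + 1L]] <- data.frame(
        task_id = id, chain_rank = r, score = ch$score,
        n_anchors = ch$n_anchors,
        first_x = a$x[idx[1]], last_x = a$x[idx[length(idx)]],
        first_y = a$y[idx[1]], last_y = a$y[idx[length(idx)]],
        anchor_indices = paste(idx, collapse = ","))
    }
  }
  tab <- do.call(rbind, c(list(data.frame(
    task_id = character(0), chain_rank = integer(0), score = numeric(0),
    n_anchors = integer(0), first_x = integer(0), last_x = integer(0),
    first_y = integer(0), last_y = integer(0),
    anchor_indices = character(0))), rows))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}

#' Write chains in PAF format
#'
#' Standard 12-column PAF, one line per chain. Anchor end positions are
#' converted to 0-based half-open intervals (`start = end - w + 1`, open
#' `end = end + 1`). The residue-matches column is the sum of anchor
#' spans capped at the block length; MAPQ is fixed at 255 (unassessed).
#'
#' @param chains chain list from [backtrack_chains()] for one task.
#' @param task the [chain_task()] the chains index into.
#' @param query_name,query_length,target_name,target_length PAF identity
#'   columns; `query_length` defaults to the task's.
#' @param path file path or connection (one line per chain).
#' @export
write_paf <- function(chains, task, query_name, target_name,
                      target_length, query_length = task$query_length,
                      path) {
  a <- task$anchors
  lines <- vapply(chains, function(ch) {
    idx <- ch$anchor_indices
    first <- idx[1]; last <- idx[length(idx)]
    qs <- a$y[first] - a$w[first] + 1L
    qe <- a$y[last] + 1L
    ts <- a$x[first] - a$w[first] + 1L
    te <- a$x[last] + 1L
    blk <- max(qe - qs, te - ts)
    nmatch <- min(sum(a$w[idx]), blk)
    paste(query_name, query_length, qs, qe, task$strand,
          target_name, target_length, ts, te, nmatch, blk, 255L,
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(NULL)
}
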