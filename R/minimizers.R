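# Minimizer seeding: sample the smallest-keyed k-mer from every window of
# wmin consecutive k-mers of a sequence, then anchor reads to a reference
# by shared minimizer keys. Keys are canonical: the 2-bit encoding
# (A=0, C=1, G=2, T=3) of the lexicographically smaller of the k-mer and
# its reverse complement, with no hash scramble, so every key is
# invertible and testable. Ties within a window go to the leftmost
# position.

BASE_CODE <- c(A = 0, C = 1, G = 2, T = 3)

encode_bases <- function(sequence) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  unname(BASE_CODE[chars])            # N and anything else -> NA
}

# Forward, reverse-complement and canonical keys for every k-mer of the
# coded sequence. k-mers containing N have NA keys. Keys are doubles
# (exact to 2^53), so k up to 26 is safe.
kmer_keys <- function(codes, k) {
  L <- length(codes)
  nk <- L - k + 1L
  if (nk < 1L) {
    return(list(fwd = numeric(0), rc = numeric(0), canonical = numeric(0),
                strand = character(0)))
  }
  pw <- 4^((k - 1L):0)
  fwd <- numeric(nk)
  rc <- numeric(nk)
  rc_pw <- rev(pw)
  for (i in seq_len(nk)) {
    win <- codes[i:(i + k - 1L)]
    if (anyNA(win)) {
      fwd[i] <- NA_real_; rc[i] <- NA_real_
    } else {
      fwd[i] <- sum(win * pw)
      rc[i] <- sum((3 - win) * rc_pw)
    }
  }
  canonical <- pmin(fwd, rc)
  strand <- rep(NA_character_, nk)
  ok <- !is.na(fwd)
  strand[ok] <- ifelse(fwd[ok] <= rc[ok], "+", "-")
  list(fwd = fwd, rc = rc, canonical = canonical, strand = strand)
}

#' Minimizers of a nucleotide sequence
#'
#' For every window of `wmin` consecutive k-mers, reports the k-mer with
#' the smallest canonical key; a position selected by several overlapping
#' windows is reported once. k-mers containing `N` are skipped (a window
#' whose k-mers are all skipped yields nothing).
#'
#' @param sequence nucleotide string over `A,C,G,T,N` (case-insensitive).
#' @param k k-mer size (1--26).
#' @param wmin window size in k-mers (>= 1).
#' @return A `data.frame` with one row per minimizer: `pos` (0-based start
#'   of the k-mer), `key` (canonical 2-bit key), `strand` (`"+"` if the
#'   forward orientation won, `"-"` otherwise), ordered by position.
#'   Sequences shorter than `k` give zero rows.
#' @examples
#' minimizers("ACGTACGTAC", k = 3, wmin = 2)
#' @export
minimizers <- function(sequence, k = 15, wmin = 10) {
  k <- check_count(k, "k", min = 1)
  if (k > 26) stop_field("k", "must be <= 26 (exact 2-bit keys)")
  wmin <- check_count(wmin, "wmin", min = 1)
  codes <- encode_bases(sequence)
  keys <- kmer_keys(codes, k)
  nk <- length(keys$canonical)
  empty <- data.frame(pos = integer(0), key = numeric(0),
                      strand = character(0))
  if (nk == 0) return(empty)
  picked <- logical(nk)
  # Monotonic-deque sliding-window minimum over k-mer keys (NA = skipped).
  dq <- integer(0)                    # candidate indices, keys increasing
  for (i in seq_len(nk)) {
    if (!is.na(keys$canonical[i])) {
      while (length(dq) > 0 &&
             keys$canonical[dq[length(dq)]] > keys$canonical[i]) {
        dq <- dq[-length(dq)]
      }
      dq <- c(dq, i)
    }
    while (length(dq) > 0 && dq[1] <= i - wmin) dq <- dq[-1]
    if (i >= wmin && length(dq) > 0) picked[dq[1]] <- TRUE
  }
  sel <- which(picked)
  data.frame(pos = sel - 1L, key = keys$canonical[sel],
             strand = keys$strand[sel])
}

#' Extract anchors for a read against a reference by shared minimizers
#'
#' Indexes the reference minimizers by canonical key; every read minimizer
#' with a matching key yields an anchor `(x = reference k-mer end,
#' y = read k-mer end, w = k)`. Matches where the two orientations
#' disagree are reverse-strand: their read coordinate is flipped
#' (`y = read_length - 1 - start`) so chaining is forward-monotone on both
#' strands.
#'
#' @param reference,read nucleotide strings.
#' @param k,wmin minimizer parameters, see [minimizers()].
#' @param task_id base identifier for the returned tasks.
#' @return A list with components `"+"` and `"-"`: one [chain_task()] per
#'   strand (tasks may be empty).
#' @export
extract_anchors <- function(reference, read, k = 15, wmin = 10,
                            task_id = "read") {
  ref_min <- minimizers(reference, k, wmin)
  read_min <- minimizers(read, k, wmin)
  read_len <- nchar(read)
  hits <- merge(read_min, ref_min, by = "key",
                suffixes = c("_read", "_ref"))
  same <- hits$strand_read == hits$strand_ref
  mk_task <- function(sel, strand) {
    h <- hits[sel, , drop = FALSE]
    if (strand == "+") {
      x <- h$pos_ref + k - 1L
      y <- h$pos_read + k - 1L
    } else {
      x <- h$pos_ref + k - 1L
      y <- read_len - 1L - h$pos_read
    }
    keep <- !duplicated(cbind(x, y))
    chain_task(task_id = paste0(task_id, strand),
               anchors = anchors(x = x[keep], y = y[keep], w = k),
               query_length = read_len, strand = strand)
  }
  list("+" = mk_task(same, "+"), "-" = mk_task(!same, "-"))
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper over `Biostrings::readDNAStringSet` returning plain named
#' character strings (multi-record, wrapped lines, case-insensitive).
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))   # first token of the header
  seqs
}
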