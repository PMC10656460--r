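# Independent brute-force oracles. These deliberately avoid the package's
# internal encodings: k-mers are handled as strings and window minima are
# taken with which.min over explicit slices.

oracle_revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

oracle_key <- function(kmer) {
  codes <- match(strsplit(kmer, "")[[1]], c("A", "C", "G", "T")) - 1
  if (anyNA(codes)) return(NA_real_)
  sum(codes * 4^(rev(seq_along(codes)) - 1))
}

# Canonical (key, strand) of one k-mer; forward wins ties.
oracle_canonical <- function(kmer) {
  fwd <- oracle_key(kmer)
  rc <- oracle_key(oracle_revcomp(kmer))
  if (is.na(fwd)) return(list(key = NA_real_, strand = NA_character_))
  if (fwd <= rc) list(key = fwd, strand = "+") else
    list(key = rc, strand = "-")
}

# O(L * wmin) sliding-window minimizer oracle: every complete window of
# wmin k-mers reports its smallest canonical key (leftmost tie), each
# position once. k-mers containing N are skipped.
oracle_minimizers <- function(sequence, k, wmin) {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  nk <- L - k + 1
  out <- data.frame(pos = integer(0), key = numeric(0),
                    strand = character(0))
  if (nk < 1) return(out)
  cano <- lapply(seq_len(nk), function(i) {
    oracle_canonical(substr(sequence, i, i + k - 1))
  })
  keys <- vapply(cano, function(c) c$key, numeric(1))
  strands <- vapply(cano, function(c) {
    if (is.na(c$key)) NA_character_ else c$strand
  }, character(1))
  picked <- integer(0)
  for (s in seq_len(nk - wmin + 1)) {
    win <- s:(s + wmin - 1)
    valid <- win[!is.na(keys[win])]
    if (length(valid) == 0) next
    picked <- c(picked, valid[which.min(keys[valid])])
  }
  picked <- sort(unique(picked))
  data.frame(pos = picked - 1L, key = keys[picked],
             strand = strands[picked])
}

# Exhaustive shared-minimizer anchor oracle: the cross product of
# reference and read minimizers with equal canonical keys, split by
# orientation agreement, in end coordinates (reverse-strand read
# positions flipped).
oracle_shared_anchors <- function(reference, read, k, wmin) {
  rm <- oracle_minimizers(reference, k, wmin)
  qm <- oracle_minimizers(read, k, wmin)
  L <- nchar(read)
  plus <- data.frame(x = integer(0), y = integer(0))
  minus <- data.frame(x = integer(0), y = integer(0))
  for (i in seq_len(nrow(qm))) {
    hit <- rm[rm$key == qm$key[i], , drop = FALSE]
    if (nrow(hit) == 0) next
    same <- hit$strand == qm$strand[i]
    if (any(same)) {
      plus <- rbind(plus, data.frame(x = hit$pos[same] + k - 1,
                                     y = qm$pos[i] + k - 1))
    }
    if (any(!same)) {
      minus <- rbind(minus, data.frame(x = hit$pos[!same] + k - 1,
                                       y = L - 1 - qm$pos[i]))
    }
  }
  list("+" = unique(plus), "-" = unique(minus))
}

# Random DNA string.
random_dna <- function(L, with_n = FALSE) {
  alphabet <- if (with_n) c("A", "C", "G", "T", "N") else
    c("A", "C", "G", "T")
  paste(sample(alphabet, L, replace = TRUE), collapse = "")
}
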