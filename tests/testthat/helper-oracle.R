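# Independent oracles used against the package's own code paths.

SYM <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "-")

# Best global affine-gap score by exhaustive recursion over every alignment.
# A gap run of length k costs open + (k-1) * extend; `last` tracks which row
# the previous column gapped so run continuations are charged `extend`.
oracle_best_score <- function(a, b, scheme = scoring_scheme()) {
  sa <- strsplit(a, "")[[1]]
  sb <- strsplit(b, "")[[1]]
  sub <- scheme$substitution_matrix
  go <- scheme$gap_open
  ge <- scheme$gap_extend
  na <- length(sa)
  nb <- length(sb)
  rec <- function(i, j, last) {
    if (i > na && j > nb) return(0)
    best <- -Inf
    if (i <= na && j <= nb)
      best <- max(best, sub[sa[i], sb[j]] + rec(i + 1L, j + 1L, 0L))
    if (i <= na)
      best <- max(best, (if (last == 1L) ge else go) + rec(i + 1L, j, 1L))
    if (j <= nb)
      best <- max(best, (if (last == 2L) ge else go) + rec(i, j + 1L, 2L))
    best
  }
  rec(1L, 1L, 0L)
}

# Direct column tally of one alignment in target coordinates, written with
# table() rather than the package's tabulate/match path.
manual_tally <- function(aln, stp_id) {
  m <- do.call(rbind, strsplit(unname(aln$rows), ""))
  rownames(m) <- aln$ids
  cols <- which(m[stp_id, ] != "-")
  others <- m[setdiff(rownames(m), stp_id), cols, drop = FALSE]
  counts <- vapply(seq_along(cols), function(k) {
    as.integer(table(factor(others[, k], levels = SYM)))
  }, integer(21L))
  rownames(counts) <- SYM
  counts
}
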