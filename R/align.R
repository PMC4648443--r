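#' Scoring scheme for global protein alignment
#'
#' Bundles a symmetric 20x20 substitution matrix with affine gap penalties.
#' A gap run of length k costs `gap_open + (k - 1) * gap_extend`; terminal
#' gaps are penalized like internal ones. Defaults are BLOSUM62 with
#' open -10 / extend -1.
#'
#' @param substitution_matrix Symmetric numeric matrix with the 20 standard
#'   amino acids as dimnames; defaults to BLOSUM62.
#' @param gap_open,gap_extend Negative gap penalties with
#'   `gap_open <= gap_extend < 0`.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(substitution_matrix = blosum62(),
                           gap_open = -10, gap_extend = -1) {
  m <- substitution_matrix[AA_ALPHABET, AA_ALPHABET]
  if (!isTRUE(all.equal(m, t(m))))
    stop("substitution matrix must be symmetric")
  if (!(gap_open <= gap_extend && gap_extend < 0))
    stop("need gap_open <= gap_extend < 0")
  structure(list(substitution_matrix = m, gap_open = gap_open,
                 gap_extend = gap_extend), class = "scoring_scheme")
}

#' BLOSUM62 substitution scores for the 20 standard amino acids
#'
#' @return A symmetric 20x20 integer matrix in alphabetical residue order.
#' @export
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
}

new_alignment <- function(ids, rows) {
  lens <- nchar(rows)
  if (length(unique(lens)) != 1L) stop("alignment rows differ in length")
  mat <- do.call(rbind, strsplit(rows, ""))
  if (any(colSums(mat != GAP) == 0L)) stop("alignment contains all-gap column")
  structure(list(ids = ids, rows = setNames(rows, ids)), class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("<alignment> %d row(s) x %d column(s)\n",
              length(x$rows), nchar(x$rows[[1]])))
  invisible(x)
}

alignment_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(unname(aln$rows), ""))
  rownames(m) <- aln$ids
  m
}

degap <- function(s) gsub("-", "", s, fixed = TRUE)

#' Optimal global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch/Gotoh global alignment. The traceback is deterministic:
#' ties are resolved preferring a residue pair, then a gap in `b`, then a
#' gap in `a`.
#'
#' @param a,b [sequence_record()] objects (or residue strings, which are
#'   given ids "a"/"b").
#' @param scheme A [scoring_scheme()].
#' @return A list with elements `alignment` (class `alignment`) and `score`.
#' @export
pairwise_align <- function(a, b, scheme = scoring_scheme()) {
  if (is.character(a)) a <- sequence_record("a", a)
  if (is.character(b)) b <- sequence_record("b", b)
  sa <- strsplit(a$residues, "")[[1]]
  sb <- strsplit(b$residues, "")[[1]]
  S <- cell_scores(sa, sb, scheme$substitution_matrix)
  res <- gotoh_core(S, scheme$gap_open, scheme$gap_extend)
  row_a <- ifelse(res$a > 0L, c(GAP, sa)[res$a + 1L], GAP)
  row_b <- ifelse(res$b > 0L, c(GAP, sb)[res$b + 1L], GAP)
  aln <- new_alignment(c(a$id, b$id),
                       c(paste(row_a, collapse = ""),
                         paste(row_b, collapse = "")))
  list(alignment = aln, score = res$score)
}

# substitution scores per cell; X scores 0 against everything
cell_scores <- function(sa, sb, submat) {
  full <- matrix(0, 21, 21, dimnames = list(c(AA_ALPHABET, UNKNOWN),
                                            c(AA_ALPHABET, UNKNOWN)))
  full[AA_ALPHABET, AA_ALPHABET] <- submat
  full[sa, sb, drop = FALSE]
}

fractional_identity <- function(aln) {
  m <- alignment_matrix(aln)
  same <- m[1, ] == m[2, ] & m[1, ] != GAP
  sum(same) / ncol(m)
}

#' Progressive multiple sequence alignment
#'
#' Builds a UPGMA guide tree from pairwise alignment distances
#' (1 - fractional identity) and merges alignments by profile-profile
#' global alignment in guide-tree order. Fully deterministic: UPGMA ties
#' are broken by the lexicographically smallest id pair, and the
#' profile-merge traceback uses the pairwise tie-break rules.
#'
#' @param library A [sequence_library()] with at least two records.
#' @param scheme A [scoring_scheme()].
#' @return An `alignment` whose rows are in the library's input order.
#' @export
progressive_msa <- function(library, scheme = scoring_scheme()) {
  n <- length(library)
  if (n < 2L) stop("progressive alignment needs at least 2 sequences")
  recs <- library$records
  ids <- lib_ids(library)
  if (n == 2L)
    return(pairwise_align(recs[[1]], recs[[2]], scheme)$alignment)

  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    pa <- pairwise_align(recs[[i]], recs[[j]], scheme)
    D[i, j] <- D[j, i] <- 1 - fractional_identity(pa$alignment)
  }

  # UPGMA with deterministic tie-break; each cluster carries its alignment
  clusters <- lapply(seq_len(n), function(i) {
    list(key = ids[i], size = 1L, ids = ids[i],
         rows = setNames(recs[[i]]$residues, ids[i]))
  })
  dist <- D
  rownames(dist) <- colnames(dist) <- vapply(clusters, `[[`, character(1), "key")
  while (length(clusters) > 1L) {
    k <- length(clusters)
    best <- NULL
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      ki <- clusters[[i]]$key; kj <- clusters[[j]]$key
      pair <- sort(c(ki, kj))
      if (is.null(best) || dist[ki, kj] < best$d - 1e-12 ||
          (abs(dist[ki, kj] - best$d) <= 1e-12 &&
           (pair[1] < best$pair[1] ||
            (pair[1] == best$pair[1] && pair[2] < best$pair[2])))) {
        best <- list(i = i, j = j, d = dist[ki, kj], pair = pair)
      }
    }
    ci <- clusters[[best$i]]; cj <- clusters[[best$j]]
    merged_rows <- merge_profiles(ci$rows, cj$rows, scheme)
    merged <- list(key = min(ci$key, cj$key), size = ci$size + cj$size,
                   ids = c(ci$ids, cj$ids), rows = merged_rows)
    # size-weighted average distances to the merged cluster
    others <- setdiff(seq_len(k), c(best$i, best$j))
    newd <- vapply(others, function(o) {
      ko <- clusters[[o]]$key
      (dist[ci$key, ko] * ci$size + dist[cj$key, ko] * cj$size) /
        (ci$size + cj$size)
    }, numeric(1))
    if (length(others)) {
      keep <- vapply(clusters[others], `[[`, character(1), "key")
      dist <- dist[keep, keep, drop = FALSE]
      dist <- rbind(cbind(dist, newd), c(newd, 0))
      rownames(dist)[nrow(dist)] <- colnames(dist)[ncol(dist)] <- merged$key
    }
    clusters <- c(clusters[others], list(merged))
  }
  rows <- clusters[[1]]$rows[ids]
  new_alignment(ids, unname(rows))
}

# align two sub-alignments column-wise (profile-profile) and propagate gaps
merge_profiles <- function(rows_a, rows_b, scheme) {
  ma <- do.call(rbind, strsplit(unname(rows_a), ""))
  mb <- do.call(rbind, strsplit(unname(rows_b), ""))
  fa <- column_freqs(ma)
  fb <- column_freqs(mb)
  S <- t(fa) %*% scheme$substitution_matrix %*% fb
  res <- gotoh_core(S, scheme$gap_open, scheme$gap_extend)
  build <- function(m, idx) {
    out <- matrix(GAP, nrow(m), length(idx))
    out[, idx > 0L] <- m[, idx[idx > 0L], drop = FALSE]
    apply(out, 1, paste, collapse = "")
  }
  c(setNames(build(ma, res$a), names(rows_a)),
    setNames(build(mb, res$b), names(rows_b)))
}

# 20 x L matrix of residue frequencies per column (gaps and X excluded;
# columns normalized by their residue count)
column_freqs <- function(m) {
  f <- vapply(seq_len(ncol(m)), function(j) {
    counts <- tabulate(match(m[, j], AA_ALPHABET), 20L)
    tot <- sum(counts)
    if (tot == 0) rep(0, 20) else counts / tot
  }, numeric(20))
  rownames(f) <- AA_ALPHABET
  f
}

#' Multiple sequence alignment via an external aligner executable
#'
#' Runs a ClustalW/MAFFT-style command-line aligner on a temporary FASTA
#' file and parses its output (aligned FASTA or Clustal format). The result
#' is validated: every degapped row must reproduce its input sequence
#' exactly. Failures are reported distinctly (missing executable, nonzero
#' exit, unparseable output, integrity violation); there is no silent
#' fallback to the internal aligner.
#'
#' @param library A [sequence_library()] with at least two records.
#' @param executable Name or path of the aligner binary.
#' @param args Character vector of extra arguments; the input FASTA path is
#'   appended last.
#' @return An `alignment` with rows in library order.
#' @export
external_msa <- function(library, executable, args = character()) {
  if (length(library) < 2L) stop("external alignment needs at least 2 sequences")
  if (Sys.which(executable) == "" && !file.exists(executable))
    stop("aligner not found: '", executable, "'")
  fin <- tempfile(fileext = ".fasta")
  fout <- tempfile(fileext = ".out")
  on.exit(unlink(c(fin, fout)))
  write_fasta(library, fin)
  status <- suppressWarnings(
    system2(executable, c(args, shQuote(fin)), stdout = fout, stderr = FALSE))
  if (!identical(status, 0L))
    stop("aligner '", executable, "' exited with status ", status)
  lines <- readLines(fout, warn = FALSE)
  rows <- tryCatch(parse_aligned(lines),
                   error = function(e) stop("unparseable aligner output: ",
                                            conditionMessage(e)))
  ids <- lib_ids(library)
  if (!setequal(names(rows), ids))
    stop("aligner output ids do not match the input library")
  rows <- rows[ids]
  orig <- lib_seqs(library)
  bad <- ids[toupper(degap(rows)) != orig]
  if (length(bad))
    stop("aligner output integrity error: degapped row(s) differ from input: ",
         paste(bad, collapse = ", "))
  new_alignment(ids, toupper(unname(rows)))
}

# parse aligned FASTA or Clustal-format text into a named row vector
parse_aligned <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty output")
  if (startsWith(lines[[1]], ">")) {
    idx <- grep("^>", lines)
    ids <- sub("\\s.*$", "", sub("^>", "", lines[idx]))
    ends <- c(idx[-1] - 1L, length(lines))
    rows <- vapply(seq_along(idx), function(k) {
      paste(lines[seq(idx[k] + 1L, ends[k])], collapse = "")
    }, character(1))
    return(setNames(gsub("\\s", "", rows), ids))
  }
  if (grepl("^(CLUSTAL|MUSCLE)", lines[[1]], ignore.case = TRUE)) {
    body <- grep("^\\S+\\s+[A-Za-z.-]+\\s*\\d*$", lines[-1], value = TRUE)
    if (!length(body)) stop("no alignment rows in Clustal output")
    ids <- sub("\\s.*$", "", body)
    seqs <- sub("\\s*\\d*$", "", sub("^\\S+\\s+", "", body))
    out <- tapply(seqs, factor(ids, levels = unique(ids)),
                  paste, collapse = "")
    return(gsub("\\.", "-", setNames(as.character(out), names(out))))
  }
  stop("unrecognized alignment format")
}
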