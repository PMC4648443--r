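#' Create a validated protein sequence record
#'
#' A sequence record holds an identifier, an optional free-text description,
#' and a residue string over the 20 standard one-letter amino-acid codes.
#' `X` is accepted as an unknown-residue placeholder; it is never counted
#' toward any frequency downstream. Lowercase input is normalized to upper.
#'
#' @param id Non-empty identifier token (no whitespace).
#' @param residues Amino-acid string; gaps are not allowed.
#' @param description Optional description string.
#' @return An object of class `sequence_record`.
#' @export
sequence_record <- function(id, residues, description = "") {
  if (!is.character(id) || length(id) != 1L || !nzchar(id) || grepl("\\s", id))
    stop("sequence id must be a non-empty token without whitespace")
  if (!is.character(residues) || length(residues) != 1L || !nzchar(residues))
    stop("residues must be a non-empty string (record '", id, "')")
  residues <- toupper(residues)
  bad <- regexpr(sprintf("[^%sX]", paste(AA_ALPHABET, collapse = "")), residues)
  if (bad > 0L)
    stop(sprintf("illegal residue '%s' in record '%s' at position %d",
                 substr(residues, bad, bad), id, bad))
  structure(list(id = id, description = description, residues = residues),
            class = "sequence_record")
}

#' @export
print.sequence_record <- function(x, ...) {
  cat(sprintf("<sequence_record> %s (%d aa)\n", x$id, nchar(x$residues)))
  invisible(x)
}

#' Create a sequence library
#'
#' An ordered collection of [sequence_record()]s with unique ids, typically
#' the homolog library from which alignment ensembles are sampled.
#'
#' @param records List of `sequence_record` objects (or a named character
#'   vector of residue strings).
#' @param source_path Provenance string recorded on the object.
#' @return An object of class `sequence_library`.
#' @export
sequence_library <- function(records, source_path = "") {
  if (is.character(records)) {
    ids <- names(records)
    if (is.null(ids)) stop("a character vector of sequences must be named")
    records <- Map(sequence_record, ids, unname(records))
  }
  if (length(records) < 1L) stop("a sequence library needs at least one record")
  ok <- vapply(records, inherits, logical(1), "sequence_record")
  if (!all(ok)) stop("all records must be sequence_record objects")
  ids <- vapply(records, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(list(records = setNames(records, ids), source_path = source_path),
            class = "sequence_library")
}

#' @export
length.sequence_library <- function(x) length(x$records)

#' @export
print.sequence_library <- function(x, ...) {
  cat(sprintf("<sequence_library> %d record(s)", length(x)))
  if (nzchar(x$source_path)) cat(" from ", x$source_path)
  cat("\n")
  invisible(x)
}

lib_ids <- function(lib) names(lib$records)
lib_seqs <- function(lib) {
  vapply(lib$records, `[[`, character(1), "residues")
}

#' Read protein sequences from a FASTA file
#'
#' Records are validated against the amino-acid alphabet (plus `X`),
#' case-normalized to upper, and checked for duplicate ids. Any line
#' wrapping is accepted.
#'
#' @param path Path to a FASTA file.
#' @param single If `TRUE`, require exactly one record and error otherwise
#'   (used for the target-protein file, which anchors all coordinates).
#' @return A [sequence_library()].
#' @export
read_fasta <- function(path, single = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA file '", path, "': ",
                             conditionMessage(e)))
  if (length(set) == 0L) stop("no records in FASTA file: ", path)
  if (single && length(set) != 1L)
    stop("expected exactly one record in '", path, "', found ", length(set))
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  recs <- Map(sequence_record, ids, as.character(set), desc)
  sequence_library(recs, source_path = path)
}

#' Write a sequence library (or designed sequences) to FASTA
#'
#' Sequences are wrapped at 60 columns.
#'
#' @param x A [sequence_library()], a single [sequence_record()], or a
#'   named character vector of sequences.
#' @param path Output file path.
#' @param header Optional character vector of `#`-prefixed provenance lines
#'   written before the first record (ignored by FASTA readers is not
#'   guaranteed; only use for files read back by this package).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(x, path, header = NULL) {
  if (inherits(x, "sequence_record")) x <- sequence_library(list(x))
  if (inherits(x, "sequence_library")) {
    seqs <- lib_seqs(x)
  } else if (is.character(x) && !is.null(names(x))) {
    seqs <- x
  } else stop("cannot write object of class ", paste(class(x), collapse = "/"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
  }
  invisible(path)
}

#' Write a frequency profile as a TSV result file
#'
#' One row per target-protein position: 1-based position, the target's own
#' residue, the 21 frequency columns (20 amino acids in alphabetical order,
#' then gap), and the effective observation count. Frequencies are written
#' with six decimals; a position with zero effective count is written with
#' count 0 and all-zero frequencies. Lines starting with `#` carry metadata
#' and are ignored on read.
#'
#' @param profile A [frequency_profile] object.
#' @param path Output file path.
#' @param header Optional extra `#` comment lines (e.g. the CLI invocation).
#' @return Invisibly, `path`.
#' @seealso [read_profile_tsv()]
#' @export
write_profile_tsv <- function(profile, path, header = NULL) {
  stopifnot(inherits(profile, "frequency_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  meta <- profile$meta
  if (!is.null(meta$seed))
    writeLines(sprintf("# seed=%s n_trial=%s n_pick=%s markers=%s",
                       meta$seed, meta$n_trial, meta$n_pick,
                       if (is.null(meta$markers) || !length(meta$markers)) "none"
                       else paste(vapply(meta$markers, format_marker,
                                         character(1)), collapse = ",")), con)
  writeLines(paste(c("pos", "stp_aa", SYMBOLS[1:20], "gap", "count"),
                   collapse = "\t"), con)
  L <- profile_length(profile)
  stp <- strsplit(profile$stp, "")[[1]]
  for (k in seq_len(L)) {
    writeLines(paste(c(k, stp[k], sprintf("%.6f", profile$freqs[, k]),
                       profile$effective_n[k]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a frequency profile from a TSV result file
#'
#' Inverse of [write_profile_tsv()]. Counts per symbol are not stored on
#' disk; the returned profile carries frequencies and per-position effective
#' counts, which is all that consensus assignment and hybrid design need.
#'
#' @param path Path to a profile TSV.
#' @return A [frequency_profile] object (without the integer count matrix).
#' @export
read_profile_tsv <- function(path) {
  if (!file.exists(path)) stop("profile file not found: ", path)
  tab <- read.delim(path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
  need <- c("pos", "stp_aa", SYMBOLS[1:20], "gap", "count")
  if (!all(need %in% names(tab)))
    stop("'", path, "' is not a profile result file (missing columns)")
  tab <- tab[order(tab$pos), , drop = FALSE]
  if (!identical(as.integer(tab$pos), seq_len(nrow(tab))))
    stop("profile positions must be 1..L without holes in '", path, "'")
  freqs <- t(as.matrix(tab[, c(SYMBOLS[1:20], "gap")]))
  dimnames(freqs) <- list(SYMBOLS, NULL)
  frequency_profile(stp = paste(tab$stp_aa, collapse = ""),
                    freqs = freqs,
                    effective_n = as.numeric(tab$count),
                    counts = NULL,
                    meta = list(source = path))
}
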