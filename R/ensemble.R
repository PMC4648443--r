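#' Configuration for an alignment-ensemble run
#'
#' `n_trial` alignment rounds are performed; each round aligns the target
#' protein together with `n_pick` sequences drawn at random from the
#' library. Published use of the approach ran 1000 rounds of 8 picks
#' against a library of several hundred homologs sharing more than 20%
#' identity with the target, and those values are the defaults here.
#'
#' @param n_trial Number of alignment rounds (>= 1).
#' @param n_pick Sequences sampled per round (without replacement within a
#'   round, independently across rounds).
#' @param seed Integer seed governing all sampling.
#' @param min_identity_pct Library admission threshold: sequences must share
#'   strictly more than this percent identity with the target.
#' @return An object of class `ensemble_config`.
#' @export
ensemble_config <- function(n_trial = 1000L, n_pick = 8L, seed = 1L,
                            min_identity_pct = 20) {
  if (n_trial < 1L) stop("n_trial must be >= 1")
  if (n_pick < 1L) stop("n_pick must be >= 1")
  if (min_identity_pct < 0 || min_identity_pct >= 100)
    stop("min_identity_pct must be in [0, 100)")
  structure(list(n_trial = as.integer(n_trial), n_pick = as.integer(n_pick),
                 seed = as.integer(seed),
                 min_identity_pct = as.numeric(min_identity_pct)),
            class = "ensemble_config")
}

#' Per-position residue frequency profile in target coordinates
#'
#' Holds, for every position of the target protein, the tallied counts and
#' frequencies of the 20 amino acids plus gap observed across the alignment
#' ensemble. Frequencies at a position are counts divided by the position's
#' effective count (all tallied symbols there; `X` observations are dropped
#' from both numerator and denominator). The target's own row is the
#' coordinate anchor and is never tallied.
#'
#' @param stp Target residue string.
#' @param freqs 21 x L numeric matrix (rows `A..Y`, `-`).
#' @param effective_n Length-L vector of per-position denominators.
#' @param counts Optional 21 x L integer count matrix.
#' @param meta List of run metadata (seed, n_trial, n_pick, markers, ...).
#' @return An object of class `frequency_profile`.
#' @export
frequency_profile <- function(stp, freqs, effective_n, counts = NULL,
                              meta = list()) {
  L <- nchar(stp)
  stopifnot(ncol(freqs) == L, length(effective_n) == L,
            identical(rownames(freqs), SYMBOLS))
  pos <- effective_n > 0
  if (any(pos)) {
    s <- colSums(freqs[, pos, drop = FALSE])
    if (any(abs(s - 1) > 1e-9))
      stop("frequencies at observed positions must sum to 1")
  }
  if (any(effective_n == 0) &&
      any(freqs[, effective_n == 0, drop = FALSE] != 0))
    stop("positions with zero effective count must have zero frequencies")
  structure(list(stp = stp, freqs = freqs,
                 effective_n = as.numeric(effective_n),
                 counts = counts, meta = meta),
            class = "frequency_profile")
}

profile_length <- function(profile) nchar(profile$stp)

#' @export
print.frequency_profile <- function(x, ...) {
  cat(sprintf("<frequency_profile> %d position(s), median effective n = %s\n",
              profile_length(x), median(x$effective_n)))
  invisible(x)
}

#' Filter a library by identity to the target protein
#'
#' Retains sequences whose global pairwise identity to the target strictly
#' exceeds `config$min_identity_pct` (see [sequence_identity()] for the
#' identity definition).
#'
#' @param stp Target [sequence_record()].
#' @param library A [sequence_library()].
#' @param config An [ensemble_config()].
#' @param scheme A [scoring_scheme()].
#' @return The filtered [sequence_library()]; the number of dropped records
#'   is reported via `message()` and stored in attribute `"n_dropped"`.
#' @export
filter_library <- function(stp, library, config = ensemble_config(),
                           scheme = scoring_scheme()) {
  keep <- vapply(library$records, function(r) {
    sequence_identity(stp, r, scheme) > config$min_identity_pct
  }, logical(1))
  dropped <- sum(!keep)
  if (dropped > 0)
    message(dropped, " sequence(s) below ", config$min_identity_pct,
            "% identity to the target were dropped")
  if (!any(keep))
    stop("no library sequence exceeds ", config$min_identity_pct,
         "% identity to the target")
  out <- sequence_library(library$records[keep], library$source_path)
  attr(out, "n_dropped") <- dropped
  out
}

#' Sample the ensemble's alignment inputs
#'
#' Draws `n_trial` input units ("ofiles"), each holding the target plus
#' `n_pick` library sequences sampled without replacement; sampling is
#' independent across units, so a library sequence may appear in many of
#' them. Fully reproducible from `config$seed`.
#'
#' @inheritParams filter_library
#' @return A list of `n_trial` lists with elements `stp` and `picks`
#'   (integer indices into the library).
#' @export
sample_ofiles <- function(stp, library, config) {
  n <- length(library)
  if (config$n_pick > n)
    stop("n_pick (", config$n_pick, ") exceeds library size (", n, ")")
  set.seed(config$seed)
  lapply(seq_len(config$n_trial), function(i) {
    list(stp = stp, picks = sample.int(n, config$n_pick))
  })
}

#' Project an alignment onto target-protein coordinates
#'
#' For each alignment column where the target row holds a residue, emits the
#' 1-based target position and the column's symbols from all other rows
#' (amino acid, gap, or `X`). Columns where the target row has a gap are
#' discarded.
#'
#' @param alignment An `alignment` containing the target row.
#' @param stp_id Id of the target row.
#' @return A list with `columns` (alignment column of each target position)
#'   and `obs` (character matrix, one row per non-target sequence, one
#'   column per target position).
#' @export
project_to_stp <- function(alignment, stp_id) {
  if (!stp_id %in% alignment$ids)
    stop("target row '", stp_id, "' missing from alignment")
  m <- alignment_matrix(alignment)
  stp_row <- m[stp_id, ]
  cols <- which(stp_row != GAP)
  obs <- m[setdiff(rownames(m), stp_id), cols, drop = FALSE]
  list(columns = cols, obs = obs)
}

tally_obs <- function(obs) {
  # 21 x L counts of AA + gap symbols; X is skipped entirely
  vapply(seq_len(ncol(obs)), function(k) {
    tabulate(match(obs[, k], SYMBOLS), 21L)
  }, integer(21L))
}

#' Accumulate ensemble residue frequencies
#'
#' Aligns every sampled input unit, projects each alignment onto target
#' coordinates, and tallies all observed symbols into a per-position count
#' table. With markers supplied, only library rows carrying every marker
#' residue (evaluated within each unit's own alignment) are tallied, and
#' the overall pass fraction is recorded.
#'
#' @param ofiles Output of [sample_ofiles()].
#' @param library The [sequence_library()] the picks index into.
#' @param scheme A [scoring_scheme()].
#' @param markers Optional list of [marker_residue()]s (ANDed).
#' @param engine Alignment engine: a function `(sequence_library, scheme)`
#'   returning an `alignment`; defaults to [progressive_msa()].
#' @param meta Extra metadata stored on the profile.
#' @return A [frequency_profile].
#' @export
accumulate_frequencies <- function(ofiles, library, scheme = scoring_scheme(),
                                   markers = NULL, engine = progressive_msa,
                                   meta = list()) {
  if (!length(ofiles)) stop("no ofiles to accumulate")
  stp <- ofiles[[1]]$stp
  L <- nchar(stp$residues)
  counts <- matrix(0L, 21L, L, dimnames = list(SYMBOLS, NULL))
  rows_seen <- 0
  rows_passed <- 0
  for (i in seq_along(ofiles)) {
    of <- ofiles[[i]]
    picks <- library$records[of$picks]
    # picked ids may repeat across ofiles but must be unique within one
    ids <- vapply(picks, `[[`, character(1), "id")
    sub <- sequence_library(c(list(stp), picks))
    aln <- tryCatch(engine(sub, scheme),
                    error = function(e) stop("alignment failed on ofile ", i,
                                             ": ", conditionMessage(e)))
    proj <- project_to_stp(aln, stp$id)
    obs <- proj$obs
    if (!is.null(markers) && length(markers)) {
      rows_seen <- rows_seen + nrow(obs)
      pass <- rep(TRUE, nrow(obs))
      for (mk in markers) {
        check_marker(mk, L)
        pass <- pass & (obs[, mk$position] == mk$amino_acid)
      }
      rows_passed <- rows_passed + sum(pass)
      obs <- obs[pass, , drop = FALSE]
    }
    if (nrow(obs)) counts <- counts + tally_obs(obs)
  }
  if (!is.null(markers) && length(markers) && rows_passed == 0)
    stop("empty fixed set: no library row matched the marker(s) in any ofile")
  effective_n <- colSums(counts)
  freqs <- counts
  freqs[, effective_n > 0] <- sweep(counts[, effective_n > 0, drop = FALSE],
                                    2, effective_n[effective_n > 0], "/")
  freqs[, effective_n == 0] <- 0
  meta <- c(meta, list(markers = markers,
                       pass_fraction = if (rows_seen > 0)
                         rows_passed / rows_seen else NA_real_))
  frequency_profile(stp$residues, freqs, effective_n, counts = counts,
                    meta = meta)
}

#' Run the full ensemble profiling pipeline
#'
#' Convenience wrapper: identity-filters the library, samples the ensemble,
#' and accumulates frequencies (optionally under residue fixation).
#'
#' @inheritParams accumulate_frequencies
#' @param stp Target [sequence_record()].
#' @param library A [sequence_library()].
#' @param config An [ensemble_config()].
#' @param filter Apply the identity filter first (default `TRUE`).
#' @return A [frequency_profile].
#' @export
ensemble_profile <- function(stp, library, config = ensemble_config(),
                             markers = NULL, scheme = scoring_scheme(),
                             engine = progressive_msa, filter = TRUE) {
  if (filter) library <- filter_library(stp, library, config, scheme)
  ofiles <- sample_ofiles(stp, library, config)
  accumulate_frequencies(ofiles, library, scheme, markers, engine,
                         meta = list(seed = config$seed,
                                     n_trial = config$n_trial,
                                     n_pick = config$n_pick))
}

#' Assign the consensus residue at every target position
#'
#' The consensus at a position is the amino acid with maximal frequency
#' (gap excluded). Ties go to the target's own residue if it is among the
#' tied maxima, else to the alphabetically first amino acid. Positions with
#' zero effective count have no defined consensus and are flagged.
#'
#' @param profile A [frequency_profile].
#' @return A data frame with columns `position`, `stp_aa`, `consensus_aa`,
#'   `consensus_freq`, `gap_freq`, `matches_stp`, `defined`.
#' @export
assign_consensus <- function(profile) {
  L <- profile_length(profile)
  stp <- strsplit(profile$stp, "")[[1]]
  aa_freq <- profile$freqs[AA_ALPHABET, , drop = FALSE]
  out <- data.frame(position = seq_len(L), stp_aa = stp,
                    consensus_aa = NA_character_,
                    consensus_freq = NA_real_,
                    gap_freq = profile$freqs[GAP, ],
                    matches_stp = NA, defined = profile$effective_n > 0,
                    stringsAsFactors = FALSE)
  for (k in seq_len(L)) {
    if (!out$defined[k]) next
    f <- aa_freq[, k]
    mx <- max(f)
    cand <- AA_ALPHABET[f >= mx - 1e-12]
    aa <- if (stp[k] %in% cand) stp[k] else cand[1]
    out$consensus_aa[k] <- aa
    out$consensus_freq[k] <- f[aa]
    out$matches_stp[k] <- aa == stp[k]
  }
  out
}
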