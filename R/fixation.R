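#' Parse a marker-residue specification
#'
#' Markers are written `"pos:AA"` in 1-based target coordinates, e.g.
#' `"237:K"` (Lys at position 237) or `"2:T"`. Residue fixation restricts
#' frequency tallies to library sequences carrying the marker, curating a
#' mixed library down to one subfamily.
#'
#' @param text A string of the form `"pos:AA"`.
#' @return An object of class `marker_residue` with fields `position` and
#'   `amino_acid`.
#' @export
parse_marker <- function(text) {
  m <- regmatches(text, regexec("^([0-9]+):([A-Za-z])$", text))[[1]]
  if (length(m) != 3L)
    stop("malformed marker '", text, "': expected \"pos:AA\", e.g. \"237:K\"")
  pos <- as.integer(m[2])
  aa <- toupper(m[3])
  if (pos < 1L) stop("marker positions are 1-based; got ", pos)
  if (!aa %in% AA_ALPHABET)
    stop("'", aa, "' is not a standard amino-acid code")
  structure(list(position = pos, amino_acid = aa), class = "marker_residue")
}

format_marker <- function(marker) {
  paste0(marker$position, ":", marker$amino_acid)
}

check_marker <- function(marker, stp_length) {
  if (marker$position > stp_length)
    stop("marker position ", marker$position,
         " exceeds target length ", stp_length)
  invisible(marker)
}

#' Test whether an aligned row carries a marker residue
#'
#' The marker's target position is mapped to its alignment column via
#' [project_to_stp()] coordinates; the row passes iff it carries exactly the
#' marker amino acid there. A gap (or `X`) at that column fails.
#'
#' @param alignment An `alignment` containing both rows.
#' @param stp_id Id of the target row.
#' @param row_id Id of the row under test.
#' @param marker A [parse_marker()] result.
#' @return Logical flag.
#' @export
row_passes_marker <- function(alignment, stp_id, row_id, marker) {
  if (!row_id %in% alignment$ids)
    stop("row '", row_id, "' missing from alignment")
  proj <- project_to_stp(alignment, stp_id)
  check_marker(marker, length(proj$columns))
  identical(unname(proj$obs[row_id, marker$position]), marker$amino_acid)
}

#' Ensemble frequency profile under residue fixation
#'
#' Identical to [ensemble_profile()] except that within every ofile
#' alignment only rows passing all marker tests are tallied; the
#' per-position effective counts reflect only passing rows, and the overall
#' pass fraction is stored in the profile metadata.
#'
#' @inheritParams ensemble_profile
#' @param markers A single marker string / `marker_residue`, or a list of
#'   them (all must pass).
#' @return A [frequency_profile].
#' @export
fixed_profile <- function(stp, library, config = ensemble_config(),
                          markers, scheme = scoring_scheme(),
                          engine = progressive_msa, filter = TRUE) {
  markers <- as_marker_list(markers)
  if (!length(markers)) stop("fixed_profile requires at least one marker")
  ensemble_profile(stp, library, config, markers = markers, scheme = scheme,
                   engine = engine, filter = filter)
}

as_marker_list <- function(markers) {
  if (is.null(markers)) return(list())
  if (inherits(markers, "marker_residue")) return(list(markers))
  lapply(markers, function(m) {
    if (inherits(m, "marker_residue")) m else parse_marker(m)
  })
}

#' Find family-diagnostic (correlated) residues from two fixed profiles
#'
#' Flags positions where the two profiles' consensus residues differ while
#' both are strongly conserved (consensus frequency at or above
#' `conservation_threshold` in each). Comparing profiles fixed on the two
#' subfamilies' markers reveals residues individually conserved in each
#' family — correlated residues in the consensus-design sense.
#'
#' @param profile_a,profile_b [frequency_profile]s over the same target.
#' @param conservation_threshold Minimum consensus frequency in both
#'   profiles (default 0.8).
#' @return A data frame (one row per flagged position, sorted by the
#'   smaller of the two consensus frequencies, descending) with columns
#'   `position`, `consensus_a`, `freq_a`, `consensus_b`, `freq_b`.
#' @export
find_diagnostic_residues <- function(profile_a, profile_b,
                                     conservation_threshold = 0.8) {
  if (profile_length(profile_a) != profile_length(profile_b))
    stop("profiles span different target lengths")
  ca <- assign_consensus(profile_a)
  cb <- assign_consensus(profile_b)
  flag <- ca$defined & cb$defined &
    ca$consensus_aa != cb$consensus_aa &
    ca$consensus_freq >= conservation_threshold &
    cb$consensus_freq >= conservation_threshold
  flag[is.na(flag)] <- FALSE
  out <- data.frame(position = ca$position[flag],
                    consensus_a = ca$consensus_aa[flag],
                    freq_a = ca$consensus_freq[flag],
                    consensus_b = cb$consensus_aa[flag],
                    freq_b = cb$consensus_freq[flag],
                    stringsAsFactors = FALSE)
  out[order(-pmin(out$freq_a, out$freq_b), out$position), , drop = FALSE]
}
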