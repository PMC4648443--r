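#' Build the full-consensus sequence from a profile
#'
#' Concatenates the consensus amino acid at every target position
#' ([assign_consensus()] rules: gap excluded, ties to the target residue
#' then alphabetical). The output is always full length over target
#' positions — a high gap frequency never produces a deletion, so designs
#' stay complete, expressible sequences.
#'
#' @param profile A [frequency_profile] with observations at every position.
#' @return The consensus amino-acid string.
#' @export
build_full_consensus <- function(profile) {
  cons <- assign_consensus(profile)
  if (any(!cons$defined))
    stop("consensus undefined (no observations) at position(s): ",
         paste(cons$position[!cons$defined], collapse = ", "))
  paste(cons$consensus_aa, collapse = "")
}

#' Hybrid full-consensus design
#'
#' Starts from the full-library consensus backbone and overlays the
#' family-specific consensus (from a residue-fixed profile) at every
#' position where the family consensus frequency, as a percentage, is
#' strictly greater than `threshold_pct`. Substitutions are recorded only
#' where the residue actually changes. Positions where the family profile
#' has no observations keep the backbone residue regardless of threshold.
#'
#' @param backbone_profile [frequency_profile] without fixation
#'   ("result file 1").
#' @param family_profile [frequency_profile] under residue fixation
#'   ("result file 2").
#' @param threshold_pct Replacement threshold in `[0, 100]`.
#' @param name_prefix Design name prefix; the threshold value is appended
#'   (e.g. `"HNL"` + 85 -> `"HNL85"`).
#' @return An object of class `designed_sequence`: list with `name`,
#'   `sequence`, `threshold_pct`, and a `substitutions` data frame
#'   (`position`, `backbone_aa`, `family_aa`, `family_freq_pct`).
#' @export
hybridize <- function(backbone_profile, family_profile, threshold_pct,
                      name_prefix = "design") {
  if (threshold_pct < 0 || threshold_pct > 100)
    stop("threshold must be in [0,100]")
  if (profile_length(backbone_profile) != profile_length(family_profile))
    stop("backbone and family profiles span different target lengths")
  backbone <- strsplit(build_full_consensus(backbone_profile), "")[[1]]
  fam <- assign_consensus(family_profile)
  fam_pct <- 100 * fam$consensus_freq
  eligible <- fam$defined & !is.na(fam_pct) & fam_pct > threshold_pct
  seq <- backbone
  seq[eligible] <- fam$consensus_aa[eligible]
  changed <- eligible & seq != backbone
  structure(list(
    name = paste0(name_prefix, format_threshold(threshold_pct)),
    sequence = paste(seq, collapse = ""),
    threshold_pct = threshold_pct,
    substitutions = data.frame(
      position = which(changed),
      backbone_aa = backbone[changed],
      family_aa = seq[changed],
      family_freq_pct = fam_pct[changed],
      stringsAsFactors = FALSE)),
    class = "designed_sequence")
}

format_threshold <- function(x) {
  if (isTRUE(all.equal(x, round(x)))) sprintf("%d", as.integer(round(x)))
  else sub("0+$", "", sprintf("%g", x))
}

#' @export
print.designed_sequence <- function(x, ...) {
  cat(sprintf("<designed_sequence> %s: %d aa, %d substitution(s) at threshold %s%%\n",
              x$name, nchar(x$sequence), nrow(x$substitutions),
              format_threshold(x$threshold_pct)))
  invisible(x)
}

#' Design a series of hybrid consensus sequences
#'
#' One design per threshold. Because eligibility uses a strict inequality,
#' substitution sets are nested: a higher threshold's substitutions are a
#' subset of a lower threshold's, so counts are non-increasing in the
#' threshold.
#'
#' @inheritParams hybridize
#' @param thresholds Numeric vector of percentages in `[0, 100]`.
#' @return A list of `designed_sequence` objects, one per threshold.
#' @export
design_series <- function(backbone_profile, family_profile, thresholds,
                          name_prefix = "design") {
  lapply(thresholds, function(t) {
    hybridize(backbone_profile, family_profile, t, name_prefix)
  })
}
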