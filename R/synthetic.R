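#' Model of one synthetic protein family
#'
#' Sequences are generated from a common ancestor with i.i.d. per-site
#' substitutions (to a uniformly random different residue) and optional
#' short indels. Diagnostic positions are always held at their fixed amino
#' acid, emulating family-defining residues such as a subfamily marker.
#' No rate matrix or tree is used: the generator trades realism for exact,
#' controllable ground truth.
#'
#' @param ancestor Ancestor residue string.
#' @param substitution_rate Per-site substitution probability in `[0, 0.5]`.
#' @param indel_rate Per-site indel probability in `[0, 0.5]`; default 0
#'   keeps ground-truth coordinates trivial.
#' @param diagnostic_positions Named amino-acid vector, names are 1-based
#'   ancestor positions (e.g. `c("237" = "K")`).
#' @return An object of class `family_model`.
#' @export
family_model <- function(ancestor, substitution_rate, indel_rate = 0,
                         diagnostic_positions = character()) {
  anc <- sequence_record("ancestor", ancestor)
  if (substitution_rate < 0 || substitution_rate > 0.5)
    stop("substitution_rate must be in [0, 0.5]")
  if (indel_rate < 0 || indel_rate > 0.5)
    stop("indel_rate must be in [0, 0.5]")
  if (length(diagnostic_positions)) {
    pos <- as.integer(names(diagnostic_positions))
    if (any(is.na(pos)) || any(pos < 1L) || any(pos > nchar(anc$residues)))
      stop("diagnostic positions must lie within the ancestor")
    if (!all(diagnostic_positions %in% AA_ALPHABET))
      stop("diagnostic residues must be standard amino acids")
  }
  structure(list(ancestor = anc$residues,
                 substitution_rate = substitution_rate,
                 indel_rate = indel_rate,
                 diagnostic_positions = diagnostic_positions),
            class = "family_model")
}

#' Generate a synthetic sequence family
#'
#' @param model A [family_model()].
#' @param n Number of sequences (>= 1).
#' @param seed Integer seed; `NULL` continues the current RNG stream (used
#'   internally by [generate_biased_library()]).
#' @param id_prefix Record id prefix.
#' @return A [sequence_library()] of `n` records.
#' @export
generate_family <- function(model, n, seed = NULL, id_prefix = "seq") {
  if (n < 1L) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  anc <- strsplit(model$ancestor, "")[[1]]
  L <- length(anc)
  diag_pos <- as.integer(names(model$diagnostic_positions))
  recs <- lapply(seq_len(n), function(i) {
    s <- anc
    hit <- which(stats::runif(L) < model$substitution_rate)
    for (k in hit) {
      s[k] <- sample(setdiff(AA_ALPHABET, s[k]), 1L)
    }
    if (length(diag_pos)) s[diag_pos] <- model$diagnostic_positions
    if (model$indel_rate > 0) {
      ev <- which(stats::runif(L) < model$indel_rate)
      ev <- setdiff(ev, diag_pos)
      del <- ev[stats::runif(length(ev)) < 0.5]
      ins <- setdiff(ev, del)
      pieces <- as.list(s)
      for (k in ins) {
        pieces[[k]] <- c(pieces[[k]],
                         sample(AA_ALPHABET, sample(1:2, 1L), replace = TRUE))
      }
      for (k in del) pieces[[k]] <- character(0)
      s <- unlist(pieces)
      if (!length(s)) s <- anc  # degenerate full deletion: keep ancestor
    }
    sequence_record(sprintf("%s_%d", id_prefix, i), paste(s, collapse = ""))
  })
  sequence_library(recs, source_path = "synthetic")
}

#' Specification of a biased two-family library
#'
#' @param family_a,family_b [family_model()]s with equal-length ancestors.
#' @param n_a,n_b Family sizes (`n_a + n_b >= 2`); unequal sizes give a
#'   phylogenetically biased mixture.
#' @param seed Integer seed.
#' @return An object of class `library_spec`.
#' @export
library_spec <- function(family_a, family_b, n_a, n_b, seed = 1L) {
  if (nchar(family_a$ancestor) != nchar(family_b$ancestor))
    stop("family ancestors must have equal length")
  if (n_a + n_b < 2L) stop("need at least 2 sequences in total")
  structure(list(family_a = family_a, family_b = family_b,
                 n_a = as.integer(n_a), n_b = as.integer(n_b),
                 seed = as.integer(seed)),
            class = "library_spec")
}

#' Generate a biased two-family library with ground truth
#'
#' Draws `n_a` sequences from family A and `n_b` from family B, shuffles
#' their order, and returns the library together with a ground-truth record
#' (per-sequence family labels, both ancestors, and the diagnostic marker
#' maps). With `n_a > n_b` the mixture emulates a homolog library biased
#' toward the majority family, the situation residue fixation is built to
#' curate.
#'
#' @param spec A [library_spec()].
#' @return A list with `library` (a [sequence_library()]) and `truth`
#'   (list with `labels` data frame, `ancestor_a`, `ancestor_b`,
#'   `markers_a`, `markers_b`).
#' @export
generate_biased_library <- function(spec) {
  set.seed(spec$seed)
  fam_a <- generate_family(spec$family_a, spec$n_a, seed = NULL,
                           id_prefix = "famA")
  fam_b <- generate_family(spec$family_b, spec$n_b, seed = NULL,
                           id_prefix = "famB")
  recs <- c(fam_a$records, fam_b$records)
  labels <- data.frame(id = names(recs),
                       family = rep(c("A", "B"), c(spec$n_a, spec$n_b)),
                       stringsAsFactors = FALSE)
  ord <- sample.int(length(recs))
  recs <- recs[ord]
  labels <- labels[ord, , drop = FALSE]
  rownames(labels) <- NULL
  list(library = sequence_library(recs, source_path = "synthetic"),
       truth = list(labels = labels,
                    ancestor_a = spec$family_a$ancestor,
                    ancestor_b = spec$family_b$ancestor,
                    markers_a = spec$family_a$diagnostic_positions,
                    markers_b = spec$family_b$diagnostic_positions))
}

#' Draw a random amino-acid string
#'
#' Convenience for tests and simulations.
#'
#' @param length Number of residues.
#' @return A residue string.
#' @export
random_protein <- function(length) {
  paste(sample(AA_ALPHABET, length, replace = TRUE), collapse = "")
}
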