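# Shared fixtures built in code.

lib_seqs_for_test <- function(lib) {
  vapply(lib$records, `[[`, character(1), "residues")
}

write_tmp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}

# Build a frequency_profile from a per-position list of named symbol counts,
# e.g. list(c(L = 6, P = 3, `-` = 1), ...). stp defaults to the first-listed
# symbol of each position.
make_profile <- function(counts_list, stp = NULL) {
  L <- length(counts_list)
  counts <- matrix(0, 21L, L, dimnames = list(SYM, NULL))
  for (k in seq_len(L)) {
    ck <- counts_list[[k]]
    counts[names(ck), k] <- ck
  }
  eff <- colSums(counts)
  freqs <- counts
  freqs[, eff > 0] <- sweep(counts[, eff > 0, drop = FALSE], 2,
                            eff[eff > 0], "/")
  if (is.null(stp)) {
    stp <- paste(vapply(counts_list, function(ck) {
      aa <- setdiff(names(ck), "-")
      if (length(aa)) aa[1] else "A"
    }, character(1)), collapse = "")
  }
  frequency_profile(stp, freqs, eff, counts = counts)
}

# A tiny two-family world reused across fixation/design tests: ancestors
# differ only at engineered diagnostic positions (incl. the marker site).
toy_two_family <- function(L = 120, n_a = 40, n_b = 10, rate = 0.1,
                           seed = 11) {
  stopifnot(L >= 50)
  set.seed(seed)
  anc_a <- random_protein(L)
  diag_pos <- pmax(1L, round(c(0.1, 0.3, 0.5, 0.7, 0.9) * L))
  marker_pos <- diag_pos[2]
  aa_a <- c("M", "A", "L", "G", "E")
  aa_b <- c("K", "S", "F", "P", "D")
  sa <- strsplit(anc_a, "")[[1]]
  sa[diag_pos] <- aa_a
  sb <- sa
  sb[diag_pos] <- aa_b
  spec <- library_spec(
    family_a = family_model(paste(sa, collapse = ""), rate,
                            diagnostic_positions = setNames(aa_a, diag_pos)),
    family_b = family_model(paste(sb, collapse = ""), rate,
                            diagnostic_positions = setNames(aa_b, diag_pos)),
    n_a = n_a, n_b = n_b, seed = seed)
  gen <- generate_biased_library(spec)
  list(gen = gen, spec = spec, diag_pos = diag_pos,
       marker_a = paste0(marker_pos, ":A"),
       marker_b = paste0(marker_pos, ":S"),
       stp = sequence_record("stp", spec$family_a$ancestor))
}
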