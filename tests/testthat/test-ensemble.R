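toy_stp <- function() sequence_record("stp", "MKTAYIAKQRQISFVKSHFSRQ")

test_that("library filtering keeps identical sequences and drops unrelated ones", {
  stp <- toy_stp()
  copies <- sequence_library(setNames(rep(stp$residues, 5), paste0("c", 1:5)))
  kept <- filter_library(stp, copies, ensemble_config(seed = 1))
  expect_equal(length(kept), 5L)
  expect_equal(attr(kept, "n_dropped"), 0L)

  # a compositionally alien sequence: identity to the target is provably
  # below the 20% admission threshold under the module's own definition
  alien <- sequence_record("alien", strrep("W", 22))
  expect_lte(sequence_identity(stp, alien), 20)
  mixed <- sequence_library(c(copies$records, list(alien)))
  expect_message(kept2 <- filter_library(stp, mixed, ensemble_config(seed = 1)),
                 "1 sequence")
  expect_false("alien" %in% names(kept2$records))

  # min_identity_pct = 0 retains sequences with identity > 0; the alien
  # shares no residue with the target, so it is still dropped
  cfg0 <- ensemble_config(seed = 1, min_identity_pct = 0)
  expect_message(kept0 <- filter_library(stp, mixed, cfg0))
  expect_equal(length(kept0), 5L)
  near <- sequence_record("near", paste0("W", substr(stp$residues, 2, 3),
                                         strrep("W", 19)))
  expect_gt(sequence_identity(stp, near), 0)
  expect_true("near" %in% names(filter_library(
    stp, sequence_library(c(copies$records, list(near))), cfg0)$records))
  expect_error(filter_library(stp, sequence_library(list(alien)),
                              ensemble_config(seed = 1)), "no library sequence")
})

test_that("ofile sampling is sized, within-ofile unique, and seed-reproducible", {
  stp <- toy_stp()
  lib <- generate_family(family_model(stp$residues, 0.1), 20, seed = 3)
  cfg <- ensemble_config(n_trial = 25, n_pick = 8, seed = 42)
  ofs <- sample_ofiles(stp, lib, cfg)
  expect_length(ofs, 25L)
  for (of in ofs) {
    expect_length(of$picks, 8L)
    expect_false(anyDuplicated(of$picks) > 0)
  }
  expect_identical(lapply(sample_ofiles(stp, lib, cfg), `[[`, "picks"),
                   lapply(ofs, `[[`, "picks"))

  # exhaustive pick uses the whole library in every ofile
  cfg_all <- ensemble_config(n_trial = 3, n_pick = 20, seed = 1)
  for (of in sample_ofiles(stp, lib, cfg_all))
    expect_setequal(of$picks, 1:20)
  expect_error(sample_ofiles(stp, lib, ensemble_config(n_pick = 21, seed = 1)),
               "exceeds library size")
})

test_that("projection onto target coordinates follows the gap rules", {
  aln <- consdesign:::new_alignment(c("stp", "r1"), c("MKT", "MRT"))
  proj <- project_to_stp(aln, "stp")
  expect_equal(proj$columns, 1:3)
  expect_equal(unname(proj$obs["r1", ]), c("M", "R", "T"))

  # target-gap columns are discarded
  aln2 <- consdesign:::new_alignment(c("stp", "r1"), c("M-KT", "MAKT"))
  proj2 <- project_to_stp(aln2, "stp")
  expect_equal(proj2$columns, c(1, 3, 4))
  expect_equal(unname(proj2$obs["r1", ]), c("M", "K", "T"))

  # a gap in the other row is an observation
  aln3 <- consdesign:::new_alignment(c("stp", "r1"), c("MKT", "M-T"))
  expect_equal(unname(project_to_stp(aln3, "stp")$obs["r1", ]),
               c("M", "-", "T"))
  expect_error(project_to_stp(aln, "nope"), "missing")
})

test_that("a library of target copies yields frequency 1 at every position", {
  stp <- toy_stp()
  lib <- sequence_library(setNames(rep(stp$residues, 6), paste0("c", 1:6)))
  prof <- ensemble_profile(stp, lib, ensemble_config(n_trial = 4, n_pick = 3,
                                                     seed = 2))
  stp_chars <- strsplit(stp$residues, "")[[1]]
  for (k in seq_along(stp_chars)) {
    expect_equal(unname(prof$freqs[stp_chars[k], k]), 1)
  }
  expect_true(all(prof$freqs["-", ] == 0))
})

test_that("n_trial = 1 with the full library equals a direct single-MSA tally", {
  set.seed(17)
  stp <- sequence_record("stp", random_protein(30))
  lib <- generate_family(family_model(stp$residues, 0.15), 4, seed = 18)
  cfg <- ensemble_config(n_trial = 1, n_pick = 4, seed = 5)
  ofs <- sample_ofiles(stp, lib, cfg)
  prof <- accumulate_frequencies(ofs, lib)

  aln <- progressive_msa(sequence_library(c(list(stp),
                                            lib$records[ofs[[1]]$picks])))
  expect_identical(unname(prof$counts), unname(manual_tally(aln, "stp")))
})

test_that("the target row itself is never tallied", {
  stp <- toy_stp()
  lib <- generate_family(family_model(stp$residues, 0.3), 6, seed = 9)
  cfg <- ensemble_config(n_trial = 5, n_pick = 3, seed = 7)
  prof <- ensemble_profile(stp, lib, cfg, filter = FALSE)
  # 5 ofiles x 3 rows = 15 observations per position (no X in this library)
  expect_true(all(prof$effective_n == 15))
})

test_that("X observations are dropped from numerator and denominator", {
  stp <- sequence_record("stp", "MKTAYIAKQR")
  withx <- sequence_library(c(r1 = "MKTAYIAKQR", r2 = "MXTAYIAKQR"))
  cfg <- ensemble_config(n_trial = 1, n_pick = 2, seed = 1)
  prof <- ensemble_profile(stp, withx, cfg, filter = FALSE)
  expect_equal(prof$effective_n[2], 1)  # only r1 observed at position 2
  expect_equal(unname(prof$freqs["K", 2]), 1)
})

test_that("consensus assignment applies argmax, tie-break, and gap rules", {
  prof <- make_profile(list(c(L = 6, P = 3, `-` = 1),
                            c(A = 4, V = 4, G = 2),
                            c(`-` = 7, P = 3),
                            c(M = 5)),
                       stp = "KVAM")
  cons <- assign_consensus(prof)
  expect_equal(cons$consensus_aa, c("L", "V", "P", "M"))
  expect_equal(cons$consensus_freq[1], 0.6)
  expect_equal(cons$gap_freq[1], 0.1)
  # tie at position 2 resolved to the target's own residue V
  expect_true(cons$matches_stp[2])
  # gap majority at position 3 still yields an amino acid
  expect_equal(cons$gap_freq[3], 0.7)

  # alphabetical tie-break when the target residue is not among the maxima
  prof2 <- make_profile(list(c(V = 3, G = 3)), stp = "K")
  expect_equal(assign_consensus(prof2)$consensus_aa, "G")

  # undefined consensus is flagged
  prof3 <- make_profile(list(c(M = 2), setNames(numeric(0), character(0))),
                        stp = "MK")
  cons3 <- assign_consensus(prof3)
  expect_false(cons3$defined[2])
  expect_true(is.na(cons3$consensus_aa[2]))
})

test_that("produced profiles are normalized and count-consistent", {
  set.seed(31)
  for (rep in 1:3) {
    stp <- sequence_record("stp", random_protein(25))
    lib <- generate_family(family_model(stp$residues, 0.2), 6,
                           seed = 100 + rep)
    prof <- ensemble_profile(stp, lib,
                             ensemble_config(n_trial = 3, n_pick = 3,
                                             seed = rep),
                             filter = FALSE)
    obs <- prof$effective_n > 0
    expect_true(all(abs(colSums(prof$freqs[, obs, drop = FALSE]) - 1) < 1e-9))
    expect_true(all(prof$counts >= 0))
    expect_equal(colSums(prof$counts), prof$effective_n)
  }
})
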