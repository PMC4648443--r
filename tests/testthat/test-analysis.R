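test_that("sequence identity matches hand alignments and is symmetric", {
  expect_equal(sequence_identity("MKT", "MKT"), 100)
  expect_equal(sequence_identity("MKT", "MAT"), 100 * 2 / 3, tolerance = 1e-9)
  set.seed(12)
  for (i in 1:5) {
    a <- random_protein(sample(10:30, 1))
    b <- random_protein(sample(10:30, 1))
    expect_equal(sequence_identity(a, b), sequence_identity(b, a))
  }
})

test_that("identity matrices are symmetric with a 100 diagonal", {
  lib <- sequence_library(c(a = "MKTAYIAK", b = "MKTAYIAK", c = "MKSAYIK"))
  M <- identity_matrix(lib)
  expect_equal(unname(diag(M)), rep(100, 3))
  expect_equal(M, t(M), tolerance = 1e-9)
  expect_equal(M["a", "b"], 100)
  expect_equal(M["a", "c"],
               sequence_identity(lib$records[["a"]], lib$records[["c"]]))
  expect_error(identity_matrix(sequence_library(c(a = "MKT"))), "at least 2")
})

test_that("specificity constants and efficiency ratios reproduce worked values", {
  expect_equal(specificity_constant(156, 0.8), 195)
  expect_equal(specificity_constant(192, 0.4), 480)
  expect_equal(specificity_constant(7, 1), 7)
  expect_error(specificity_constant(5, 0), "positive")
})

test_that("enantioselectivity E is the preferred/non-preferred ratio", {
  e1 <- enantioselectivity_E(39.3, 8.1)
  expect_equal(signif(e1$E, 2), 4.9)
  expect_equal(e1$label, "S-selective")
  e2 <- enantioselectivity_E(480, 3.6)
  expect_equal(signif(e2$E, 3), 133)
  expect_equal(e2$preferred, "S")
  # symmetry: swapping arguments flips the label, not the value
  e3 <- enantioselectivity_E(8.1, 39.3)
  expect_equal(e3$E, e1$E)
  expect_equal(e3$preferred, "R")
  e4 <- enantioselectivity_E(7, 7)
  expect_equal(e4$E, 1)
  expect_equal(e4$preferred, "none")
  expect_gte(enantioselectivity_E(runif(1, 0.1, 100), runif(1, 0.1, 100))$E, 1)
  expect_error(enantioselectivity_E(-1, 2), "positive")
})

test_that("fraction folded interpolates between the baselines", {
  expect_equal(fraction_folded(-20, -20, -2), 1)
  expect_equal(fraction_folded(-2, -20, -2), 0)
  expect_equal(fraction_folded(-11, -20, -2), 0.5)
  expect_warning(a <- fraction_folded(-25, -20, -2), "outside")
  expect_gt(a, 1)
  expect_error(fraction_folded(-5, -3, -3), "identical")
})

two_state <- function(T, tm, slope = 2, thF = -20, thU = -2) {
  thU + (thF - thU) / (1 + exp((T - tm) / slope))
}

test_that("two-state fits recover the transition midpoint", {
  T <- seq(5, 95, by = 0.5)
  fit <- fit_melting_curve(melting_curve(T, two_state(T, 67.5)))
  expect_lt(abs(fit$tm - 67.5), 0.1)

  set.seed(14)
  noisy <- two_state(T, 50.5) + rnorm(length(T), sd = 0.02 * 18)
  fit2 <- fit_melting_curve(melting_curve(T, noisy))
  expect_lt(abs(fit2$tm - 50.5), 0.5)

  # fraction folded at the fitted Tm is 0.5 by construction of the model
  theta_tm <- fit2$theta_U +
    (fit2$theta_F - fit2$theta_U) / (1 + exp(0))
  expect_equal(fraction_folded(theta_tm, fit2$theta_F, fit2$theta_U), 0.5)

  set.seed(15)
  expect_error(fit_melting_curve(
    melting_curve(T, rnorm(length(T), -10, 0.1))), "no transition")
  expect_error(melting_curve(c(5, 4, 6), 1:3), "increasing|at least")
})

test_that("refolding yield reads the renaturation plateau against denaturation baselines", {
  T <- seq(5, 95, by = 0.5)
  denat <- melting_curve(T, two_state(T, 60))
  # full reversibility: renaturation retraces the denaturation curve
  expect_equal(refolding_yield(denat, denat),
               fraction_folded(two_state(5, 60), -20, -2), tolerance = 1e-3)
  expect_equal(refolding_yield(denat, denat), 1, tolerance = 1e-3)
  # plateau at 60% of the folded baseline
  plateau60 <- melting_curve(T, rep(-2 + 0.6 * (-20 - -2), length(T)))
  expect_equal(refolding_yield(denat, plateau60), 0.6, tolerance = 1e-3)
  # no refolding: stuck at the unfolded baseline
  plateau0 <- melting_curve(T, rep(-2, length(T)))
  expect_equal(refolding_yield(denat, plateau0), 0, tolerance = 1e-3)
})

test_that("mutation-site distances follow hand geometry and the strict cutoff", {
  ca <- data.frame(resno = c(10, 20, 50), x = c(10, 0, 3), y = c(0, 20, 4),
                   z = 0)
  ref <- c(0, 0, 0)
  res <- mutation_site_distances(ca, ref, c(10, 20))
  expect_equal(unname(res$distances), c(10, 20))
  expect_equal(res$mean, 15)
  expect_equal(res$sd, sd(c(10, 20)))
  # distance exactly 10 is not strictly within a 10 A cutoff
  expect_equal(res$n_within, 0L)
  res2 <- mutation_site_distances(ca, ref, c(10, 20, 50))
  expect_equal(res2$n_within, 1L)  # site 50 at distance 5
  expect_error(mutation_site_distances(ca, ref, c(10, 99)), "missing")
})

test_that("entrance-region fractions count inclusive interval membership", {
  ca <- data.frame(resno = c(120, 180, 50), x = 1:3, y = 0, z = 0)
  res <- mutation_site_distances(ca, c(0, 0, 0), c(120, 180, 50),
                                 entrance_regions = list(c(115, 147),
                                                         c(178, 186)))
  expect_equal(res$frac_entrance, 2 / 3)
})

test_that("distance summaries match a direct recomputation on random coordinates", {
  set.seed(16)
  ca <- data.frame(resno = 1:30, x = rnorm(30, sd = 10), y = rnorm(30, sd = 10),
                   z = rnorm(30, sd = 10))
  ref <- rnorm(3, sd = 5)
  sites <- sample(1:30, 12)
  res <- mutation_site_distances(ca, ref, sites)
  direct <- apply(ca[match(sites, ca$resno), c("x", "y", "z")], 1,
                  function(p) sqrt(sum((p - ref)^2)))
  expect_equal(unname(res$distances), unname(direct))
  expect_equal(res$mean, mean(direct))
  expect_equal(res$sd, sqrt(sum((direct - mean(direct))^2) / (12 - 1)))
})

test_that("PDB ATOM records provide C-alpha and reference-atom coordinates", {
  pdb <- tempfile(fileext = ".pdb")
  fmt <- "ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s"
  writeLines(c(
    sprintf(fmt, 1, " CA ", "SER", "A", 80, 0, 0, 0, "C"),
    sprintf(fmt, 2, " OG ", "SER", "A", 80, 1, 1, 1, "O"),
    sprintf(fmt, 3, " CA ", "ALA", "A", 81, 3, 4, 0, "C"),
    sprintf(fmt, 4, " CA ", "GLY", "B", 90, 9, 9, 9, "C"),
    "END"), pdb)
  coords <- read_structure(pdb, chain = "A")
  expect_equal(coords$ca$resno, c(80, 81))
  ref <- reference_atom(coords, 80, "OG")
  expect_equal(unname(ref), c(1, 1, 1))
  res <- mutation_site_distances(coords, ref, 81)
  expect_equal(unname(res$distances), sqrt(2^2 + 3^2 + 1))
  expect_error(reference_atom(coords, 81, "OG"), "expected exactly one")
})

test_that("differing positions are located by direct comparison", {
  expect_equal(diff_positions("MKT", "MKT"), integer(0))
  expect_equal(diff_positions("MKT", "MAT"), 2L)
  set.seed(19)
  a <- random_protein(50)
  b <- strsplit(a, "")[[1]]
  flip <- sample(50, 8)
  for (k in flip) b[k] <- setdiff(c("A", "V"), b[k])[1]
  expect_setequal(diff_positions(a, paste(b, collapse = "")), flip)
  expect_error(diff_positions("MK", "MKT"), "length")
})

test_that("kinetics and melting tables read with derived columns", {
  kin <- tempfile(fileext = ".tsv")
  writeLines(c("# toy kinetics", "enzyme\tsubstrate\tkcat\tkm",
               "HNL30\t(S)-Man\t192\t0.4", "HNL30\t(R)-Man\t18.0\t5.0"), kin)
  tab <- read_kinetics_tsv(kin)
  expect_equal(tab$kcat_over_km, c(480, 3.6))
  melt <- tempfile(fileext = ".tsv")
  T <- seq(5, 95, by = 0.5)
  writeLines(c("temperature_C\tellipticity",
               paste(T, two_state(T, 60), sep = "\t")), melt)
  curve <- read_melting_tsv(melt)
  expect_s3_class(curve, "melting_curve")
  expect_lt(abs(fit_melting_curve(curve)$tm - 60), 0.1)
})
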