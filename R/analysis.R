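#' Global pairwise sequence identity
#'
#' Aligns the two sequences globally (affine gaps, [scoring_scheme()]
#' defaults) and reports `100 * identical columns / columns with at least
#' one residue`. Terminal gaps count in the denominator, so the measure is
#' symmetric and comparable across length differences.
#'
#' @param a,b [sequence_record()]s or residue strings.
#' @param scheme A [scoring_scheme()].
#' @return Identity percentage in `[0, 100]`.
#' @export
sequence_identity <- function(a, b, scheme = scoring_scheme()) {
  pa <- pairwise_align(a, b, scheme)
  m <- alignment_matrix(pa$alignment)
  denom <- sum(colSums(m != GAP) > 0)
  100 * sum(m[1, ] == m[2, ] & m[1, ] != GAP) / denom
}

#' Pairwise identity matrix for a library
#'
#' @param library A [sequence_library()] with at least two records.
#' @param scheme A [scoring_scheme()].
#' @return Symmetric percentage matrix with 100 on the diagonal, dimnames
#'   set to the record ids.
#' @export
identity_matrix <- function(library, scheme = scoring_scheme()) {
  n <- length(library)
  if (n < 2L) stop("identity matrix needs at least 2 sequences")
  ids <- lib_ids(library)
  M <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    M[i, j] <- M[j, i] <-
      sequence_identity(library$records[[i]], library$records[[j]], scheme)
  }
  M
}

#' Specificity constant kcat/Km
#'
#' @param kcat Turnover number (per minute).
#' @param km Michaelis constant (mM), strictly positive.
#' @return kcat/Km in per-minute-per-mM.
#' @export
specificity_constant <- function(kcat, km) {
  if (any(km <= 0)) stop("Km must be positive")
  kcat / km
}

#' Enantioselectivity E value from specificity constants
#'
#' E is the ratio of the specificity constants (kcat/Km) of the preferred
#' to the non-preferred enantiomer, so E >= 1 by construction.
#'
#' @param eff_S,eff_R Specificity constants toward the (S)- and
#'   (R)-enantiomer (per-minute-per-mM, positive).
#' @return A list with `E` (the ratio), `preferred` (`"S"`, `"R"`, or
#'   `"none"` when equal), and `label` (e.g. `"S-selective"`).
#' @export
enantioselectivity_E <- function(eff_S, eff_R) {
  if (eff_S <= 0 || eff_R <= 0)
    stop("specificity constants must be positive")
  E <- max(eff_S, eff_R) / min(eff_S, eff_R)
  preferred <- if (eff_S > eff_R) "S" else if (eff_R > eff_S) "R" else "none"
  list(E = E, preferred = preferred,
       label = if (preferred == "none") "no preference"
               else paste0(preferred, "-selective"))
}

#' Fraction of folded protein from CD ellipticity
#'
#' `alpha = (theta_t - theta_U) / (theta_F - theta_U)`, where `theta_F` and
#' `theta_U` are the folded- and unfolded-state baseline ellipticities.
#' Values outside `[0, 1]` (measurement noise) are returned as-is with a
#' warning.
#'
#' @param theta_t Observed ellipticity (vectorized).
#' @param theta_F,theta_U Folded/unfolded baselines (must differ).
#' @return Fraction(s) folded.
#' @export
fraction_folded <- function(theta_t, theta_F, theta_U) {
  if (theta_F == theta_U)
    stop("folded and unfolded baselines are identical")
  alpha <- (theta_t - theta_U) / (theta_F - theta_U)
  out_of_range <- alpha < 0 | alpha > 1
  if (any(out_of_range))
    warning(sum(out_of_range),
            " fraction-folded value(s) outside [0, 1] (noise)")
  alpha
}

#' Construct a melting curve
#'
#' @param temperatures Temperatures in degrees C, strictly increasing,
#'   length >= 10.
#' @param ellipticities CD signal (e.g. at 222 nm), same length.
#' @return An object of class `melting_curve`.
#' @export
melting_curve <- function(temperatures, ellipticities) {
  if (length(temperatures) != length(ellipticities))
    stop("temperature and ellipticity vectors differ in length")
  if (length(temperatures) < 10L)
    stop("need at least 10 points for a melting curve")
  if (any(diff(temperatures) <= 0))
    stop("temperatures must be strictly increasing")
  structure(list(temperatures = as.numeric(temperatures),
                 ellipticities = as.numeric(ellipticities)),
            class = "melting_curve")
}

#' Fit a two-state thermal denaturation curve
#'
#' Least-squares fit (Levenberg-Marquardt, via minpack.lm) of the two-state
#' sigmoid with constant baselines
#' `theta(T) = theta_U + (theta_F - theta_U) / (1 + exp((T - Tm) / slope))`.
#' Tm is the transition midpoint: the temperature where the fraction folded
#' is 0.5. Curves with no visible transition (amplitude indistinguishable
#' from noise) are rejected.
#'
#' @param curve A [melting_curve()].
#' @return An object of class `melting_fit`: list with `tm`, `theta_F`,
#'   `theta_U`, `slope` (transition steepness, degrees C), `residual_norm`,
#'   and `fitted` values.
#' @export
fit_melting_curve <- function(curve) {
  stopifnot(inherits(curve, "melting_curve"))
  T <- curve$temperatures
  y <- curve$ellipticities
  k <- max(3L, length(T) %/% 10L)
  thF0 <- mean(head(y, k))
  thU0 <- mean(tail(y, k))
  noise <- sd(diff(y)) / sqrt(2)
  if (!is.finite(noise)) noise <- 0
  amp <- abs(thF0 - thU0)
  if (amp <= max(4 * noise, 1e-8 * max(1, max(abs(y)))))
    stop("no transition: curve amplitude is indistinguishable from noise")
  mid <- (thF0 + thU0) / 2
  tm0 <- T[which.min(abs(y - mid))]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ theta_U + (theta_F - theta_U) / (1 + exp((T - tm) / slope)),
      start = list(theta_F = thF0, theta_U = thU0, tm = tm0, slope = 2),
      lower = c(-Inf, -Inf, min(T), 1e-3),
      upper = c(Inf, Inf, max(T), diff(range(T))),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("melting-curve fit failed to converge: ",
                             conditionMessage(e)))
  p <- coef(fit)
  structure(list(tm = unname(p["tm"]), theta_F = unname(p["theta_F"]),
                 theta_U = unname(p["theta_U"]), slope = unname(p["slope"]),
                 residual_norm = sqrt(sum(resid(fit)^2)),
                 fitted = unname(fitted(fit))),
            class = "melting_fit")
}

#' @export
print.melting_fit <- function(x, ...) {
  cat(sprintf("<melting_fit> Tm = %.2f degC (slope %.2f, residual norm %.3g)\n",
              x$tm, x$slope, x$residual_norm))
  invisible(x)
}

#' Refolding yield after thermal renaturation
#'
#' Fits folded/unfolded baselines to the denaturation curve, then reports
#' the fraction folded of the renaturation curve at the lowest temperature
#' common to both curves.
#'
#' @param denaturation,renaturation [melting_curve()]s over a shared
#'   temperature range.
#' @return Fraction refolded.
#' @export
refolding_yield <- function(denaturation, renaturation) {
  fit <- fit_melting_curve(denaturation)
  t0 <- max(min(denaturation$temperatures), min(renaturation$temperatures))
  theta0 <- stats::approx(renaturation$temperatures,
                          renaturation$ellipticities, xout = t0)$y
  suppressWarnings(fraction_folded(theta0, fit$theta_F, fit$theta_U))
}

#' Read C-alpha and reference-atom coordinates from a PDB file
#'
#' Parses ATOM records and returns per-residue C-alpha coordinates for one
#' chain.
#'
#' @param path Path to a PDB file.
#' @param chain Optional chain id; default uses all chains.
#' @return An object of class `structure_coords`: list with `ca` (data
#'   frame `resno`, `x`, `y`, `z`) and `atoms` (all ATOM records).
#' @export
read_structure <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- bio3d::read.pdb(path)
  atoms <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (!is.null(chain)) atoms <- atoms[atoms$chain %in% chain, , drop = FALSE]
  if (!nrow(atoms)) stop("no ATOM records", if (!is.null(chain))
    paste0(" for chain ", chain), " in ", path)
  ca <- atoms[atoms$elety == "CA", c("resno", "x", "y", "z"), drop = FALSE]
  if (anyDuplicated(ca$resno)) stop("duplicate residue numbers in ", path)
  structure(list(ca = ca, atoms = atoms), class = "structure_coords")
}

#' Coordinates of a named reference atom
#'
#' @param coords A [read_structure()] result.
#' @param resno Residue number.
#' @param atom Atom name in PDB nomenclature (e.g. `"OG"` for a serine
#'   O-gamma).
#' @return Numeric xyz vector (Angstrom).
#' @export
reference_atom <- function(coords, resno, atom = "OG") {
  a <- coords$atoms
  hit <- a[a$resno == resno & a$elety == atom, , drop = FALSE]
  if (nrow(hit) != 1L)
    stop("expected exactly one '", atom, "' atom in residue ", resno,
         "; found ", nrow(hit))
  c(x = hit$x, y = hit$y, z = hit$z)
}

#' Distance statistics of mutation sites relative to a reference atom
#'
#' Computes the Euclidean distance from each mutated residue's C-alpha atom
#' to a reference atom (e.g. the O-gamma of a catalytic serine), the mean
#' and sample (n-1) standard deviation of those distances, the count and
#' fraction strictly within a cutoff, and the fraction of sites falling in
#' given residue ranges (e.g. a substrate-entrance region).
#'
#' @param coords A [read_structure()] result (or a data frame with columns
#'   `resno`, `x`, `y`, `z` of C-alpha coordinates).
#' @param reference_xyz Numeric xyz of the reference atom.
#' @param mutated_positions Residue numbers of the mutation sites.
#' @param entrance_regions List of inclusive `c(from, to)` residue ranges.
#' @param cutoff Distance cutoff in Angstrom (strict `<`; default 10).
#' @return A list with `distances` (named by residue), `mean`, `sd`,
#'   `n_within`, `frac_within`, `frac_entrance`, `cutoff`.
#' @export
mutation_site_distances <- function(coords, reference_xyz, mutated_positions,
                                    entrance_regions = list(),
                                    cutoff = 10) {
  ca <- if (inherits(coords, "structure_coords")) coords$ca else coords
  missing <- setdiff(mutated_positions, ca$resno)
  if (length(missing))
    stop("residue(s) missing from structure: ",
         paste(missing, collapse = ", "))
  idx <- match(mutated_positions, ca$resno)
  d <- sqrt((ca$x[idx] - reference_xyz[1])^2 +
            (ca$y[idx] - reference_xyz[2])^2 +
            (ca$z[idx] - reference_xyz[3])^2)
  names(d) <- mutated_positions
  in_region <- vapply(mutated_positions, function(p) {
    any(vapply(entrance_regions, function(r) p >= r[1] && p <= r[2],
               logical(1)))
  }, logical(1))
  list(distances = d, mean = mean(d),
       sd = if (length(d) > 1) sd(d) else NA_real_,
       n_within = sum(d < cutoff), frac_within = mean(d < cutoff),
       frac_entrance = if (length(entrance_regions)) mean(in_region)
                       else NA_real_,
       cutoff = cutoff)
}

#' Positions at which two equal-length sequences differ
#'
#' @param a,b Amino-acid strings of equal length (designed sequences share
#'   the target's coordinate system).
#' @return Integer vector of 1-based differing positions.
#' @export
diff_positions <- function(a, b) {
  if (inherits(a, "designed_sequence")) a <- a$sequence
  if (inherits(b, "designed_sequence")) b <- b$sequence
  if (nchar(a) != nchar(b)) stop("sequences differ in length")
  which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Read a kinetics table
#'
#' Tab-separated with columns `enzyme`, `substrate`, `kcat` (per minute),
#' `km` (mM); `#` lines are comments. A `kcat_over_km` column is added.
#'
#' @param path Path to the TSV file.
#' @return Data frame with the derived specificity constants.
#' @export
read_kinetics_tsv <- function(path) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("enzyme", "substrate", "kcat", "km")
  if (!all(need %in% names(tab)))
    stop("kinetics table needs columns: ", paste(need, collapse = ", "))
  tab$kcat_over_km <- specificity_constant(tab$kcat, tab$km)
  tab
}

#' Read a melting curve table
#'
#' Tab-separated, two columns `temperature_C` and `ellipticity`; `#` lines
#' are comments.
#'
#' @param path Path to the TSV file.
#' @return A [melting_curve()].
#' @export
read_melting_tsv <- function(path) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("temperature_C", "ellipticity")
  if (!all(need %in% names(tab)))
    stop("melting table needs columns: ", paste(need, collapse = ", "))
  melting_curve(tab$temperature_C, tab$ellipticity)
}
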