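# Natural-abundance correction of GC-MS mass-isotopologue distributions
# (MIDs) by multiple linear regression, plus the forward convolution used
# by the cohort simulator.

#' Standard isotope abundances
#'
#' Natural isotopic abundances (IUPAC representative values) for the
#' elements of the measured glucose-derivative ion. Each element maps to a
#' vector of abundances ordered by mass shift (+0, +1, +2 u).
#'
#' @return Named list of numeric abundance vectors for C, H, N and O.
#' @export
#' @examples
#' iso_abundances()$C  # 12C, 13C
iso_abundances <- function() {
  list(
    C = c(0.9893, 0.0107),
    H = c(0.999885, 0.000115),
    N = c(0.99636, 0.00364),
    O = c(0.99757, 0.00038, 0.00205)
  )
}

#' Elemental composition of the measured glucose derivative ion
#'
#' Default ion monitored by GC-MS: the ammonium adduct of glucose
#' pentaacetate, C16H26NO11 (nominal monoisotopic m/z 408, so the m0..m4
#' isotopologues fall at m/z 408-412). Six of the sixteen carbons are the
#' glucose backbone and can carry the 13C label.
#'
#' @return Named integer vector of atom counts.
#' @export
glucose_pentaacetate_ion <- function() {
  c(C = 16L, H = 26L, N = 1L, O = 11L)
}

# Truncated polynomial product: convolve coefficient vectors, keep the
# first `len` terms (mass-shift window).
poly_mult_trunc <- function(a, b, len) {
  out <- numeric(len)
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    jmax <- min(length(b), len - i + 1L)
    if (jmax < 1L) break
    idx <- i + seq_len(jmax) - 1L
    out[idx] <- out[idx] + a[i] * b[seq_len(jmax)]
  }
  out
}

#' Natural-abundance design matrix for MID correction
#'
#' Column `j` (j = 0..`n_label`) is the theoretical measured spectrum of a
#' species carrying exactly `j` 13C labels: the labelled carbons contribute
#' a fixed +j mass shift, and every remaining atom contributes natural
#' isotope abundance. Probabilities are truncated to the retained mass
#' window m0..`n_mass`, so columns sum to at most 1.
#'
#' @param formula Named vector of atom counts of the measured ion
#'   (elements must appear in `abundances`). Default
#'   [glucose_pentaacetate_ion()].
#' @param n_label Number of label-carrying carbon positions (default 6 for
#'   \code{[U-13C6]} glucose).
#' @param n_mass Highest retained mass shift; the window is m0..`n_mass`
#'   (default `n_label`, i.e. m0..m6; set 4 for an m0..m4 window).
#' @param abundances Isotope abundance table, see [iso_abundances()].
#' @return Numeric matrix with `n_mass + 1` rows (m0..m`n_mass`) and
#'   `n_label + 1` columns (0..`n_label` labels).
#' @export
#' @examples
#' M <- natural_abundance_matrix()
#' colSums(M)  # all <= 1
natural_abundance_matrix <- function(formula = glucose_pentaacetate_ion(),
                                     n_label = 6L,
                                     n_mass = n_label,
                                     abundances = iso_abundances()) {
  if (any(formula < 0)) stop("configuration error: negative atom counts")
  if (is.null(names(formula)) || !all(names(formula) %in% names(abundances)))
    stop("configuration error: formula elements must be named and present in `abundances`")
  if (!("C" %in% names(formula)) || formula[["C"]] < n_label)
    stop("configuration error: n_label exceeds the ion's carbon count")
  len <- n_mass + 1L
  M <- matrix(0, nrow = len, ncol = n_label + 1L,
              dimnames = list(paste0("m", 0:n_mass), paste0("lab", 0:n_label)))
  for (j in 0:n_label) {
    p <- 1
    for (el in names(formula)) {
      n_at <- formula[[el]]
      if (el == "C") n_at <- n_at - j  # labelled carbons are fixed 13C
      ab <- abundances[[el]]
      for (k in seq_len(n_at)) p <- poly_mult_trunc(p, ab, len)
    }
    p <- c(p, numeric(len - length(p)))
    # shift by the j labelled carbons, truncate to the window
    col <- numeric(len)
    if (j < len) col[(j + 1L):len] <- p[seq_len(len - j)]
    M[, j + 1L] <- col
  }
  M
}

#' Correct a raw MID for natural isotope abundance
#'
#' Solves `matrix %*% x ~ raw` by least squares (the multiple-linear-
#' regression correction) and renormalizes the solution to sum to one.
#' Negative components are retained by default so that ill-conditioning or
#' inconsistent spectra stay visible; `nonnegative = TRUE` switches to a
#' non-negative least-squares solve.
#'
#' @param raw Numeric vector of raw fractional ion abundances m0..mN.
#' @param matrix Correction matrix from [natural_abundance_matrix()].
#' @param nonnegative Use non-negative least squares
#'   ([pracma::lsqnonneg()]) instead of the unconstrained solve.
#' @param renormalize Rescale the solution to sum to 1 (default TRUE).
#' @return Numeric vector of corrected fractions, one per label count.
#' @export
#' @examples
#' M <- natural_abundance_matrix()
#' raw <- as.vector(M %*% c(0.95, 0, 0, 0, 0, 0, 0.05))
#' correct_mid(raw / sum(raw), M)
correct_mid <- function(raw, matrix, nonnegative = FALSE, renormalize = TRUE) {
  if (length(raw) != nrow(matrix))
    stop("schema error: raw spectrum length must match matrix rows")
  kap <- kappa(matrix, exact = TRUE)
  if (!is.finite(kap) || kap > 1e8)
    stop(sprintf("numerical error: correction matrix is ill-conditioned (condition number %.3g)", kap))
  x <- if (nonnegative) {
    pracma::lsqnonneg(matrix, as.numeric(raw))$x
  } else {
    qr.solve(matrix, as.numeric(raw))
  }
  if (renormalize) {
    s <- sum(x)
    if (abs(s) < .Machine$double.eps^0.5)
      stop("numerical error: corrected spectrum sums to ~0, cannot renormalize")
    x <- x / s
  }
  names(x) <- paste0("m", seq_along(x) - 1L)
  x
}

#' Forward natural-abundance convolution of a labelled mixture
#'
#' Maps true isotopologue fractions (by label count) to the raw spectrum
#' that a mass spectrometer would measure, i.e. `matrix %*% fractions`
#' renormalized to the retained window. This is the exact inverse path of
#' [correct_mid()] and is what the cohort simulator uses to emit raw MIDs.
#'
#' @param fractions True fractions by label count (length `ncol(matrix)`).
#' @param matrix Correction matrix from [natural_abundance_matrix()].
#' @return Raw spectrum over the mass window, summing to 1.
#' @export
convolve_mid <- function(fractions, matrix) {
  if (length(fractions) != ncol(matrix))
    stop("schema error: fractions length must match matrix columns")
  raw <- as.vector(matrix %*% fractions)
  raw <- raw / sum(raw)
  names(raw) <- rownames(matrix)
  raw
}

#' Tracer enrichment from a corrected MID
#'
#' Reads the fully labelled (m6) fraction of a corrected spectrum as the
#' \code{[U-13C6]} tracer enrichment. `species = "one_minus_m0"` instead
#' returns 1 minus the unlabelled fraction, an alternative reading of
#' "fraction of labelled glucose".
#'
#' @param corrected Corrected MID from [correct_mid()].
#' @param species `"m6"` (default) or `"one_minus_m0"`.
#' @return Scalar enrichment fraction.
#' @export
enrichment_from_mid <- function(corrected, species = c("m6", "one_minus_m0")) {
  species <- match.arg(species)
  if (species == "m6") {
    if (length(corrected) < 7L)
      stop("configuration error: fully labelled species m6 outside the mass window")
    unname(corrected[7L])
  } else {
    unname(1 - corrected[1L])
  }
}
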