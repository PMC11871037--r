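# Shared fixtures and independent oracles.

# A design with all assay noise switched off.
noiseless_design <- function(n = 2, protocol = "OGTT", seed = 7) {
  cohort_design(n_per_group_per_sex = n,
                noise_cv_glucose = 0, noise_cv_enrichment = 0,
                noise_cv_insulin = 0, protocol = protocol, seed = seed)
}

# Full estimation chain on one measurement record: MID correction,
# tracer fit, unlabelled curve, EGP reconstruction.
run_chain <- function(rec, mouse, M = natural_abundance_matrix()) {
  enr <- apply(rec$mid_raw, 1, function(r) enrichment_from_mid(correct_mid(r, M)))
  tracer <- rec$glucose * enr
  tf <- suppressWarnings(
    fit_tracer(rec$glucose_times, tracer,
               rec$dose_total * rec$dose_tracer_fraction, mouse$pool_volume))
  qu <- unlabeled_glucose(rec$glucose, enr)
  curve <- smooth_unlabeled(rec$glucose_times, qu)
  egp <- reconstruct_egp(curve, tf, rec$dose_total * (1 - rec$dose_tracer_fraction),
                         mouse$pool_volume)
  list(enrichment = enr, tracer = tracer, fit = tf, qu = qu,
       curve = curve, egp = egp)
}

# Brute-force natural-abundance spectrum by enumeration over all isotope
# assignments of a small ion (independent of the polynomial convolution).
enumerate_spectrum <- function(formula, abundances, n_mass) {
  shifts <- list(); probs <- list()
  for (el in names(formula)) {
    ab <- abundances[[el]]
    for (k in seq_len(formula[[el]])) {
      shifts[[length(shifts) + 1L]] <- seq_along(ab) - 1L
      probs[[length(probs) + 1L]] <- ab
    }
  }
  grid <- do.call(expand.grid, shifts)
  p <- rep(1, nrow(grid))
  for (j in seq_along(probs)) p <- p * probs[[j]][grid[[j]] + 1L]
  total <- rowSums(grid)
  out <- numeric(n_mass + 1L)
  for (m in 0:n_mass) out[m + 1L] <- sum(p[total == m])
  out
}

# Two-compartment tracer ODE integrated numerically (independent oracle
# for the closed-form solution). Returns plasma concentration.
tracer_ode_oracle <- function(t, ka, k2, amplitude) {
  out <- deSolve::lsoda(
    y = c(q1 = 1, c2 = 0),
    times = t,
    func = function(t, y, p) {
      list(c(-ka * y["q1"], amplitude * ka * y["q1"] - k2 * y["c2"]))
    },
    parms = NULL, rtol = 1e-11, atol = 1e-12)
  unname(out[, "c2"])
}
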