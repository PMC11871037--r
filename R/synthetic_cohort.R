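# Virtual-mouse cohort generator: samples ground-truth physiological
# parameters per animal and forward-simulates the tracer OGTT/MMTT
# measurement design (glucose, raw MID spectra, blood-spot insulin).
#
# All compartment ODEs are linear with exponential forcings, so the
# simulator evaluates their exact closed-form solutions; numerical
# integration appears only as an independent oracle in the test suite.

GLUCOSE_TIMES <- c(0, 5, 10, 20, 30, 45, 60, 90, 120)
INSULIN_TIMES <- c(0, 10, 30, 60, 90, 120)

#' Cohort simulation design
#'
#' Bundles the sampling design of a simulated tolerance-test cohort:
#' group sizes, group-effect multipliers, assay noise levels, protocol
#' and seed. The seed fully determines the generated cohort.
#'
#' @param n_per_group_per_sex Animals per diet group per sex (each dam
#'   contributes one male and one female, so this is also dams/group).
#' @param group_effects Named list `LF`/`HF`/`GDM`; each entry a list with
#'   optional elements `all`, `M`, `F` holding named multiplicative shifts
#'   on ground-truth parameters (`ka`, `k2`, `F`, `fasting_glucose`,
#'   `egp_basal`, `body_weight`, `ins_C`, `ins_ke`, `ins_ka`,
#'   `ins_baseline`, `egp_depth`). See [default_group_effects()].
#' @param noise_cv_glucose,noise_cv_enrichment,noise_cv_insulin
#'   Multiplicative lognormal assay CVs (defaults 3%, 2%, 10%).
#' @param protocol `"OGTT"` or `"MMTT"`. The mixed meal is emulated by
#'   slower absorption and a later EGP-suppression minimum.
#' @param seed Integer seed.
#' @return Object of class `cohort_design`.
#' @export
cohort_design <- function(n_per_group_per_sex = 2,
                          group_effects = default_group_effects(),
                          noise_cv_glucose = 0.03,
                          noise_cv_enrichment = 0.02,
                          noise_cv_insulin = 0.10,
                          protocol = c("OGTT", "MMTT"),
                          seed = 1L) {
  protocol <- match.arg(protocol)
  stopifnot(n_per_group_per_sex >= 1,
            noise_cv_glucose >= 0, noise_cv_enrichment >= 0,
            noise_cv_insulin >= 0)
  validate_group_effects(group_effects)
  structure(list(n_per_group_per_sex = as.integer(n_per_group_per_sex),
                 group_effects = group_effects,
                 noise_cv_glucose = noise_cv_glucose,
                 noise_cv_enrichment = noise_cv_enrichment,
                 noise_cv_insulin = noise_cv_insulin,
                 protocol = protocol, seed = as.integer(seed)),
            class = "cohort_design")
}

GROUPS <- c("LF", "HF", "GDM")
EFFECT_KEYS <- c("ka", "k2", "F", "fasting_glucose", "egp_basal",
                 "body_weight", "ins_C", "ins_ke", "ins_ka",
                 "ins_baseline", "egp_depth")

validate_group_effects <- function(ge) {
  if (!all(names(ge) %in% GROUPS))
    stop("configuration error: group-effect groups must be among LF/HF/GDM")
  for (g in names(ge)) {
    if (!all(names(ge[[g]]) %in% c("all", "M", "F")))
      stop("configuration error: group-effect scopes must be 'all', 'M' or 'F'")
    for (sc in names(ge[[g]])) {
      bad <- setdiff(names(ge[[g]][[sc]]), EFFECT_KEYS)
      if (length(bad))
        stop(sprintf("configuration error: unknown group-effect key(s): %s",
                     paste(bad, collapse = ", ")))
    }
  }
  invisible(TRUE)
}

#' Default group-effect multipliers
#'
#' Emulates the qualitative offspring phenotype of intrauterine
#' hyperglycaemia exposure: faster apparent glucose absorption (higher
#' ka) and a blunted insulin response in GDM offspring of both sexes,
#' with additionally lowered basal endogenous glucose production (and
#' hence lower fasting glucose and HOMA-IR) in GDM females. The HF-diet
#' group carries only a mild absorption shift.
#'
#' @return Nested list usable as `group_effects` in [cohort_design()].
#' @export
default_group_effects <- function() {
  list(
    LF = list(),
    HF = list(all = c(ka = 1.05)),
    GDM = list(all = c(ka = 1.25, ins_C = 0.70),
               F = c(egp_basal = 0.80, ins_baseline = 0.85))
  )
}

# Lognormal multiplicative jitter with unit mean and given CV.
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s <- sqrt(log1p(cv^2))
  exp(stats::rnorm(n, -s^2 / 2, s))
}

#' Sample a virtual cohort
#'
#' Draws per-animal ground-truth parameters. Each dam contributes one
#' male and one female pup (shared litter multiplier on fasting glucose
#' and insulin response), sexes differ in body weight and insulin
#' amplitude, and group effects from the design are applied as
#' multiplicative shifts. The fasting steady state
#' `egp_basal = k2 * fasting_glucose` holds for every animal; an
#' `egp_basal` shift is therefore realized through fasting glucose at
#' fixed clearance.
#'
#' @param design A [cohort_design()].
#' @return Data frame of class `virtual_cohort`, one row per animal, with
#'   the full ground-truth parameter set.
#' @export
sample_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(design$seed)
  mmtt <- design$protocol == "MMTT"
  base_ka <- if (mmtt) 0.045 * 0.6 else 0.045
  taus <- if (mmtt) c(90, 30) else c(40, 10)
  rows <- list()
  for (g in GROUPS) {
    for (d in seq_len(design$n_per_group_per_sex)) {
      dam_id <- sprintf("%s%02d", g, d)
      litter <- rlnorm_cv(1, 0.05)
      for (sex in c("M", "F")) {
        bw <- (if (sex == "M") 27 else 22) * rlnorm_cv(1, 0.08)
        ka <- base_ka * rlnorm_cv(1, 0.12)
        Fbio <- stats::plogis(stats::qlogis(0.8) + stats::rnorm(1, 0, 0.2))
        k2 <- 0.02 * rlnorm_cv(1, 0.10)
        fast <- 8.0 * litter * rlnorm_cv(1, 0.08)
        depth <- min(0.5 * rlnorm_cv(1, 0.15), 0.95)
        ins_C <- (if (sex == "M") 1.8 else 1.5) * litter * rlnorm_cv(1, 0.20)
        ins_ke <- 0.012 * rlnorm_cv(1, 0.10)
        ratio <- 4 * rlnorm_cv(1, 0.15)
        ins_ka <- ins_ke * max(ratio, 1.2)
        ins_baseline <- 0.4 * rlnorm_cv(1, 0.20)
        p <- list(body_weight = bw, ka = ka, F = Fbio, k2 = k2,
                  fasting_glucose = fast, egp_depth = depth,
                  ins_C = ins_C, ins_ke = ins_ke, ins_ka = ins_ka,
                  ins_baseline = ins_baseline)
        p <- apply_group_effects(p, design$group_effects[[g]], sex)
        rows[[length(rows) + 1L]] <- data.frame(
          id = sprintf("%s_%s_%02d", g, sex, d), dam_id = dam_id,
          group = g, sex = sex, body_weight = p$body_weight,
          k1 = p$F * p$ka, kL = (1 - p$F) * p$ka, k2_true = p$k2,
          pool_volume = 0.2 * p$body_weight,
          fasting_glucose = p$fasting_glucose,
          egp_basal = p$k2 * p$fasting_glucose,
          egp_suppression_depth = p$egp_depth,
          egp_tau1 = taus[1], egp_tau2 = taus[2],
          ins_C = p$ins_C, ins_ke = p$ins_ke, ins_ka = p$ins_ka,
          ins_baseline = p$ins_baseline, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$group <- factor(out$group, levels = GROUPS)
  class(out) <- c("virtual_cohort", "data.frame")
  out
}

apply_group_effects <- function(p, eff, sex) {
  if (is.null(eff)) return(p)
  shifts <- c(eff$all, eff[[sex]])
  for (key in names(shifts)) {
    m <- shifts[[key]]
    p <- switch(key,
      ka = { p$ka <- p$ka * m; p },
      k2 = { p$k2 <- p$k2 * m; p },
      F = { p$F <- min(p$F * m, 0.99); p },
      egp_basal = { p$fasting_glucose <- p$fasting_glucose * m; p },
      egp_depth = { p$egp_depth <- min(p$egp_depth * m, 0.95); p },
      { p[[key]] <- p[[key]] * m; p })
  }
  p
}

# Response of a k2-cleared pool to a unit exp(-lambda t) input:
# (exp(-lambda t) - exp(-k2 t)) / (k2 - lambda), limit t exp(-k2 t).
exp_response <- function(t, lambda, k2) {
  if (abs(k2 - lambda) < 1e-9 * k2) {
    t * exp(-k2 * t)
  } else {
    (exp(-lambda * t) - exp(-k2 * t)) / (k2 - lambda)
  }
}

# Ground-truth EGP (mM/min) at time t for a mouse row.
egp_true_fun <- function(mouse) {
  t1 <- mouse$egp_tau1; t2 <- mouse$egp_tau2
  tpk <- log(t1 / t2) / (1 / t2 - 1 / t1)
  smax <- exp(-tpk / t1) - exp(-tpk / t2)
  force(mouse)
  function(t) {
    dip <- (exp(-t / t1) - exp(-t / t2)) / smax
    mouse$egp_basal * (1 - mouse$egp_suppression_depth * dip)
  }
}

# Closed-form noiseless states at times t for one mouse and dose split.
# Returns tracer conc (mM), unlabelled conc (mM), total, enrichment.
true_states <- function(mouse, t, dose_total, tracer_fraction = 0.05) {
  ka <- mouse$k1 + mouse$kL
  Fbio <- mouse$k1 / ka
  k2 <- mouse$k2_true
  V <- mouse$pool_volume
  Dtr <- dose_to_conc(dose_total * tracer_fraction, V)
  Du <- dose_to_conc(dose_total * (1 - tracer_fraction), V)
  resp_ka <- vapply(t, exp_response, numeric(1), lambda = ka, k2 = k2)
  ctr <- Fbio * ka * Dtr * resp_ka
  t1 <- mouse$egp_tau1; t2 <- mouse$egp_tau2
  tpk <- log(t1 / t2) / (1 / t2 - 1 / t1)
  smax <- exp(-tpk / t1) - exp(-tpk / t2)
  dipresp <- (vapply(t, exp_response, numeric(1), lambda = 1 / t1, k2 = k2) -
                vapply(t, exp_response, numeric(1), lambda = 1 / t2, k2 = k2)) / smax
  cu <- mouse$fasting_glucose + Fbio * ka * Du * resp_ka -
    mouse$egp_basal * mouse$egp_suppression_depth * dipresp
  total <- ctr + cu
  list(tracer = ctr, unlabeled = cu, total = total,
       enrichment = ifelse(total > 0, ctr / total, 0))
}

# Analytic tracer mass balance (amounts in mg-equivalents of the dose):
# GI remainder, plasma, cumulative cleared, cumulative GI loss.
tracer_mass_balance <- function(mouse, t, dose_tracer) {
  ka <- mouse$k1 + mouse$kL
  Fbio <- mouse$k1 / ka
  k2 <- mouse$k2_true
  gi <- dose_tracer * exp(-ka * t)
  resp <- vapply(t, exp_response, numeric(1), lambda = ka, k2 = k2)
  plasma <- Fbio * ka * dose_tracer * resp
  # integral of plasma amount from 0 to t (closed form)
  int_plasma <- Fbio * ka * dose_tracer / (k2 - ka) *
    ((1 - exp(-ka * t)) / ka - (1 - exp(-k2 * t)) / k2)
  cleared <- k2 * int_plasma
  lost <- (1 - Fbio) * dose_tracer * (1 - exp(-ka * t))
  list(gi = gi, plasma = plasma, cleared = cleared, lost = lost)
}

# True (noiseless) plasma insulin (ng/mL).
insulin_true <- function(mouse, t) {
  mouse$ins_baseline + insulin_model(t, mouse$ins_C, mouse$ins_ke, mouse$ins_ka)
}

#' Forward-simulate one tolerance test
#'
#' Evaluates the closed-form tracer and unlabelled glucose solutions at
#' the protocol sampling times, convolves the true (m0, m6) mixture with
#' natural isotope abundance to raw MID spectra, generates the insulin
#' response, and applies multiplicative lognormal assay noise at the
#' design CVs. Blood-spot insulin is emitted on the spot scale (plasma /
#' 1.28). The returned record carries a `truth` element with the exact
#' noiseless states for validation.
#'
#' @param mouse One-row data frame from [sample_cohort()].
#' @param design The [cohort_design()].
#' @param seed Seed for the measurement noise; defaults to a per-animal
#'   value derived from the design seed and animal id.
#' @return A `measurement_record` list: identifiers, `glucose_times`,
#'   `glucose` (mM), `mid_raw` (times x m0..m6 matrix), `insulin_times`,
#'   `insulin_spot` (ng/mL), `dose_total` (mg), `dose_tracer_fraction`,
#'   and `truth`.
#' @export
simulate_test <- function(mouse, design,
                          seed = design$seed + sum(utf8ToInt(mouse$id))) {
  stopifnot(nrow(mouse) == 1, inherits(design, "cohort_design"))
  set.seed(seed)
  dose_total <- 1.0 * mouse$body_weight  # 1 g/kg BW, in mg
  st <- true_states(mouse, GLUCOSE_TIMES, dose_total)
  if (any(!is.finite(st$total)))
    stop(sprintf("numerical error simulating %s (ka=%.4g, k2=%.4g)",
                 mouse$id, mouse$k1 + mouse$kL, mouse$k2_true))
  glucose <- st$total * rlnorm_cv(length(GLUCOSE_TIMES), design$noise_cv_glucose)
  M <- natural_abundance_matrix()
  # the noise CV applies to the enrichment reading itself, so perturb the
  # true label fraction before the natural-abundance convolution
  enr_noisy <- pmin(st$enrichment *
                      rlnorm_cv(length(GLUCOSE_TIMES),
                                design$noise_cv_enrichment), 1)
  mid_raw <- t(vapply(seq_along(GLUCOSE_TIMES), function(i) {
    e <- enr_noisy[i]
    convolve_mid(c(1 - e, 0, 0, 0, 0, 0, e), M)
  }, numeric(7)))
  rownames(mid_raw) <- paste0("t", GLUCOSE_TIMES)
  ins_true <- insulin_true(mouse, INSULIN_TIMES)
  ins_meas <- ins_true * rlnorm_cv(length(INSULIN_TIMES), design$noise_cv_insulin)
  egp_fun <- egp_true_fun(mouse)
  structure(list(
    animal = mouse$id, dam_id = mouse$dam_id,
    group = as.character(mouse$group), sex = mouse$sex,
    body_weight = mouse$body_weight, protocol = design$protocol,
    glucose_times = GLUCOSE_TIMES, glucose = glucose,
    mid_raw = mid_raw,
    insulin_times = INSULIN_TIMES,
    insulin_spot = ins_meas / 1.28,
    dose_total = dose_total, dose_tracer_fraction = 0.05,
    truth = list(tracer_conc = st$tracer, unlabeled = st$unlabeled,
                 total = st$total, enrichment = st$enrichment,
                 insulin_plasma = ins_true,
                 egp_grid = 0:120, egp_true = egp_fun(0:120))),
    class = "measurement_record")
}

#' Simulate a full cohort
#'
#' @param design A [cohort_design()].
#' @return List with `mice` (the [sample_cohort()] table) and `records`
#'   (one [simulate_test()] record per animal).
#' @export
simulate_cohort <- function(design) {
  mice <- sample_cohort(design)
  records <- lapply(seq_len(nrow(mice)), function(i)
    simulate_test(mice[i, ], design, seed = design$seed * 1000L + i))
  names(records) <- mice$id
  list(mice = mice, records = records)
}

#' Write a simulated dataset to disk
#'
#' Long-format measurement CSV (`data.csv`: animal_id, dam_id, group,
#' sex, body_weight_g, protocol, time_min, analyte, value with analyte in
#' glucose / insulin / mid_m0..mid_m6), per-animal metadata CSV
#' (`animals.csv`, including doses) and a JSON ground-truth sidecar
#' (`truth.json`) keyed by animal id. Round-trips losslessly through
#' [read_dataset()].
#'
#' @param records List of `measurement_record`s.
#' @param mice `virtual_cohort` table (ground truth; omit with NULL to
#'   skip the sidecar).
#' @param path Output directory (created if missing).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(records, mice, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(records, function(r) {
    meta <- data.frame(animal_id = r$animal, dam_id = r$dam_id,
                       group = r$group, sex = r$sex,
                       body_weight_g = signif(r$body_weight, 6),
                       protocol = r$protocol,
                       stringsAsFactors = FALSE)
    g <- cbind(meta, time_min = r$glucose_times, analyte = "glucose",
               value = r$glucose, row.names = NULL)
    mids <- do.call(rbind, lapply(0:6, function(m)
      cbind(meta, time_min = r$glucose_times, analyte = paste0("mid_m", m),
            value = r$mid_raw[, m + 1L], row.names = NULL)))
    ins <- cbind(meta, time_min = r$insulin_times, analyte = "insulin",
                 value = r$insulin_spot, row.names = NULL)
    rbind(g, mids, ins)
  })
  data <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  data$value <- signif(data$value, 6)
  utils::write.csv(data, file.path(path, "data.csv"), row.names = FALSE)
  animals <- do.call(rbind, lapply(records, function(r)
    data.frame(animal_id = r$animal, dam_id = r$dam_id, group = r$group,
               sex = r$sex, body_weight_g = signif(r$body_weight, 6),
               protocol = r$protocol, dose_total_mg = signif(r$dose_total, 6),
               dose_tracer_fraction = r$dose_tracer_fraction,
               stringsAsFactors = FALSE)))
  utils::write.csv(animals, file.path(path, "animals.csv"), row.names = FALSE)
  if (!is.null(mice)) {
    truth <- split(as.data.frame(mice)[setdiff(names(mice), "id")],
                   seq_len(nrow(mice)))
    names(truth) <- mice$id
    truth <- lapply(truth, function(x) as.list(x[1, ]))
    jsonlite::write_json(truth, file.path(path, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param path Dataset directory.
#' @return List with `data` (long measurement table), `animals`
#'   (metadata) and `truth` (ground-truth list, or NULL when absent).
#' @export
read_dataset <- function(path) {
  fd <- file.path(path, "data.csv")
  fa <- file.path(path, "animals.csv")
  if (!file.exists(fd) || !file.exists(fa))
    stop("I/O error: dataset directory must contain data.csv and animals.csv")
  data <- utils::read.csv(fd, stringsAsFactors = FALSE)
  animals <- utils::read.csv(fa, stringsAsFactors = FALSE)
  ft <- file.path(path, "truth.json")
  truth <- if (file.exists(ft)) jsonlite::read_json(ft, simplifyVector = TRUE) else NULL
  list(data = data, animals = animals, truth = truth)
}
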