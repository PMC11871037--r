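test_that("cohort sampling is seeded, sized and validated", {
  des <- cohort_design(2, seed = 7)
  m1 <- sample_cohort(des)
  m2 <- sample_cohort(des)
  expect_identical(m1, m2)                               # seeded determinism
  expect_identical(nrow(m1), 12L)                        # 3 groups x 2 sexes x 2
  expect_identical(as.integer(table(m1$group)), c(4L, 4L, 4L))
  expect_identical(length(unique(m1$dam_id)), 6L)        # one M + one F per dam
  m3 <- sample_cohort(cohort_design(2, seed = 8))
  expect_false(isTRUE(all.equal(m1$k1, m3$k1)))          # seed changes draws
  expect_error(cohort_design(2, group_effects = list(GDM = list(all = c(foo = 2)))),
               "configuration")
  expect_error(cohort_design(2, group_effects = list(XX = list())),
               "configuration")
})

test_that("ground-truth invariants hold for every sampled animal", {
  for (prot in c("OGTT", "MMTT")) {
    mice <- sample_cohort(cohort_design(3, protocol = prot, seed = 5))
    rates <- c(mice$k1, mice$kL, mice$k2_true, mice$ins_ke, mice$ins_ka)
    expect_true(all(rates >= 0))
    expect_true(all(mice$k1 > 0 & mice$k2_true > 0))
    expect_equal(mice$egp_basal, mice$k2_true * mice$fasting_glucose,
                 tolerance = 1e-12)                      # fasting steady state
    expect_true(all(mice$egp_suppression_depth <= 1))
    expect_true(all(mice$ins_ka > mice$ins_ke))
    expect_equal(mice$pool_volume, 0.2 * mice$body_weight, tolerance = 1e-12)
  }
})

test_that("group effects shift parameters as configured", {
  des_null <- cohort_design(3, group_effects = list(LF = list(), HF = list(),
                                                    GDM = list()), seed = 9)
  des_eff <- cohort_design(3, seed = 9)  # default effects
  m0 <- sample_cohort(des_null); m1 <- sample_cohort(des_eff)
  # same seed: the GDM ka values differ exactly by the configured factor
  gdm <- m1$group == "GDM"
  expect_equal((m1$k1 + m1$kL)[gdm], 1.25 * (m0$k1 + m0$kL)[gdm],
               tolerance = 1e-12)
  gdm_f <- gdm & m1$sex == "F"
  expect_equal(m1$fasting_glucose[gdm_f], 0.8 * m0$fasting_glucose[gdm_f],
               tolerance = 1e-12)
  expect_equal(m1$ins_C[gdm], 0.7 * m0$ins_C[gdm], tolerance = 1e-12)
  # LF untouched
  lf <- m1$group == "LF"
  expect_identical(m1$k1[lf], m0$k1[lf])
})

test_that("dosing follows 1 g/kg with a 5% tracer share", {
  des <- noiseless_design()
  mice <- sample_cohort(des)
  m <- mice[1, ]; m$body_weight <- 25; m$pool_volume <- 5
  rec <- simulate_test(m, des)
  expect_equal(rec$dose_total, 25)                       # mg for a 25 g mouse
  expect_equal(rec$dose_total * rec$dose_tracer_fraction, 1.25)
})

test_that("noiseless enrichment never exceeds the 5% bolus enrichment", {
  for (prot in c("OGTT", "MMTT")) {
    des <- noiseless_design(n = 2, protocol = prot, seed = 13)
    sim <- simulate_cohort(des)
    for (r in sim$records) {
      expect_true(all(r$truth$enrichment <= 0.05 + 1e-12))
      expect_true(all(r$truth$enrichment >= 0))
    }
  }
})

test_that("zero suppression leaves only the absorption transient", {
  des <- noiseless_design()
  mice <- sample_cohort(des)
  m <- mice[1, ]
  m$egp_suppression_depth <- 0
  rec <- simulate_test(m, des)
  expect_true(all(abs(rec$truth$egp_true - m$egp_basal) < 1e-12))
  # unlabelled pool = fasting level + scaled copy of the tracer transient
  # (tracee dose is 19x the tracer dose)
  expect_equal(rec$truth$unlabeled - m$fasting_glucose,
               19 * rec$truth$tracer, tolerance = 1e-10)
})

test_that("tracer mass is conserved among GI, plasma, cleared and lost", {
  mice <- sample_cohort(noiseless_design())
  m <- mice[6, ]
  dose_tr <- 0.05 * m$body_weight
  t <- c(0, 1, 7, 30, 60, 120, 500)
  mb <- tracegtt:::tracer_mass_balance(m, t, dose_tr)
  total <- mb$gi + mb$plasma + mb$cleared + mb$lost
  expect_lt(max(abs(total - dose_tr)), 1e-8 * dose_tr)
  # and the closed-form plasma amount matches numerical integration
  ka <- m$k1 + m$kL
  ode_plasma <- tracer_ode_oracle(0:120, ka, m$k2_true, (m$k1 / ka) * dose_tr)
  cf_plasma <- tracegtt:::tracer_mass_balance(m, 0:120, dose_tr)$plasma
  expect_lt(max(abs(ode_plasma - cf_plasma)), 1e-8 * dose_tr)
})

test_that("noiseless measurements pass through the full estimation chain", {
  des <- noiseless_design(seed = 19)
  mice <- sample_cohort(des)
  for (i in c(2, 9)) {
    m <- mice[i, ]
    rec <- simulate_test(m, des)
    ch <- run_chain(rec, m)
    ka_true <- m$k1 + m$kL
    expect_lt(abs(ch$fit$ka - ka_true) / ka_true, 0.01)
    expect_lt(abs(ch$fit$k2 - m$k2_true) / m$k2_true, 0.01)
    idx <- ch$egp$grid >= 5
    expect_lt(max(abs(ch$egp$egp[idx] - rec$truth$egp_true[idx]) /
                    rec$truth$egp_true[idx]), 0.05)
    # the simulator's internal unlabelled state is recovered exactly
    expect_equal(unname(ch$qu), rec$truth$unlabeled, tolerance = 1e-8)
  }
})

test_that("datasets round-trip through disk", {
  des <- cohort_design(2, seed = 23)
  sim <- simulate_cohort(des)
  dir <- file.path(tempdir(), "ds_roundtrip")
  write_dataset(sim$records, sim$mice, dir)
  ds <- read_dataset(dir)
  # 12 animals x 9 glucose times
  expect_identical(nrow(ds$data[ds$data$analyte == "glucose", ]), 108L)
  expect_identical(nrow(ds$animals), 12L)
  # sidecar holds every ground-truth field for every animal
  expect_setequal(names(ds$truth), sim$mice$id)
  expect_true(all(setdiff(names(sim$mice), "id") %in%
                    names(ds$truth[[sim$mice$id[1]]])))
  # write the read-back tables again: byte-identical files
  dir2 <- file.path(tempdir(), "ds_roundtrip2")
  dir.create(dir2, showWarnings = FALSE)
  utils::write.csv(ds$data, file.path(dir2, "data.csv"), row.names = FALSE)
  expect_identical(readBin(file.path(dir, "data.csv"), "raw", 1e6),
                   readBin(file.path(dir2, "data.csv"), "raw", 1e6))
  # values survive the 6-significant-digit serialization
  rec <- sim$records[[1]]
  g <- ds$data[ds$data$animal_id == rec$animal & ds$data$analyte == "glucose", ]
  expect_equal(g$value[order(g$time_min)], rec$glucose, tolerance = 1e-5)
})
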