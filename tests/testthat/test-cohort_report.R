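test_that("partial AUC matches trapezoid arithmetic and closed forms", {
  expect_equal(auc_partial(c(0, 10, 20), c(5, 7, 5), 0, 20), 120)
  expect_equal(auc_partial(c(0, 15, 30), c(5, 5, 5), 0, 30), 150)
  # linear series: integral of (2 + 0.1 t) on [0, 30] = 105
  t <- c(0, 5, 10, 20, 30, 45)
  expect_equal(auc_partial(t, 2 + 0.1 * t, 0, 30), 105)
  # edge interpolation inside a segment: same linear closed form
  expect_equal(auc_partial(t, 2 + 0.1 * t, 7, 23), 2 * 16 + 0.1 * (23^2 - 7^2) / 2)
  expect_error(auc_partial(t, 2 + 0.1 * t, 30, 30), "domain")
  expect_error(auc_partial(t, 2 + 0.1 * t, 0, 60), "domain")
})

make_groups <- function(values_by_group, dams_per_group = NULL) {
  do.call(rbind, lapply(names(values_by_group), function(g) {
    v <- values_by_group[[g]]
    data.frame(value = v, group = g,
               dam_id = paste0(g, seq_along(v)))
  }))
}

test_that("identical groups give F = 0 and p = 1", {
  df <- make_groups(list(LF = c(1, 2, 3), HF = c(1, 2, 3), GDM = c(1, 2, 3)))
  tab <- one_way_anova_tukey(df)
  expect_equal(tab$statistic[tab$contrast == "ANOVA"], 0)
  expect_equal(tab$p[tab$contrast == "ANOVA"], 1)
  expect_true(all(tab$p_adj[-1] > 0.999))
  expect_false(any(tab$significant))
})

test_that("a five-sd group shift is detected in every GDM contrast", {
  set.seed(31)
  df <- make_groups(list(LF = stats::rnorm(10), HF = stats::rnorm(10),
                         GDM = stats::rnorm(10) + 5))
  tab <- one_way_anova_tukey(df)
  gdm <- grepl("GDM", tab$contrast)
  expect_true(all(tab$significant[gdm]))
  expect_true(tab$significant[tab$contrast == "ANOVA"])
})

test_that("the ANOVA F matches a from-scratch sums-of-squares oracle", {
  set.seed(32)
  vals <- list(LF = stats::rnorm(6, 10), HF = stats::rnorm(6, 11),
               GDM = stats::rnorm(6, 12))
  df <- make_groups(vals)
  tab <- one_way_anova_tukey(df)
  y <- unlist(vals); g <- rep(names(vals), each = 6)
  ssb <- sum(tapply(y, g, function(x) length(x) * (mean(x) - mean(y))^2))
  ssw <- sum(tapply(y, g, function(x) sum((x - mean(x))^2)))
  F_oracle <- (ssb / 2) / (ssw / (length(y) - 3))
  expect_equal(tab$statistic[tab$contrast == "ANOVA"], F_oracle,
               tolerance = 1e-10)
})

test_that("dam averaging respects litter structure", {
  # two same-sex siblings per dam; balanced litters leave group means as
  # the pup-level means, and n is the number of dams
  df <- data.frame(value = c(1, 3, 5, 7, 2, 4, 6, 8),
                   group = rep(c("LF", "GDM"), each = 4),
                   sex = "F",
                   dam_id = c("a", "a", "b", "b", "c", "c", "d", "d"))
  dd <- tracegtt:::dam_average(df)
  expect_identical(nrow(dd), 4L)
  expect_equal(sort(tapply(dd$value, dd$group, mean)),
               sort(tapply(df$value, df$group, mean)))
  expect_error(one_way_anova_tukey(df[df$dam_id != "a", ]), "insufficient")
})

test_that("exactly additive two-way layouts have zero interaction", {
  sexes <- c("M", "F"); groups <- c("LF", "HF", "GDM")
  a <- c(M = 1, F = 3); b <- c(LF = 0, HF = 2, GDM = 5)
  rows <- list()
  for (s in sexes) for (g in groups) for (d in 1:3) {
    rows[[length(rows) + 1L]] <- data.frame(
      value = a[[s]] + b[[g]] + c(-0.5, 0, 0.5)[d],  # cell means stay additive
      group = g, sex = s, dam_id = paste0(g, d))
  }
  df <- do.call(rbind, rows)
  tab <- two_way_anova(df)
  expect_equal(tab$statistic[tab$term == "sex:group"], 0, tolerance = 1e-10)
  expect_equal(tab$p[tab$term == "sex:group"], 1, tolerance = 1e-6)
  expect_true(tab$p[tab$term == "sex"] < 0.05)
  expect_true(tab$p[tab$term == "group"] < 0.05)
})

test_that("an injected sex effect is attributed to sex, not group", {
  set.seed(33)
  df <- expand.grid(sex = c("M", "F"), group = c("LF", "HF", "GDM"),
                    dam = 1:10)
  df$dam_id <- paste0(df$group, df$dam)
  df$value <- stats::rnorm(nrow(df)) + ifelse(df$sex == "M", 2, 0)
  tab <- two_way_anova(df)
  expect_lt(tab$p[tab$term == "sex"], 1e-4)
  expect_gt(tab$p[tab$term == "group"], 0.01)
})

test_that("type-II sums of squares equal sequential ones for balanced designs", {
  set.seed(34)
  df <- expand.grid(sex = c("M", "F"), group = c("LF", "HF", "GDM"), dam = 1:4)
  df$dam_id <- paste0(df$group, df$sex, df$dam)
  df$value <- stats::rnorm(nrow(df), mean = as.integer(df$group))
  tab <- two_way_anova(df)
  seq_ss <- stats::anova(stats::lm(value ~ sex * group, df))
  expect_equal(tab$sumsq[tab$term == "sex"], seq_ss["sex", "Sum Sq"],
               tolerance = 1e-10)
  expect_equal(tab$sumsq[tab$term == "group"], seq_ss["group", "Sum Sq"],
               tolerance = 1e-10)
})

test_that("type-I error stays nominal when all group effects are identity", {
  null_effects <- list(LF = list(), HF = list(), GDM = list())
  hits <- 0; n_seeds <- 12
  for (s in seq_len(n_seeds)) {
    des <- cohort_design(4, group_effects = null_effects, seed = 100 + s)
    mice <- sample_cohort(des)
    df <- data.frame(value = mice$k1 + mice$kL, group = mice$group,
                     sex = mice$sex, dam_id = mice$dam_id)
    tab <- one_way_anova_tukey(df[df$sex == "F", ])
    hits <- hits + (tab$p[tab$contrast == "ANOVA"] < 0.05)
  }
  # Binomial(12, 0.05): seeing 4+ false positives has probability ~2e-3
  expect_lte(hits, 3)
})

test_that("the pipeline is deterministic and isolates per-animal failures", {
  fx <- system.file("extdata", "ogtt12_synthetic", package = "tracegtt")
  out1 <- file.path(tempdir(), "rep1"); out2 <- file.path(tempdir(), "rep2")
  r1 <- suppressWarnings(run_pipeline(list(dataset = fx), out1, plots = FALSE))
  r2 <- suppressWarnings(run_pipeline(list(dataset = fx), out2, plots = FALSE))
  expect_length(r1$failed, 0)
  for (f in c("per_animal.csv", "group_summary.csv", "statistics.csv")) {
    expect_identical(readBin(file.path(out1, f), "raw", 1e6),
                     readBin(file.path(out2, f), "raw", 1e6))
  }
  # drop one animal's insulin -> only that animal is flagged
  ds <- read_dataset(fx)
  drop_id <- ds$animals$animal_id[1]
  ds$data <- ds$data[!(ds$data$animal_id == drop_id &
                         ds$data$analyte == "insulin"), ]
  r3 <- suppressWarnings(analyze_cohort(ds))
  expect_named(r3$failed, drop_id)
  keep <- setdiff(r1$per_animal$animal_id, drop_id)
  cols <- c("ka", "k2", "egp_overall", "homa_ir")
  expect_equal(r3$per_animal[match(keep, r3$per_animal$animal_id), cols],
               r1$per_animal[match(keep, r1$per_animal$animal_id), cols],
               tolerance = 1e-12, ignore_attr = TRUE)
})
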