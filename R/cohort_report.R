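# Cohort-level analysis: AUC summaries, dam-as-experimental-unit group
# statistics, and the end-to-end pipeline chaining MID correction, tracer
# and insulin fits, EGP reconstruction and sensitivity indices.

#' Trapezoidal AUC over a sub-window
#'
#' Trapezoidal area of the raw measured points restricted to
#' `[t_start, t_end]`, with linear interpolation at the window edges when
#' they fall between samples.
#'
#' @param times Sampling times (min), increasing.
#' @param values Measured values at `times`.
#' @param t_start,t_end Window bounds (must lie within the sampled range).
#' @return Trapezoidal AUC (value units x min).
#' @export
#' @examples
#' auc_partial(c(0, 10, 20), c(5, 7, 5), 0, 20)  # 120
auc_partial <- function(times, values, t_start, t_end) {
  if (t_end <= t_start) stop("domain error: empty window")
  if (t_start < min(times) || t_end > max(times))
    stop("domain error: window outside sampled range")
  edge <- stats::approx(times, values, xout = c(t_start, t_end))$y
  keep <- times > t_start & times < t_end
  tt <- c(t_start, times[keep], t_end)
  vv <- c(edge[1], values[keep], edge[2])
  pracma::trapz(tt, vv)
}

# Average same-sex siblings per dam: returns one row per dam (x sex if
# present) so that the dam is the experimental unit.
dam_average <- function(df, value_col = "value") {
  by_cols <- intersect(c("dam_id", "group", "sex"), names(df))
  agg <- stats::aggregate(df[[value_col]], df[by_cols], mean)
  names(agg)[ncol(agg)] <- value_col
  agg
}

#' One-way group comparison with Tukey HSD, dam as experimental unit
#'
#' Same-sex siblings are averaged per dam, then a one-way ANOVA across
#' diet groups is followed by Tukey's honest significant difference test.
#' Two-sided p < 0.05 is flagged as significant.
#'
#' @param df Data frame with columns `value`, `group`, `dam_id` (already
#'   restricted to one sex if sex-stratified analysis is wanted).
#' @param value_col Name of the value column (default `"value"`).
#' @return Data frame: one `ANOVA` row (F statistic, p) and one row per
#'   pairwise Tukey contrast (difference estimate, adjusted p).
#' @export
one_way_anova_tukey <- function(df, value_col = "value") {
  df$group <- droplevels(factor(df$group))
  dd <- dam_average(df, value_col)
  counts <- table(dd$group)
  if (length(counts) < 2 || any(counts < 2))
    stop("insufficient data: need >= 2 groups with >= 2 dams each")
  dd$.y <- dd[[value_col]]
  fit <- stats::aov(.y ~ group, data = dd)
  an <- summary(fit)[[1]]
  Fv <- an$`F value`[1]; pv <- an$`Pr(>F)`[1]
  tk <- stats::TukeyHSD(fit)$group
  out <- data.frame(
    contrast = c("ANOVA", rownames(tk)),
    estimate = c(NA_real_, tk[, "diff"]),
    statistic = c(Fv, rep(NA_real_, nrow(tk))),
    p = c(pv, rep(NA_real_, nrow(tk))),
    p_adj = c(NA_real_, tk[, "p adj"]),
    stringsAsFactors = FALSE)
  out$significant <- ifelse(is.na(out$p_adj), out$p < 0.05, out$p_adj < 0.05)
  rownames(out) <- NULL
  out
}

#' Two-way sex-by-group ANOVA, dam as experimental unit
#'
#' Same-sex siblings are averaged per dam and sex, then sex, group and
#' their interaction are tested with type-II sums of squares
#' ([car::Anova()]), appropriate for the unbalanced layouts that litter
#' attrition produces.
#'
#' @param df Data frame with columns `value`, `group`, `sex`, `dam_id`.
#' @param value_col Name of the value column.
#' @return Data frame with one row per term: sum of squares, df, F, p.
#' @export
two_way_anova <- function(df, value_col = "value") {
  df$group <- droplevels(factor(df$group))
  df$sex <- droplevels(factor(df$sex))
  dd <- dam_average(df, value_col)
  cell <- table(dd$group, dd$sex)
  if (any(cell < 2))
    stop("insufficient data: need >= 2 dams in every sex x group cell")
  dd$.y <- dd[[value_col]]
  fit <- stats::lm(.y ~ sex * group, data = dd)
  an <- car::Anova(fit, type = 2)
  data.frame(term = rownames(an)[-nrow(an)],
             sumsq = an$`Sum Sq`[-nrow(an)],
             df = an$Df[-nrow(an)],
             statistic = an$`F value`[-nrow(an)],
             p = an$`Pr(>F)`[-nrow(an)],
             stringsAsFactors = FALSE)
}

# Analyze one animal's long-format measurements; returns a one-row
# data.frame of fitted quantities, or signals an error.
analyze_animal <- function(meas, meta, M = natural_abundance_matrix(),
                           spot_factor = 1.28, ins_uU_per_ng = 23.1,
                           smooth_method = "monoH.FC") {
  gl <- meas[meas$analyte == "glucose", ]
  gl <- gl[order(gl$time_min), ]
  times <- gl$time_min
  glucose <- gl$value
  mid_cols <- paste0("mid_m", 0:6)
  mid <- sapply(mid_cols, function(a) {
    x <- meas[meas$analyte == a, ]
    x$value[order(x$time_min)]
  })
  enrichment <- apply(mid, 1, function(raw)
    enrichment_from_mid(correct_mid(raw, M)))
  pool_volume <- 0.2 * meta$body_weight_g
  dose_tracer <- meta$dose_total_mg * meta$dose_tracer_fraction
  dose_unlab <- meta$dose_total_mg * (1 - meta$dose_tracer_fraction)
  tracer_conc <- glucose * enrichment
  tfit <- fit_tracer(times, tracer_conc, dose_tracer, pool_volume)
  if (!isTRUE(tfit$converged)) stop("tracer fit did not converge")
  ins <- meas[meas$analyte == "insulin", ]
  ins <- ins[order(ins$time_min), ]
  ins_plasma <- blood_spot_to_plasma(ins$value, spot_factor)
  ifit <- fit_insulin(ins$time_min, ins_plasma)
  if (!isTRUE(ifit$converged)) stop("insulin fit did not converge")
  qu <- unlabeled_glucose(glucose, enrichment)
  curve <- smooth_unlabeled(times, qu, method = smooth_method)
  egp <- reconstruct_egp(curve, tfit, dose_unlab, pool_volume)
  ins_0_120 <- average_insulin(ifit, 0, 120)
  ins_5_120 <- average_insulin(ifit, 5, 120)
  ins_uU <- insulin_ng_to_uU(ins_plasma, ins_uU_per_ng)
  data.frame(
    animal_id = meta$animal_id, dam_id = meta$dam_id, group = meta$group,
    sex = meta$sex, protocol = meta$protocol,
    body_weight_g = meta$body_weight_g,
    ka = tfit$ka, k2 = tfit$k2, F = tfit$F, k1 = tfit$k1, kL = tfit$kL,
    tracer_sse = tfit$residual_sse,
    ins_C = ifit$C, ins_ke = ifit$ke, ins_ka = ifit$ka_ins,
    ins_baseline = ifit$baseline,
    ins_avg_0_120 = ins_0_120, ins_avg_5_120 = ins_5_120,
    egp_steady = egp$egp_steady, egp_overall = egp$egp_overall,
    egp_negative_fraction = egp$negative_fraction,
    fasting_glucose = glucose[times == 0],
    auc_glucose_0_30 = auc_partial(times, glucose, 0, 30),
    auc_insulin_0_30 = auc_partial(ins$time_min, ins_plasma, 0, 30),
    is_p = is_peripheral(tfit$k2, ins_0_120),
    homa_ir = homa_ir(glucose[times == 0],
                      insulin_ng_to_uU(ins_plasma[ins$time_min == 0],
                                       ins_uU_per_ng)),
    matsuda = matsuda(glucose, ins_uU, times, ins$time_min),
    converged = TRUE, stringsAsFactors = FALSE)
}

ENDPOINTS <- c("ka", "k2", "F", "egp_steady", "egp_overall",
               "ins_avg_0_120", "auc_glucose_0_30", "auc_insulin_0_30",
               "is_p", "is_l", "homa_ir", "matsuda")

#' Analyze a tolerance-test cohort
#'
#' Runs the full estimation chain per animal (natural-abundance MID
#' correction, tracer-kinetics fit, insulin fit, EGP reconstruction,
#' index computation), then attaches the cohort-referenced hepatic index
#' IS-L (reference means taken per sex within the analyzed cohort, on the
#' 5-120 min window), dam-averaged group summaries (mean +/- SEM with the
#' dam as experimental unit) and group statistics (per-sex one-way ANOVA
#' + Tukey, plus two-way sex x group ANOVA) per endpoint. Animals whose
#' fits fail are flagged and excluded from statistics; the pipeline
#' continues.
#'
#' @param dataset A dataset list from [read_dataset()] /
#'   [simulate_cohort()] output written by [write_dataset()], or a path
#'   to a dataset directory.
#' @param isl_window IS-L averaging window (min), default `c(5, 120)`.
#' @param smooth_method Interpolation scheme for [smooth_unlabeled()].
#' @return Object of class `cohort_result`: `per_animal`, `group_summary`,
#'   `statistics`, `failed` (per-animal failure messages, if any).
#' @export
analyze_cohort <- function(dataset, isl_window = c(5, 120),
                           smooth_method = "monoH.FC") {
  if (is.character(dataset)) dataset <- read_dataset(dataset)
  M <- natural_abundance_matrix()
  per <- list(); failed <- list()
  for (i in seq_len(nrow(dataset$animals))) {
    meta <- dataset$animals[i, ]
    meas <- dataset$data[dataset$data$animal_id == meta$animal_id, ]
    res <- tryCatch(
      analyze_animal(meas, meta, M, smooth_method = smooth_method),
      error = function(e) e)
    if (inherits(res, "error")) {
      failed[[meta$animal_id]] <- conditionMessage(res)
      message(sprintf("animal %s failed: %s", meta$animal_id,
                      conditionMessage(res)))
    } else per[[meta$animal_id]] <- res
  }
  per_animal <- do.call(rbind, c(per, list(make.row.names = FALSE)))
  # IS-L: cohort reference means per sex (same protocol per dataset)
  per_animal$is_l <- NA_real_
  for (sx in unique(per_animal$sex)) {
    sel <- per_animal$sex == sx
    egp_ref <- mean(per_animal$egp_overall[sel])
    ins_ref <- mean(per_animal$ins_avg_5_120[sel])
    per_animal$is_l[sel] <- is_liver(per_animal$egp_overall[sel],
                                     per_animal$ins_avg_5_120[sel],
                                     egp_ref, ins_ref)
  }
  group_summary <- cohort_group_summary(per_animal)
  statistics <- cohort_statistics(per_animal)
  structure(list(per_animal = per_animal, group_summary = group_summary,
                 statistics = statistics, failed = failed,
                 isl_window = isl_window), class = "cohort_result")
}

cohort_group_summary <- function(per_animal) {
  out <- list()
  for (ep in ENDPOINTS) {
    df <- data.frame(value = per_animal[[ep]], group = per_animal$group,
                     sex = per_animal$sex, dam_id = per_animal$dam_id)
    dd <- dam_average(df)
    agg <- stats::aggregate(value ~ group + sex, dd, function(x)
      c(mean = mean(x), sem = stats::sd(x) / sqrt(length(x)), n = length(x)))
    out[[ep]] <- data.frame(endpoint = ep, group = agg$group, sex = agg$sex,
                            mean = agg$value[, "mean"],
                            sem = agg$value[, "sem"],
                            n_dams = agg$value[, "n"],
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

cohort_statistics <- function(per_animal) {
  out <- list()
  for (ep in ENDPOINTS) {
    df <- data.frame(value = per_animal[[ep]], group = per_animal$group,
                     sex = per_animal$sex, dam_id = per_animal$dam_id)
    for (sx in unique(df$sex)) {
      tab <- tryCatch(one_way_anova_tukey(df[df$sex == sx, ]),
                      error = function(e) NULL)
      if (!is.null(tab))
        out[[paste(ep, sx)]] <- cbind(endpoint = ep, sex = sx, test = "one_way",
                                      tab[c("contrast", "estimate", "statistic",
                                            "p", "p_adj", "significant")])
    }
    tw <- tryCatch(two_way_anova(df), error = function(e) NULL)
    if (!is.null(tw))
      out[[paste(ep, "2w")]] <- cbind(
        endpoint = ep, sex = "both", test = "two_way",
        data.frame(contrast = tw$term, estimate = NA_real_,
                   statistic = tw$statistic, p = tw$p, p_adj = NA_real_,
                   significant = tw$p < 0.05))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("Cohort analysis: %d animals analyzed, %d failed\n",
              nrow(x$per_animal), length(x$failed)))
  cat("Endpoints:", paste(ENDPOINTS, collapse = ", "), "\n")
  invisible(x)
}

#' Run the full cohort pipeline and write a report
#'
#' Loads (or simulates) a dataset, runs [analyze_cohort()], and writes
#' `per_animal.csv`, `group_summary.csv`, `statistics.csv` and group-mean
#' time-course / index plots into `out_dir`. Output tables are plain CSV
#' with fixed formatting, so a rerun with the same config and seed is
#' byte-identical.
#'
#' @param config Either a path to a YAML file or a list. Recognized
#'   entries: `dataset` (path to an existing dataset directory) or the
#'   [cohort_design()] fields (`n_per_group_per_sex`, `protocol`, noise
#'   CVs, `seed`) to simulate one.
#' @param out_dir Report output directory.
#' @param seed Overrides the config seed when not NULL.
#' @param plots Write PNG figures (default TRUE).
#' @return The `cohort_result`, invisibly.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL, plots = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(config$dataset)) {
    dataset <- read_dataset(config$dataset)
  } else {
    des <- cohort_design(
      n_per_group_per_sex = config$n_per_group_per_sex %||% 2,
      noise_cv_glucose = config$noise_cv_glucose %||% 0.03,
      noise_cv_enrichment = config$noise_cv_enrichment %||% 0.02,
      noise_cv_insulin = config$noise_cv_insulin %||% 0.10,
      protocol = config$protocol %||% "OGTT",
      seed = seed %||% config$seed %||% 1L)
    sim <- simulate_cohort(des)
    ds_dir <- file.path(out_dir, "dataset")
    write_dataset(sim$records, sim$mice, ds_dir)
    dataset <- read_dataset(ds_dir)
  }
  res <- analyze_cohort(dataset)
  write_table <- function(df, file) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, 8))
    utils::write.csv(df, file.path(out_dir, file), row.names = FALSE)
  }
  write_table(res$per_animal, "per_animal.csv")
  write_table(res$group_summary, "group_summary.csv")
  write_table(res$statistics, "statistics.csv")
  if (plots) report_plots(dataset, res, out_dir)
  invisible(res)
}

# Group-mean time-course and index plots for the report.
report_plots <- function(dataset, res, out_dir) {
  pdir <- file.path(out_dir, "plots")
  dir.create(pdir, showWarnings = FALSE)
  groups <- GROUPS[GROUPS %in% unique(dataset$animals$group)]
  cols <- stats::setNames(c("#1b9e77", "#d95f02", "#7570b3")[seq_along(groups)],
                          groups)
  curve_plot <- function(analyte, ylab, file) {
    d <- dataset$data[dataset$data$analyte == analyte, ]
    grDevices::png(file.path(pdir, file), width = 900, height = 450)
    graphics::par(mfrow = c(1, 2))
    for (sx in c("M", "F")) {
      ds <- d[d$sex == sx, ]
      agg <- stats::aggregate(value ~ time_min + group, ds, mean)
      graphics::plot(range(agg$time_min), range(agg$value), type = "n",
                     xlab = "time (min)", ylab = ylab,
                     main = sprintf("%s (%s)", analyte, sx))
      for (g in groups) {
        a <- agg[agg$group == g, ]
        graphics::lines(a$time_min, a$value, col = cols[[g]], lwd = 2)
        graphics::points(a$time_min, a$value, col = cols[[g]], pch = 16)
      }
      graphics::legend("topright", legend = groups, col = cols, lwd = 2,
                       bty = "n")
    }
    grDevices::dev.off()
  }
  curve_plot("glucose", "blood glucose (mM)", "glucose.png")
  curve_plot("insulin", "blood-spot insulin (ng/mL)", "insulin.png")
  grDevices::png(file.path(pdir, "indices.png"), width = 1200, height = 300)
  graphics::par(mfrow = c(1, 4))
  for (ep in c("is_p", "is_l", "homa_ir", "matsuda")) {
    graphics::stripchart(res$per_animal[[ep]] ~ factor(res$per_animal$group,
                                                       levels = groups),
                         vertical = TRUE, method = "jitter", pch = 16,
                         col = cols, main = ep, ylab = ep)
  }
  grDevices::dev.off()
  invisible(NULL)
}
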