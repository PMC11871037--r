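# Tissue-specific and whole-body insulin-sensitivity indices.

#' Convert insulin from ng/mL to uU/mL
#'
#' Conversion convention used for HOMA-IR and the Matsuda index; the
#' factor is configurable because ELISA standards differ.
#'
#' @param x Insulin (ng/mL).
#' @param factor uU per ng (default 23.1).
#' @return Insulin (uU/mL).
#' @export
insulin_ng_to_uU <- function(x, factor = 23.1) x * factor

#' Convert glucose from mM to mg/dL
#' @param x Glucose (mM).
#' @return Glucose (mg/dL) using 18.016 mg/dL per mM.
#' @export
glucose_mM_to_mgdl <- function(x) x * 18.016

#' Peripheral insulin sensitivity IS-P
#'
#' `IS-P = k2 / INS(0->120)`: the fractional plasma glucose clearance
#' rate normalized by the time-averaged insulin over the test, so higher
#' values mean more clearance per unit circulating insulin.
#'
#' @param k2 Plasma clearance rate constant (1/min).
#' @param ins_avg_0_120 Time-averaged insulin over 0-120 min (ng/mL).
#' @return IS-P ((1/min)/(ng/mL)).
#' @export
#' @examples
#' is_peripheral(0.02, 2)  # 0.01
is_peripheral <- function(k2, ins_avg_0_120) {
  if (any(k2 <= 0) || any(ins_avg_0_120 <= 0))
    stop("domain error: inputs must be positive")
  k2 / ins_avg_0_120
}

#' Hepatic insulin sensitivity IS-L
#'
#' `IS-L = (EGP_ref * INS_ref) / (EGP * INS)`: the product of an
#' individual's time-averaged EGP and insulin over a common window,
#' normalized by the reference-cohort means of the same quantities. An
#' individual at the cohort reference has IS-L = 1; a liver that keeps
#' producing glucose despite high insulin scores below 1.
#'
#' @param egp Individual time-averaged EGP over the window (mM/min).
#' @param ins Individual time-averaged insulin over the window (ng/mL).
#' @param egp_ref,ins_ref Reference-cohort arithmetic means of the same
#'   quantities on the same window.
#' @return Dimensionless IS-L.
#' @export
is_liver <- function(egp, ins, egp_ref, ins_ref) {
  if (any(c(egp, ins, egp_ref, ins_ref) <= 0))
    stop("domain error: inputs must be positive")
  (egp_ref * ins_ref) / (egp * ins)
}

#' HOMA-IR from fasting values
#'
#' Standard homeostasis-model insulin-resistance surrogate:
#' `(fasting glucose [mM] x fasting insulin [uU/mL]) / 22.5`.
#'
#' @param fasting_glucose Fasting glucose (mM).
#' @param fasting_insulin Fasting insulin (uU/mL).
#' @return Dimensionless HOMA-IR.
#' @export
#' @examples
#' homa_ir(22.5, 1)  # 1
homa_ir <- function(fasting_glucose, fasting_insulin) {
  if (any(fasting_glucose <= 0) || any(fasting_insulin <= 0))
    stop("domain error: inputs must be positive")
  fasting_glucose * fasting_insulin / 22.5
}

#' Matsuda whole-body insulin-sensitivity index
#'
#' Standard composite index
#' `10000 / sqrt(G0 * I0 * Gbar * Ibar)` with glucose in mg/dL, insulin
#' in uU/mL, and `Gbar`, `Ibar` trapezoidal time-averages over the test
#' (0-120 min). Glucose and insulin may be sampled on different grids.
#'
#' @param glucose_mM Glucose series (mM), t = 0 first.
#' @param insulin_uU Insulin series (uU/mL), t = 0 first.
#' @param times Glucose sampling times (min), must include 0.
#' @param insulin_times Insulin sampling times (default `times`).
#' @return Dimensionless Matsuda index.
#' @export
matsuda <- function(glucose_mM, insulin_uU, times, insulin_times = times) {
  if (!any(times == 0) || !any(insulin_times == 0))
    stop("schema error: t = 0 measurement required in both series")
  if (any(glucose_mM <= 0) || any(insulin_uU <= 0))
    stop("domain error: inputs must be positive")
  G <- glucose_mM_to_mgdl(glucose_mM)
  G0 <- G[match(0, times)]
  I0 <- insulin_uU[match(0, insulin_times)]
  Gbar <- pracma::trapz(times, G) / diff(range(times))
  Ibar <- pracma::trapz(insulin_times, insulin_uU) / diff(range(insulin_times))
  10000 / sqrt(G0 * I0 * Gbar * Ibar)
}
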