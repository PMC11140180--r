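#' Oxygen-carrying constant of haemoglobin
#'
#' 1.36 mL of oxygen (at one atmosphere) binds per gram of haemoglobin.
#'
#' @param k_O2 mL O2 per g Hb; default 1.36.
#' @return Numeric constant.
#' @export
oxygen_constants <- function(k_O2 = 1.36) {
  if (!is.finite(k_O2) || k_O2 <= 0) stop("k_O2 must be positive", call. = FALSE)
  k_O2
}

.hb_g_per_ml <- function(Hb, units) {
  switch(match.arg(units, c("g/L", "g/mL")),
         "g/L" = Hb / 1000, "g/mL" = Hb)
}

.need <- function(x, name) {
  if (is.null(x) || any(is.na(x)))
    stop("missing field '", name, "'", call. = FALSE)
  x
}

#' Fetal and uterine oxygen delivery and consumption
#'
#' The oxygen-transport quantities combining flow, saturation and
#' haemoglobin:
#' \deqn{fetal\ DO_2 = 1.36 \times Hb \times Y_{UV} \times \dot Q_{UV}}
#' \deqn{fetal\ \dot VO_2 = 1.36 \times Hb \times (Y_{UV} - Y_{DAo}) \times \dot Q_{UV}}
#' \deqn{UtA\ DO_2 = 1.36 \times Hb \times Y_{UtA} \times \dot Q_{UtA}}
#' With Hb in g/L and flow in mL/min, the result is in mL O2/min
#' (haemoglobin is converted internally to g/mL). All functions are
#' vectorised; fetal quantities take fetal Hb, the uterine quantity
#' maternal Hb.
#'
#' @param Hb Haemoglobin concentration (g/L unless `hb_units = "g/mL"`).
#' @param Y_UV,Y_DAo,Y_UtA Oxygen saturation fractions in `[0, 1]` of the
#'   umbilical vein, fetal descending aorta and uterine artery.
#' @param Q_UV,Q_UtA Umbilical-vein and total uterine-artery flow
#'   (mL/min).
#' @param k `oxygen_constants()`: mL O2 bound per g Hb.
#' @param hb_units `"g/L"` (default) or `"g/mL"`.
#' @return Oxygen delivery/consumption in mL O2/min.
#' @export
fetal_do2 <- function(Hb, Y_UV, Q_UV, k = oxygen_constants(),
                      hb_units = "g/L") {
  .need(Hb, "Hb"); .need(Y_UV, "Y_UV"); .need(Q_UV, "Q_UV")
  k * .hb_g_per_ml(Hb, hb_units) * Y_UV * Q_UV
}

#' @rdname fetal_do2
#' @details `fetal_vo2()` may be negative only when the measured venous
#'   saturation falls below the arterial one (`Y_DAo > Y_UV`); this
#'   physiologically inverted case is returned with a warning rather than
#'   an error.
#' @export
fetal_vo2 <- function(Hb, Y_UV, Y_DAo, Q_UV, k = oxygen_constants(),
                      hb_units = "g/L") {
  .need(Hb, "Hb"); .need(Y_UV, "Y_UV"); .need(Y_DAo, "Y_DAo")
  .need(Q_UV, "Q_UV")
  if (any(Y_DAo > Y_UV))
    warning("Y_DAo > Y_UV: arteriovenous difference inverted; ",
            "returning negative consumption", call. = FALSE)
  k * .hb_g_per_ml(Hb, hb_units) * (Y_UV - Y_DAo) * Q_UV
}

#' @rdname fetal_do2
#' @export
uta_do2 <- function(Hb, Y_UtA, Q_UtA, k = oxygen_constants(),
                    hb_units = "g/L") {
  .need(Hb, "Hb"); .need(Y_UtA, "Y_UtA"); .need(Q_UtA, "Q_UtA")
  k * .hb_g_per_ml(Hb, hb_units) * Y_UtA * Q_UtA
}

#' Fetal oxygen extraction fraction
#'
#' The fraction of delivered oxygen consumed by the fetus,
#' `(Y_UV - Y_DAo) / Y_UV`, identical to VO2/DO2 and independent of
#' haemoglobin and flow.
#'
#' @inheritParams fetal_do2
#' @return Dimensionless fraction (vectorised).
#' @export
oxygen_extraction_fraction <- function(Y_UV, Y_DAo) {
  .need(Y_UV, "Y_UV"); .need(Y_DAo, "Y_DAo")
  if (any(Y_UV <= 0)) stop("Y_UV must be > 0", call. = FALSE)
  (Y_UV - Y_DAo) / Y_UV
}

#' Uterine DO2 as a percentage of available maternal DO2
#'
#' Uterine-artery oxygen delivery expressed as a percentage of the total
#' oxygen leaving the maternal left ventricle,
#' `100 * UtA DO2 / (k * Hb * Y_arterial * LVCO)`. Changes from the basal
#' state are plain arithmetic differences of this percentage.
#'
#' @inheritParams fetal_do2
#' @param Y_arterial Maternal arterial oxygen saturation fraction.
#' @param LVCO Left ventricular cardiac output (mL/min), > 0.
#' @return Percentage (0-100 under physiological inputs).
#' @export
uta_do2_fraction <- function(Hb, Y_UtA, Q_UtA, Y_arterial, LVCO,
                             k = oxygen_constants(), hb_units = "g/L") {
  .need(LVCO, "LVCO"); .need(Y_arterial, "Y_arterial")
  if (any(LVCO <= 0)) stop("LVCO must be > 0", call. = FALSE)
  100 * uta_do2(Hb, Y_UtA, Q_UtA, k, hb_units) /
    (k * .hb_g_per_ml(Hb, hb_units) * Y_arterial * LVCO)
}

#' Augment a cohort table with oxygen-transport quantities
#'
#' Takes one haemodynamic record per row (columns `Hb_fetal`,
#' `Hb_maternal`, `Y_UV`, `Y_DAo`, `Y_UtA`, `Y_arterial`, `Q_UV`,
#' `Q_UtA`, `LVCO`, `maternal_weight`) and appends `fetal_DO2`,
#' `fetal_VO2`, `OEF`, `UtA_DO2`, `UtA_DO2_pct_available`,
#' `Q_UtA_pct_LVCO` and `Q_UtA_per_kg` columns.
#'
#' @param records A data.frame of haemodynamic records.
#' @param k `oxygen_constants()`.
#' @return The input data.frame with derived columns appended.
#' @export
oxygen_transport_table <- function(records, k = oxygen_constants()) {
  stopifnot(is.data.frame(records))
  records$fetal_DO2 <- fetal_do2(records$Hb_fetal, records$Y_UV,
                                 records$Q_UV, k)
  records$fetal_VO2 <- fetal_vo2(records$Hb_fetal, records$Y_UV,
                                 records$Y_DAo, records$Q_UV, k)
  records$OEF <- oxygen_extraction_fraction(records$Y_UV, records$Y_DAo)
  records$UtA_DO2 <- uta_do2(records$Hb_maternal, records$Y_UtA,
                             records$Q_UtA, k)
  records$UtA_DO2_pct_available <- uta_do2_fraction(
    records$Hb_maternal, records$Y_UtA, records$Q_UtA,
    records$Y_arterial, records$LVCO, k)
  records$Q_UtA_pct_LVCO <- normalize_flow(records$Q_UtA,
                                           lvco = records$LVCO, to = "lvco")
  records$Q_UtA_per_kg <- normalize_flow(records$Q_UtA,
                                         weight = records$maternal_weight,
                                         to = "weight")
  records
}
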