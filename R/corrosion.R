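# Corrosion and scaling potential indices: the calcium-carbonate
# saturation family (LSI, RSI, PSI, AI via the saturation pH and the
# Puckorius equilibrium pH) and the anion-ratio family (Revelle index,
# chloride-sulphate mass ratio, Larson-Skold index).

.check_pos <- function(x, field) {
  if (any(is.na(x) | x <= 0))
    stop("non-positive value in '", field, "': logarithm undefined")
  x
}

#' Calcium-carbonate saturation pH
#'
#' pHs = 9.3 + A + B - (C + D) with
#' A = (log10 TDS - 1)/10, B = -13.12 log10(T Kelvin) + 34.55,
#' C = log10(Ca hardness as CaCO3) - 0.4, D = log10(alkalinity as
#' CaCO3). Calcium enters as calcium hardness expressed as CaCO3, the
#' standard Langelier usage.
#'
#' @param tds total dissolved solids, mg/L.
#' @param temperature degC.
#' @param ca_hardness calcium hardness, mg/L as CaCO3.
#' @param alkalinity total alkalinity, mg/L as CaCO3.
#' @return pHs in pH units (vectorised).
#' @export
saturation_ph <- function(tds, temperature, ca_hardness, alkalinity) {
  a <- (log10(.check_pos(tds, "tds")) - 1) / 10
  b <- -13.12 * log10(.check_pos(temperature + 273.15, "temperature")) + 34.55
  cc <- log10(.check_pos(ca_hardness, "ca_hardness")) - 0.4
  d <- log10(.check_pos(alkalinity, "alkalinity"))
  9.3 + a + b - (cc + d)
}

#' Puckorius equilibrium pH
#'
#' pHeq = 1.465 log10(alkalinity as CaCO3) + 4.54.
#'
#' @inheritParams saturation_ph
#' @return pHeq in pH units.
#' @export
equilibrium_ph <- function(alkalinity) {
  1.465 * log10(.check_pos(alkalinity, "alkalinity")) + 4.54
}

#' Carbonate-saturation corrosion indices
#'
#' LSI = pH - pHs; RSI = 2 pHs - pH; PSI = 2 pHs - pHeq;
#' AI = pH + log10(alkalinity x Ca hardness), all hardness/alkalinity as
#' CaCO3. The identities RSI = 2 pHs - pH and RSI + 2 LSI = pH hold
#' exactly.
#'
#' @param ph measured pH.
#' @inheritParams saturation_ph
#' @return data.frame with `phs`, `pheq`, `lsi`, `rsi`, `psi`, `ai`.
#' @export
carbonate_indices <- function(ph, tds, temperature, ca_hardness,
                              alkalinity) {
  phs <- saturation_ph(tds, temperature, ca_hardness, alkalinity)
  pheq <- equilibrium_ph(alkalinity)
  data.frame(phs = phs, pheq = pheq, lsi = ph - phs, rsi = 2 * phs - ph,
             psi = 2 * phs - pheq,
             ai = ph + log10(.check_pos(alkalinity * ca_hardness,
                                        "alkalinity * ca_hardness")))
}

#' Anion-ratio corrosion indices
#'
#' Revelle index RI = Cl/HCO3 (meq/L), chloride-sulphate mass ratio
#' CSMR = Cl/SO4 (mg/L mass ratio, per its name), Larson-Skold index
#' LS = (Cl + SO4)/HCO3 (meq/L, the Larson-Skold convention). Unit
#' conventions can be overridden.
#'
#' @param cl,so4,hco3 concentrations in mg/L.
#' @param ri_units,ls_units `"meq"` (default) or `"mass"`.
#' @param csmr_units `"mass"` (default) or `"meq"`.
#' @return data.frame with `ri`, `csmr`, `ls`; zero denominators give
#'   NA with a warning-free `undefined` flag column.
#' @export
ratio_indices <- function(cl, so4, hco3, ri_units = "meq",
                          csmr_units = "mass", ls_units = "meq") {
  ew <- equivalent_weights()
  pick <- function(x, ion, units)
    if (units == "meq") x / ew[[ion]] else x
  div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  ri <- div(pick(cl, "Cl", ri_units), pick(hco3, "HCO3", ri_units))
  csmr <- div(pick(cl, "Cl", csmr_units), pick(so4, "SO4", csmr_units))
  ls <- div(pick(cl, "Cl", ls_units) + pick(so4, "SO4", ls_units),
            pick(hco3, "HCO3", ls_units))
  data.frame(ri = ri, csmr = csmr, ls = ls,
             undefined = is.na(ri) | is.na(csmr) | is.na(ls))
}

.classify_one <- function(report, thresholds) {
  th <- thresholds
  list(
    lsi = ifelse(report$lsi < th$lsi$balanced_at, "corrosive",
                 ifelse(report$lsi > th$lsi$balanced_at, "scale-forming",
                        "balanced")),
    rsi = ifelse(report$rsi > th$rsi$corrosive_above, "corrosive",
                 "scale-forming"),
    ai = ifelse(report$ai < th$ai$highly_aggressive_below,
                "highly aggressive",
                ifelse(report$ai > th$ai$non_aggressive_above,
                       "non-aggressive", "moderately aggressive")),
    psi = ifelse(report$psi > th$psi$corrosive_above, "corrosive",
                 "scaling"),
    ls = ifelse(report$ls < th$ls$low_below, "low corrosion risk",
                ifelse(report$ls > th$ls$high_above, "high corrosion risk",
                       "moderate corrosion risk")),
    csmr = ifelse(report$csmr > th$csmr$elevated_above,
                  "elevated galvanic-corrosion concern", "low concern"))
}

#' Full corrosion/scaling report for a sample table
#'
#' Derives the inputs (TDS, calcium hardness and alkalinity as CaCO3)
#' from the major ions where not measured, computes all seven indices
#' and attaches class labels: LSI <0 corrosive / >0 scale-forming / =0
#' balanced; RSI > 6.8 corrosive; AI < 10 highly aggressive, 10-12
#' moderately, > 12 non-aggressive; PSI > 6 corrosive, < 6 scaling;
#' LS < 0.8 low, 0.8-1.2 moderate, > 1.2 high; CSMR > 0.5 elevated
#' galvanic-corrosion concern. RI is reported without a class (buffering
#' descriptor).
#'
#' @param samples a sample data.frame with major ions, `ph` and
#'   `temperature`.
#' @param thresholds classification cutoffs; defaults to the shipped
#'   table.
#' @return data.frame of class `corrosion_report`: site/campaign, the
#'   seven indices, `phs`, `pheq` and one `<index>_class` column per
#'   classified index.
#' @export
corrosion_report <- function(samples,
                             thresholds = load_corrosion_thresholds()) {
  s <- derive_bulk_properties(samples)
  carb <- carbonate_indices(s$ph, s$tds, s$temperature,
                            s$ca_hardness_caco3, s$alkalinity_caco3)
  rat <- ratio_indices(s$Cl, s$SO4, s$HCO3)
  report <- cbind(s[c("site_id", "campaign")], carb,
                  rat[c("ri", "csmr", "ls")])
  cls <- .classify_one(report, thresholds)
  for (nm in names(cls)) report[[paste0(nm, "_class")]] <- cls[[nm]]
  class(report) <- c("corrosion_report", "data.frame")
  report
}

#' Classify an existing set of corrosion indices
#'
#' Applies the threshold table to pre-computed index values; useful for
#' classifying published index values without the underlying chemistry.
#'
#' @param lsi,rsi,ai,psi,ls,csmr index values (any may be NA).
#' @param thresholds classification cutoffs.
#' @return list of class labels (NA indices give NA labels).
#' @export
classify_corrosion <- function(lsi = NA, rsi = NA, ai = NA, psi = NA,
                               ls = NA, csmr = NA,
                               thresholds = load_corrosion_thresholds()) {
  .classify_one(data.frame(lsi = lsi, rsi = rsi, ai = ai, psi = psi,
                           ls = ls, csmr = csmr), thresholds)
}
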