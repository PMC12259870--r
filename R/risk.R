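# Deterministic USEPA-style health risk: chronic daily intake via
# ingestion and dermal contact, hazard quotients/indices and
# (cumulative) carcinogenic risk. All quantities are linear in
# concentration; the same functions serve the Monte-Carlo engine, which
# simply supplies vectorised parameter draws.

.at_for <- function(profile, horizon) {
  switch(horizon,
         carcinogenic = profile$at_carcinogenic,
         noncarcinogenic = profile$at_noncarcinogenic,
         stop("horizon must be 'carcinogenic' or 'noncarcinogenic'"))
}

#' Chronic daily intake by ingestion
#'
#' CDI_oral = (EF x IR x ED) / (BW x AT) x C, in mg/kg/day, with the
#' averaging time chosen per risk horizon (carcinogenic: lifetime AT;
#' non-carcinogenic: ED x 365 under the default rule).
#'
#' All exposure arguments may be vectors (recycled), which is how the
#' Monte-Carlo engine reuses this single code path.
#'
#' @param c_conc concentration in water, mg/L.
#' @param profile an [exposure_profile()].
#' @param horizon `"noncarcinogenic"` or `"carcinogenic"`.
#' @param ir,ef,ed,bw,at optional overrides of the profile fields
#'   (vectorisable).
#' @return CDI in mg/kg/day.
#' @export
cdi_oral <- function(c_conc, profile,
                     horizon = c("noncarcinogenic", "carcinogenic"),
                     ir = profile$ir, ef = profile$ef, ed = profile$ed,
                     bw = profile$bw, at = NULL) {
  horizon <- match.arg(horizon)
  stopifnot(all(c_conc >= 0))
  if (is.null(at)) at <- .at_for(profile, horizon)
  (ef * ir * ed) / (bw * at) * c_conc
}

#' Chronic daily intake by dermal contact
#'
#' CDI_dermal = (EF x ET x ED x Kp x SA x CF) / (BW x AT) x C, in
#' mg/kg/day. The dermal absorption fraction does not enter the intake;
#' it acts through the dermal reference dose (RfD_dermal = RfD_oral x
#' ABS).
#'
#' @inheritParams cdi_oral
#' @param kp dermal permeability coefficient, cm/h.
#' @param et,sa,cf optional overrides of the profile fields
#'   (vectorisable).
#' @return CDI in mg/kg/day.
#' @export
cdi_dermal <- function(c_conc, kp, profile,
                       horizon = c("noncarcinogenic", "carcinogenic"),
                       et = profile$et, sa = profile$sa, cf = profile$cf,
                       ef = profile$ef, ed = profile$ed, bw = profile$bw,
                       at = NULL) {
  horizon <- match.arg(horizon)
  stopifnot(all(c_conc >= 0), all(kp >= 0))
  if (is.null(at)) at <- .at_for(profile, horizon)
  (ef * et * ed * kp * sa * cf) / (bw * at) * c_conc
}

#' Hazard quotient and hazard index
#'
#' HQ = CDI / RfD; HI is the sum of HQs over an aggregation set (the
#' usual reporting aggregates per pathway over metals; per metal over
#' pathways is the HQ_oral + HQ_dermal form). The HI of an empty set
#' is 0.
#'
#' @param cdi chronic daily intake, mg/kg/day.
#' @param rfd reference dose, mg/kg/day (must be positive).
#' @return `hazard_quotient`: dimensionless HQ; `hazard_index`: sum of
#'   the supplied HQs.
#' @export
hazard_quotient <- function(cdi, rfd) {
  if (any(rfd <= 0)) stop("reference dose must be positive")
  cdi / rfd
}

#' @rdname hazard_quotient
#' @param hqs numeric vector of hazard quotients.
#' @export
hazard_index <- function(hqs) sum(hqs)

#' Carcinogenic risk and cumulative carcinogenic risk
#'
#' CR = CDI x CSF with the lifetime (carcinogenic) averaging time;
#' cumulative risk sums CRs over carcinogens within one pathway and
#' receptor. The conventional tolerable band is 1e-6 to 1e-4.
#'
#' @param cdi_carcinogenic chronic daily intake at the carcinogenic
#'   averaging time, mg/kg/day.
#' @param csf cancer slope factor, (mg/kg/day)^-1; NA means the metal is
#'   not a carcinogen for the pathway and is an error.
#' @return `cancer_risk`: dimensionless lifetime excess risk;
#'   `cumulative_cancer_risk`: sum of the supplied risks.
#' @export
cancer_risk <- function(cdi_carcinogenic, csf) {
  if (anyNA(csf))
    stop("no cancer slope factor: metal is not treated as a carcinogen ",
         "for this pathway")
  cdi_carcinogenic * csf
}

#' @rdname cancer_risk
#' @param crs numeric vector of per-carcinogen risks.
#' @export
cumulative_cancer_risk <- function(crs) sum(crs)

#' Acceptable carcinogenic-risk band
#'
#' @return The conventional `c(1e-6, 1e-4)` comparator band.
#' @export
cr_acceptable_band <- function() c(lower = 1e-6, upper = 1e-4)

#' Full deterministic risk assessment for one concentration set
#'
#' Computes, for one receptor, the per-metal CDIs and hazard quotients
#' for both pathways, the per-pathway hazard indices, per-carcinogen
#' cancer risks and the per-pathway cumulative cancer risk.
#'
#' @param concentrations named numeric vector of metal concentrations
#'   (mg/L); names must appear in the toxicity table.
#' @param profile an [exposure_profile()].
#' @param toxicity a toxicity table from [load_toxicity()].
#' @param carcinogens metals entering the carcinogenic-risk stage.
#'   Defaults to chromium and lead, the metals consistently quantified
#'   well enough for cancer-risk work; cadmium's slope factors are
#'   carried in the toxicity table but excluded here by default.
#' @return Object of class `risk_result`: `per_metal` data.frame (cdi,
#'   hq by pathway), `hi` (named by pathway), `cancer` data.frame (cr by
#'   metal x pathway), `cumulative_cr` (named by pathway), `receptor`.
#' @export
site_risk <- function(concentrations, profile, toxicity = load_toxicity(),
                      carcinogens = c("Cr", "Pb")) {
  metals <- names(concentrations)
  missing <- setdiff(metals, rownames(toxicity))
  if (length(missing)) stop("no toxicity entry for: ",
                            paste(missing, collapse = ", "))
  tox <- toxicity[metals, ]
  c_conc <- as.numeric(concentrations)
  cdi_o <- cdi_oral(c_conc, profile, "noncarcinogenic")
  cdi_d <- cdi_dermal(c_conc, tox$kp, profile, "noncarcinogenic")
  hq_o <- hazard_quotient(cdi_o, tox$rfd_oral)
  hq_d <- hazard_quotient(cdi_d, tox$rfd_dermal)
  per_metal <- data.frame(metal = metals, concentration = c_conc,
                          cdi_oral = cdi_o, cdi_dermal = cdi_d,
                          hq_oral = hq_o, hq_dermal = hq_d,
                          hi_metal = hq_o + hq_d, stringsAsFactors = FALSE)
  hi <- c(oral = hazard_index(hq_o), dermal = hazard_index(hq_d))

  carc <- intersect(metals, carcinogens)
  carc <- carc[!is.na(toxicity[carc, "csf_oral"]) |
                 !is.na(toxicity[carc, "csf_dermal"])]
  cancer <- NULL
  cumulative <- c(oral = NA_real_, dermal = NA_real_)
  if (length(carc)) {
    tox_c <- toxicity[carc, ]
    cc <- c_conc[match(carc, metals)]
    cr_o <- ifelse(is.na(tox_c$csf_oral), NA_real_,
                   cdi_oral(cc, profile, "carcinogenic") * tox_c$csf_oral)
    cr_d <- ifelse(is.na(tox_c$csf_dermal), NA_real_,
                   cdi_dermal(cc, tox_c$kp, profile, "carcinogenic") *
                     tox_c$csf_dermal)
    cancer <- data.frame(metal = carc, cr_oral = cr_o, cr_dermal = cr_d,
                         stringsAsFactors = FALSE)
    cumulative <- c(oral = cumulative_cancer_risk(cr_o[!is.na(cr_o)]),
                    dermal = cumulative_cancer_risk(cr_d[!is.na(cr_d)]))
  }
  structure(list(per_metal = per_metal, hi = hi, cancer = cancer,
                 cumulative_cr = cumulative, receptor = profile$receptor),
            class = "risk_result")
}

#' @export
print.risk_result <- function(x, ...) {
  cat(sprintf("Health risk (%s): HI oral %.3g, HI dermal %.3g\n",
              x$receptor, x$hi[["oral"]], x$hi[["dermal"]]))
  if (!is.null(x$cancer))
    cat(sprintf("  cumulative CR: oral %.3g, dermal %.3g (band 1e-6..1e-4)\n",
                x$cumulative_cr[["oral"]], x$cumulative_cr[["dermal"]]))
  invisible(x)
}

#' Worked-example metal concentrations for the most contaminated spring
#'
#' A ten-metal concentration set (mg/L) used throughout the worked
#' examples: Hg, Cr, Pb and Ni are reported monitoring extrema for the
#' site; the remaining six are reconstructed from the site's published
#' per-metal hazard quotients and lie inside the reported seasonal
#' ranges. A reconstructed, not a measured, dataset.
#'
#' @return Named numeric vector of concentrations in mg/L.
#' @export
reference_site_metals <- function() {
  c(Cd = 0.00025, Cr = 0.0015, Cu = 0.002, Fe = 0.029, Hg = 0.00784,
    Mn = 0.00852, Ni = 0.002, Pb = 0.002, Sr = 0.095, Zn = 0.009)
}
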