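# Hydrochemical facies classification: Piper and Chadha coordinates,
# Gibbs ratios, Na-normalised ionic ratios and chloro-alkaline indices.
# All coordinate systems work on milliequivalent percentages except the
# Gibbs ratios, which follow the original mass-concentration convention.

#' Piper trilinear coordinates and facies label
#'
#' Cation percentages (Ca, Mg, Na+K as meq% of total cations) and anion
#' percentages (HCO3, SO4, Cl as meq% of total anions), each triple
#' summing to 100. The facies label follows the diamond-quadrant
#' dominance rule: alkaline earths (Ca+Mg) vs alkalis (Na+K) and weak
#' acids (HCO3) vs strong acids (Cl+SO4), yielding one of
#' `"Ca-Mg-HCO3"`, `"Ca-Mg-Cl/SO4"`, `"Na-Cl"` or `"Na-HCO3"`.
#' Coordinates are invariant to uniform scaling of all ion
#' concentrations.
#'
#' @param samples a sample data.frame with the eight major-ion columns.
#' @return data.frame with the six percentage columns and `facies`.
#' @export
piper_coordinates <- function(samples) {
  eq <- to_equivalents(samples)
  if (any(eq$total_cations == 0) || any(eq$total_anions == 0))
    stop("Piper coordinates undefined: zero total cations or anions")
  cat_pct <- 100 * cbind(Ca = eq$Ca, Mg = eq$Mg,
                         NaK = eq$Na + eq$K) / eq$total_cations
  an_pct <- 100 * cbind(HCO3 = eq$HCO3, SO4 = eq$SO4,
                        Cl = eq$Cl) / eq$total_anions
  alkaline_earth <- cat_pct[, "Ca"] + cat_pct[, "Mg"]
  weak_acid <- an_pct[, "HCO3"]
  facies <- ifelse(alkaline_earth >= 50,
                   ifelse(weak_acid >= 50, "Ca-Mg-HCO3", "Ca-Mg-Cl/SO4"),
                   ifelse(weak_acid >= 50, "Na-HCO3", "Na-Cl"))
  data.frame(Ca_pct = cat_pct[, "Ca"], Mg_pct = cat_pct[, "Mg"],
             NaK_pct = cat_pct[, "NaK"], HCO3_pct = an_pct[, "HCO3"],
             SO4_pct = an_pct[, "SO4"], Cl_pct = an_pct[, "Cl"],
             facies = facies, stringsAsFactors = FALSE)
}

#' Chadha coordinates and hydrochemical field
#'
#' x = (Ca+Mg) - (Na+K) as meq% of total cations;
#' y = HCO3 - (Cl+SO4) as meq% of total anions. Quadrants:
#' (+,+) recharge `"Ca-Mg-HCO3"`, (+,-) reverse ion exchange
#' `"Ca-Mg-Cl/SO4"`, (-,-) seawater-type `"Na-Cl"`, (-,+) base exchange
#' `"Na-HCO3"`. x equals Piper (%Ca + %Mg) - %NaK exactly.
#'
#' @inheritParams piper_coordinates
#' @return data.frame with columns `x`, `y`, `field`.
#' @export
chadha_coordinates <- function(samples) {
  p <- piper_coordinates(samples)
  x <- p$Ca_pct + p$Mg_pct - p$NaK_pct
  y <- p$HCO3_pct - (p$Cl_pct + p$SO4_pct)
  field <- ifelse(x >= 0,
                  ifelse(y >= 0, "recharge Ca-Mg-HCO3",
                         "reverse-exchange Ca-Mg-Cl/SO4"),
                  ifelse(y >= 0, "base-exchange Na-HCO3",
                         "seawater-type Na-Cl"))
  data.frame(x = x, y = y, field = field, stringsAsFactors = FALSE)
}

# Rectangular approximation of the Gibbs boomerang boundaries: low-TDS,
# high-ratio waters are precipitation-dominated; high-TDS, high-ratio
# waters are evaporation-dominated; everything else is rock weathering.
.GIBBS_TDS_PRECIP_MAX <- 100
.GIBBS_TDS_EVAP_MIN <- 1000
.GIBBS_RATIO_MIN <- 0.5

#' Gibbs ratios and controlling-mechanism label
#'
#' Anion ratio Cl/(Cl+HCO3) and cation ratio Na/(Na+Ca), computed on mass
#' concentrations (the original Gibbs convention; set `units = "meq"` for
#' an equivalent-based variant), plotted against TDS. The mechanism label
#' uses documented rectangular boundary boxes: `"precipitation"` (TDS
#' <= 100 mg/L and ratio >= 0.5), `"evaporation"` (TDS >= 1000 mg/L and
#' ratio >= 0.5), otherwise `"rock-weathering"`.
#'
#' @inheritParams piper_coordinates
#' @param units `"mass"` (default) or `"meq"`.
#' @return data.frame with `anion_ratio`, `cation_ratio`, `tds`,
#'   `mechanism`. Zero denominators yield NA ratios and an
#'   `"undefined"` mechanism.
#' @export
gibbs_ratios <- function(samples, units = c("mass", "meq")) {
  units <- match.arg(units)
  s <- derive_bulk_properties(samples)
  if (units == "meq") {
    ew <- equivalent_weights()
    cl <- s$Cl / ew[["Cl"]]; hco3 <- s$HCO3 / ew[["HCO3"]]
    na <- s$Na / ew[["Na"]]; ca <- s$Ca / ew[["Ca"]]
  } else {
    cl <- s$Cl; hco3 <- s$HCO3; na <- s$Na; ca <- s$Ca
  }
  anion_ratio <- ifelse(cl + hco3 > 0, cl / (cl + hco3), NA_real_)
  cation_ratio <- ifelse(na + ca > 0, na / (na + ca), NA_real_)
  ratio <- pmax(anion_ratio, cation_ratio)
  mechanism <- ifelse(is.na(ratio), "undefined",
    ifelse(ratio >= .GIBBS_RATIO_MIN & s$tds <= .GIBBS_TDS_PRECIP_MAX,
           "precipitation",
    ifelse(ratio >= .GIBBS_RATIO_MIN & s$tds >= .GIBBS_TDS_EVAP_MIN,
           "evaporation", "rock-weathering")))
  data.frame(anion_ratio = anion_ratio, cation_ratio = cation_ratio,
             tds = s$tds, mechanism = mechanism, stringsAsFactors = FALSE)
}

#' Ionic ratios used in end-member and process diagrams
#'
#' Na-normalised molar ratios (Ca/Na, Mg/Na, HCO3/Na, NO3/Na, SO4/Na,
#' Cl/Na — the convention of silicate/carbonate end-member diagrams) and
#' milliequivalent pairs for the bivariate plots (Ca+Mg vs SO4+HCO3,
#' Ca+Mg vs HCO3, Ca vs SO4, Na vs Cl), plus the (Ca+Mg)/HCO3 equivalent
#' ratio whose conventional interpretation threshold is 0.5 (carbonate
#' weathering near 0.5; silicate weathering/reverse exchange above it).
#'
#' @inheritParams piper_coordinates
#' @return data.frame of ratios and meq pairs. Ratios with a zero
#'   denominator are NA with the `na_undefined` / `hco3_undefined`
#'   flags set.
#' @export
ionic_ratios <- function(samples) {
  .require_ions(samples, major_ions())
  mm <- molar_masses()
  ew <- equivalent_weights()
  mol <- function(ion) samples[[ion]] / mm[[ion]]
  meq <- function(ion) samples[[ion]] / ew[[ion]]
  na_mol <- mol("Na")
  rat <- function(x) ifelse(na_mol > 0, x / na_mol, NA_real_)
  hco3_meq <- meq("HCO3")
  data.frame(
    ca_na = rat(mol("Ca")), mg_na = rat(mol("Mg")),
    hco3_na = rat(mol("HCO3")), no3_na = rat(mol("NO3")),
    so4_na = rat(mol("SO4")), cl_na = rat(mol("Cl")),
    ca_mg_meq = meq("Ca") + meq("Mg"),
    so4_hco3_meq = meq("SO4") + hco3_meq,
    hco3_meq = hco3_meq, ca_meq = meq("Ca"), so4_meq = meq("SO4"),
    na_meq = meq("Na"), cl_meq = meq("Cl"),
    ca_mg_over_hco3 = ifelse(hco3_meq > 0,
                             (meq("Ca") + meq("Mg")) / hco3_meq, NA_real_),
    na_undefined = !(na_mol > 0),
    hco3_undefined = !(hco3_meq > 0))
}

#' Chloro-alkaline indices
#'
#' Schoeller's indices, in meq/L:
#' CAI-I = (Cl - (Na+K)) / Cl and
#' CAI-II = (Cl - (Na+K)) / (SO4 + HCO3 + CO3 + NO3), with CO3 taken as 0.
#' Positive values indicate reverse ion exchange (aquifer Ca/Mg replacing
#' water Na/K); negative values direct exchange; zero none. When Cl is
#' zero CAI-I is undefined and the label falls back to CAI-II alone.
#' Sign disagreement between the two indices is reported as
#' `"disagreement"`.
#'
#' @inheritParams piper_coordinates
#' @return data.frame with `cai1`, `cai2`, `exchange`.
#' @export
chloro_alkaline <- function(samples) {
  eq <- to_equivalents(samples)
  num <- eq$Cl - (eq$Na + eq$K)
  cai1 <- ifelse(eq$Cl > 0, num / eq$Cl, NA_real_)
  denom2 <- eq$SO4 + eq$HCO3 + eq$NO3
  cai2 <- ifelse(denom2 > 0, num / denom2, NA_real_)
  lab <- function(v) ifelse(v > 0, "reverse", ifelse(v < 0, "direct", "none"))
  exchange <- ifelse(is.na(cai1), lab(cai2),
                     ifelse(is.na(cai2), lab(cai1),
                            ifelse(lab(cai1) == lab(cai2), lab(cai1),
                                   "disagreement")))
  data.frame(cai1 = cai1, cai2 = cai2, exchange = exchange,
             stringsAsFactors = FALSE)
}
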