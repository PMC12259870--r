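# Core water-chemistry data model: unit conversions, derived bulk
# properties, charge-balance QC and delimited-text I/O.
#
# Samples are plain data.frames, one row per site x campaign, with fixed
# units: concentrations mg/L, temperature degC, EC uS/cm. Concentration
# columns use chemical symbols (Ca, Mg, Na, K, HCO3, Cl, SO4, NO3 and the
# trace metals); everything else is lower snake_case.

#' Major-ion and trace-metal parameter names
#'
#' Canonical column names for the eight major ions and eleven trace metals
#' handled by the package, plus the cation/anion split used for
#' charge-balance accounting.
#'
#' @return A character vector of parameter names.
#' @export
major_ions <- function() c("Ca", "Mg", "Na", "K", "HCO3", "Cl", "SO4", "NO3")

#' @rdname major_ions
#' @export
trace_metals <- function() {
  c("Fe", "Al", "Mn", "Ni", "Cu", "Sr", "Cd", "Cr", "Pb", "Hg", "Zn")
}

#' @rdname major_ions
#' @export
major_cations <- function() c("Ca", "Mg", "Na", "K")

#' @rdname major_ions
#' @export
major_anions <- function() c("HCO3", "Cl", "SO4", "NO3")

#' Equivalent weights of the major ions
#'
#' Fixed two-decimal constants (molar mass / charge) used for all
#' mg/L to meq/L conversions. Exposed so alternative constants can be
#' injected where a different rounding convention is required.
#'
#' @return Named numeric vector, g/eq.
#' @export
equivalent_weights <- function() {
  c(Ca = 20.04, Mg = 12.15, Na = 22.99, K = 39.10,
    HCO3 = 61.02, Cl = 35.45, SO4 = 48.03, NO3 = 62.00)
}

#' Molar masses used for molar (mmol-based) ionic ratios
#'
#' @return Named numeric vector, g/mol.
#' @export
molar_masses <- function() {
  c(Ca = 40.08, Mg = 24.31, Na = 22.99, K = 39.10,
    HCO3 = 61.02, Cl = 35.45, SO4 = 96.06, NO3 = 62.00)
}

# equivalent weight of CaCO3 (100.09/2) used for hardness/alkalinity
.EW_CACO3 <- 50.04

#' Assemble a water-sample table
#'
#' Builds and validates the canonical sample data.frame from per-parameter
#' vectors. Any subset of the concentration columns may be supplied; most
#' downstream operations state which columns they require.
#'
#' @param site_id character, spring identifier.
#' @param campaign character, season label or ISO date.
#' @param temperature degC, in \[-5, 60\].
#' @param ph pH units, in \[0, 14\].
#' @param ec electrical conductivity, uS/cm.
#' @param ... named concentration vectors in mg/L (e.g. `Ca = 40`), plus
#'   optionally `tds`, `alkalinity_caco3`, `dissolved_oxygen`.
#' @param bdl optional logical data.frame (same row count) flagging values
#'   stored at their detection limit.
#' @return A validated `data.frame` with a `bdl` attribute.
#' @export
water_samples <- function(site_id, campaign, temperature = NA_real_,
                          ph = NA_real_, ec = NA_real_, ..., bdl = NULL) {
  df <- data.frame(site_id = as.character(site_id),
                   campaign = as.character(campaign),
                   temperature = as.numeric(temperature),
                   ph = as.numeric(ph), ec = as.numeric(ec),
                   stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- as.numeric(extra[[nm]])
  validate_samples(df)
  attr(df, "bdl") <- .normalise_bdl(df, bdl)
  df
}

.conc_cols <- function(samples) {
  intersect(c(major_ions(), trace_metals(), "tds", "alkalinity_caco3",
              "dissolved_oxygen", "ca_hardness_caco3", "total_hardness_caco3"),
            names(samples))
}

.normalise_bdl <- function(samples, bdl) {
  cols <- .conc_cols(samples)
  out <- as.data.frame(matrix(FALSE, nrow(samples), length(cols),
                              dimnames = list(NULL, cols)))
  if (!is.null(bdl) && nrow(as.data.frame(bdl)) == nrow(samples)) {
    keep <- intersect(names(bdl), cols)
    out[keep] <- lapply(bdl[keep], function(x) as.logical(x) %in% TRUE)
  }
  out
}

#' Below-detection flags of a sample table
#'
#' @param samples a sample data.frame.
#' @return Logical data.frame aligned with the concentration columns.
#' @export
bdl_flags <- function(samples) {
  b <- attr(samples, "bdl")
  if (is.null(b)) b <- .normalise_bdl(samples, NULL)
  b
}

#' Validate a sample table
#'
#' Checks the physical invariants: non-negative concentrations, pH in
#' \[0, 14\], temperature in \[-5, 60\] degC.
#'
#' @param samples a sample data.frame.
#' @return The input, invisibly, or an error describing the violation.
#' @export
validate_samples <- function(samples) {
  stopifnot(is.data.frame(samples))
  if (!all(c("site_id", "campaign") %in% names(samples)))
    stop("samples must have 'site_id' and 'campaign' columns")
  for (col in .conc_cols(samples)) {
    bad <- which(!is.na(samples[[col]]) & samples[[col]] < 0)
    if (length(bad))
      stop(sprintf("negative concentration in column '%s' (row %d)",
                   col, bad[1]))
  }
  if ("ph" %in% names(samples)) {
    bad <- which(!is.na(samples$ph) & (samples$ph < 0 | samples$ph > 14))
    if (length(bad)) stop(sprintf("pH out of [0, 14] (row %d)", bad[1]))
  }
  if ("temperature" %in% names(samples)) {
    bad <- which(!is.na(samples$temperature) &
                   (samples$temperature < -5 | samples$temperature > 60))
    if (length(bad))
      stop(sprintf("temperature out of [-5, 60] degC (row %d)", bad[1]))
  }
  invisible(samples)
}

.require_ions <- function(samples, ions) {
  missing <- setdiff(ions, names(samples))
  if (length(missing))
    stop("missing required ion column(s): ", paste(missing, collapse = ", "))
  for (ion in ions) {
    if (anyNA(samples[[ion]]))
      stop(sprintf("missing (NA) values in required ion '%s'", ion))
  }
  invisible(TRUE)
}

#' Convert major-ion concentrations to milliequivalents
#'
#' meq/L = (mg/L) / equivalent weight, with the constants of
#' [equivalent_weights()]. Conversion is linear in concentration.
#'
#' @param samples a sample data.frame with all eight major-ion columns.
#' @param weights named equivalent-weight vector; override to inject
#'   alternative constants.
#' @return A data.frame with one meq/L column per ion plus
#'   `total_cations` and `total_anions`.
#' @export
to_equivalents <- function(samples, weights = equivalent_weights()) {
  .require_ions(samples, major_ions())
  eq <- as.data.frame(
    lapply(major_ions(), function(i) samples[[i]] / weights[[i]]))
  names(eq) <- major_ions()
  eq$total_cations <- rowSums(eq[major_cations()])
  eq$total_anions <- rowSums(eq[major_anions()])
  eq
}

#' Charge-balance error (percent)
#'
#' CBE = 100 (sum cations - sum anions) / (sum cations + sum anions), in
#' meq/L, sign preserved. Analyses with |CBE| <= 5 percent are
#' conventionally accepted.
#'
#' @param samples a sample data.frame with all eight major-ion columns.
#' @return Numeric vector of CBE percentages, one per row.
#' @export
charge_balance_error <- function(samples) {
  eq <- to_equivalents(samples)
  tot <- eq$total_cations + eq$total_anions
  if (any(tot == 0))
    stop("charge balance undefined: total cations and anions are both zero")
  100 * (eq$total_cations - eq$total_anions) / tot
}

#' Derive bulk properties from the major ions
#'
#' Fills, where absent: `tds` (sum of major ions, mg/L; an EC-based
#' estimate `0.64 * EC` is available via `tds_from_ec`), `alkalinity_caco3`
#' (HCO3 x 50.04/61.02, mg/L as CaCO3, assuming no carbonate at pH < 8.3),
#' `ca_hardness_caco3` (Ca x 100.09/40.08) and `total_hardness_caco3`
#' ((Ca/20.04 + Mg/12.15) x 50.04). Idempotent: already-present values are
#' never overwritten.
#'
#' @param samples a sample data.frame with the major-ion columns.
#' @param tds_from_ec if TRUE and `ec` is present, estimate missing TDS as
#'   0.64 x EC instead of the ion sum.
#' @return The enriched sample data.frame.
#' @export
derive_bulk_properties <- function(samples, tds_from_ec = FALSE) {
  .require_ions(samples, major_ions())
  bdl <- bdl_flags(samples)
  ew <- equivalent_weights()
  ion_sum <- rowSums(samples[major_ions()])
  if (is.null(samples$tds)) samples$tds <- NA_real_
  fill <- is.na(samples$tds)
  samples$tds[fill] <- if (tds_from_ec && "ec" %in% names(samples))
    0.64 * samples$ec[fill] else ion_sum[fill]
  if (is.null(samples$alkalinity_caco3)) samples$alkalinity_caco3 <- NA_real_
  fill <- is.na(samples$alkalinity_caco3)
  samples$alkalinity_caco3[fill] <- samples$HCO3[fill] * .EW_CACO3 / ew[["HCO3"]]
  samples$ca_hardness_caco3 <- samples$Ca * 100.09 / 40.08
  samples$total_hardness_caco3 <-
    (samples$Ca / ew[["Ca"]] + samples$Mg / ew[["Mg"]]) * .EW_CACO3
  attr(samples, "bdl") <- .normalise_bdl(samples, bdl)
  samples
}

#' Read and write sample tables
#'
#' Delimited-text I/O with a configurable column map. Below-detection
#' entries are written as `<value` tokens and parsed back into the `bdl`
#' attribute, so `read_samples(write_samples(x))` round-trips both values
#' and flags.
#'
#' @param path file path.
#' @param sep field delimiter (`","` or `"\t"`).
#' @param column_map optional named character vector mapping file headers
#'   to canonical column names (`c(file_header = "canonical")`).
#' @return `read_samples`: a sample data.frame; `write_samples`: the path,
#'   invisibly.
#' @export
read_samples <- function(path, sep = ",", column_map = NULL) {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    hit <- names(raw) %in% names(column_map)
    names(raw)[hit] <- column_map[names(raw)[hit]]
  }
  known <- c("site_id", "campaign", "temperature", "ph", "ec",
             "dissolved_oxygen", "tds", "alkalinity_caco3",
             "ca_hardness_caco3", "total_hardness_caco3",
             major_ions(), trace_metals())
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    warning("ignoring unknown column(s): ", paste(unknown, collapse = ", "))
    raw <- raw[setdiff(names(raw), unknown)]
  }
  if (nrow(raw) == 0) {
    out <- raw
    for (col in setdiff(names(raw), c("site_id", "campaign")))
      out[[col]] <- numeric(0)
    attr(out, "bdl") <- .normalise_bdl(out, NULL)
    return(out)
  }
  out <- raw[intersect(c("site_id", "campaign"), names(raw))]
  num_cols <- setdiff(names(raw), c("site_id", "campaign"))
  bdl <- list()
  for (col in num_cols) {
    txt <- trimws(raw[[col]])
    is_bdl <- startsWith(txt, "<")
    txt[is_bdl] <- substring(txt[is_bdl], 2)
    val <- suppressWarnings(as.numeric(txt))
    bad <- which(!is.na(txt) & txt != "" & txt != "NA" & is.na(val))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' in column '%s' (data line %d)",
                   raw[[col]][bad[1]], col, bad[1]))
    out[[col]] <- val
    bdl[[col]] <- is_bdl
  }
  validate_samples(out)
  attr(out, "bdl") <- .normalise_bdl(out, as.data.frame(bdl))
  out
}

#' @rdname read_samples
#' @param samples a sample data.frame.
#' @export
write_samples <- function(samples, path, sep = ",") {
  bdl <- bdl_flags(samples)
  out <- samples
  for (col in names(out)) {
    if (col %in% names(bdl)) {
      txt <- as.character(out[[col]])
      flag <- bdl[[col]]
      txt[flag] <- paste0("<", txt[flag])
      out[[col]] <- txt
    }
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Long-format export of a sample table
#'
#' One row per sample x parameter, convenient for plotting.
#'
#' @param samples a sample data.frame.
#' @return data.frame with columns site_id, campaign, parameter, value.
#' @export
samples_long <- function(samples) {
  cols <- .conc_cols(samples)
  do.call(rbind, lapply(cols, function(col) {
    data.frame(site_id = samples$site_id, campaign = samples$campaign,
               parameter = col, value = samples[[col]],
               stringsAsFactors = FALSE)
  }))
}
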