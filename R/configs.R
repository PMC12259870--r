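# Loaders for the shipped YAML parameter tables (guidelines, toxicity,
# exposure constants, corrosion thresholds). All defaults ship as editable
# data files rather than hard-coded constants.

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "springrisk")
  if (!nzchar(path)) stop("cannot locate shipped data file ", file)
  path
}

#' Load a guideline set
#'
#' Reads a YAML file of per-parameter drinking-water objectives into a
#' guideline data.frame with columns `parameter`, `objective` and
#' `direction` (`"ceiling"`: value must not exceed the objective;
#' `"floor"`: must not fall below it). A parameter may carry both a floor
#' and a ceiling (pH does). The shipped default holds WHO-2017-based
#' values.
#'
#' @param path YAML file; defaults to the shipped WHO 2017 set.
#' @return data.frame of class `guideline_set`.
#' @export
load_guidelines <- function(path = .extdata("guidelines_who2017.yaml")) {
  raw <- yaml::read_yaml(path)$guidelines
  g <- do.call(rbind, lapply(raw, function(e) {
    data.frame(parameter = e$parameter, objective = as.numeric(e$objective),
               direction = e$direction, stringsAsFactors = FALSE)
  }))
  bad <- g$direction == "ceiling" & g$objective <= 0
  if (any(bad))
    stop("non-positive ceiling objective for: ",
         paste(g$parameter[bad], collapse = ", "))
  if (!all(g$direction %in% c("ceiling", "floor")))
    stop("guideline direction must be 'ceiling' or 'floor'")
  class(g) <- c("guideline_set", "data.frame")
  g
}

#' Load the per-metal toxicity table
#'
#' Reference doses (oral and dermal), dermal absorption fractions,
#' permeability coefficients, cancer slope factors, toxic response factors
#' and geochemical background values for the ten risk-assessed metals.
#'
#' @param path YAML file; defaults to the shipped table.
#' @return data.frame of class `toxicity_table`, one row per metal, with
#'   columns `metal`, `rfd_oral`, `rfd_dermal`, `abs`, `kp`, `csf_oral`,
#'   `csf_dermal`, `tr`, `cbg`.
#' @export
load_toxicity <- function(path = .extdata("toxicity.yaml")) {
  raw <- yaml::read_yaml(path)$metals
  num <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  tox <- do.call(rbind, lapply(names(raw), function(m) {
    e <- raw[[m]]
    data.frame(metal = m, rfd_oral = num(e$rfd_oral),
               rfd_dermal = num(e$rfd_dermal), abs = num(e$abs),
               kp = num(e$kp), csf_oral = num(e$csf_oral),
               csf_dermal = num(e$csf_dermal), tr = num(e$tr),
               cbg = num(e$cbg), stringsAsFactors = FALSE)
  }))
  rownames(tox) <- tox$metal
  if (any(tox$kp <= 0, na.rm = TRUE)) stop("Kp must be positive")
  # internal consistency of the dermal reference doses
  rel <- abs(tox$rfd_dermal - tox$rfd_oral * tox$abs) / tox$rfd_dermal
  if (any(rel > 1e-6))
    stop("rfd_dermal != rfd_oral * abs for: ",
         paste(tox$metal[rel > 1e-6], collapse = ", "))
  class(tox) <- c("toxicity_table", "data.frame")
  tox
}

#' Build a receptor exposure profile
#'
#' Exposure constants for the intake equations. The non-carcinogenic
#' averaging time defaults to `ed * 365` days; the tabulated literal value
#' can be requested instead (`use_literal_at_nc = TRUE`), or any field can
#' be overridden via `...`.
#'
#' @param receptor `"adult"` or `"child"`.
#' @param path YAML file of receptor constants; defaults to the shipped
#'   table.
#' @param use_literal_at_nc use the tabulated non-carcinogenic averaging
#'   time instead of `ed * 365`.
#' @param ... named overrides for individual fields (e.g. `ir = 2`).
#' @return list of class `exposure_profile` with fields `receptor`, `ir`,
#'   `ef`, `ed`, `bw`, `sa`, `et`, `cf`, `at_carcinogenic`,
#'   `at_noncarcinogenic`.
#' @export
exposure_profile <- function(receptor = c("adult", "child"),
                             path = .extdata("exposure.yaml"),
                             use_literal_at_nc = NULL, ...) {
  receptor <- match.arg(receptor)
  raw <- yaml::read_yaml(path)
  if (is.null(use_literal_at_nc))
    use_literal_at_nc <- isTRUE(raw$use_literal_at_nc)
  p <- raw$receptors[[receptor]]
  if (is.null(p)) stop("no exposure constants for receptor ", receptor)
  p <- lapply(p, as.numeric)
  p$at_noncarcinogenic <- if (use_literal_at_nc)
    p$at_noncarcinogenic_literal else p$ed * 365
  p$at_noncarcinogenic_literal <- NULL
  over <- list(...)
  p[names(over)] <- lapply(over, as.numeric)
  p$receptor <- receptor
  if (any(unlist(p[setdiff(names(p), "receptor")]) <= 0))
    stop("all exposure constants must be positive")
  structure(p, class = "exposure_profile")
}

#' @export
print.exposure_profile <- function(x, ...) {
  cat(sprintf("Exposure profile: %s\n", x$receptor))
  cat(sprintf(
    "  IR %.2f L/d, EF %g d/y, ED %g y, BW %g kg, SA %g cm2, ET %g h/d\n",
    x$ir, x$ef, x$ed, x$bw, x$sa, x$et))
  cat(sprintf("  AT: %g d (carcinogenic), %g d (non-carcinogenic)\n",
              x$at_carcinogenic, x$at_noncarcinogenic))
  invisible(x)
}

#' Load corrosion-classification thresholds
#'
#' @param path YAML file; defaults to the shipped thresholds.
#' @return Nested list of per-index cutoffs.
#' @export
load_corrosion_thresholds <- function(path = .extdata("corrosion_thresholds.yaml")) {
  yaml::read_yaml(path)
}
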