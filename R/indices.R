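# Water-quality and contamination indices: the CCME water quality index
# (CWQI), the heavy metal pollution index (HPI), the heavy metal index
# (HMI) and the Hakanson potential ecological risk index (ERI), each with
# its published classification tiers.

#' Metal standards from a guideline set
#'
#' Extracts the ceiling objectives of the risk-assessed metals, used as
#' the WHO standards S_i of the HPI and the higher allowable limits of
#' the HMI.
#'
#' @param guidelines a guideline data.frame from [load_guidelines()].
#' @param metals metal names to extract.
#' @return Named numeric vector of objectives (mg/L).
#' @export
metal_standards <- function(guidelines = load_guidelines(),
                            metals = rownames(load_toxicity())) {
  g <- guidelines[guidelines$direction == "ceiling" &
                    guidelines$parameter %in% metals, ]
  stats::setNames(g$objective, g$parameter)[metals]
}

# CCME categorisation (Table-style bands on the 0-100 score)
.cwqi_category <- function(score) {
  ifelse(score >= 95, "Excellent",
         ifelse(score >= 80, "Good",
                ifelse(score >= 65, "Fair",
                       ifelse(score >= 45, "Marginal", "Poor"))))
}

#' CCME water quality index
#'
#' Combines the scope (F1: percent of parameters failing at least once),
#' frequency (F2: percent of failed tests) and amplitude (F3: scaled mean
#' excursion) of guideline exceedances over a set of samples into a
#' 0-100 score:
#' \deqn{CWQI = 100 - \sqrt{F1^2 + F2^2 + F3^2} / 1.732}
#' Excursions are value/objective - 1 for ceilings and
#' objective/value - 1 for floors; nse is their sum divided by the total
#' number of tests and F3 = nse / (0.01 nse + 0.01). A parameter counts
#' once towards F1 however many of its tests fail. Categories: 95-100
#' Excellent, 80-94 Good, 65-79 Fair, 45-64 Marginal, 0-44 Poor.
#'
#' @param samples a sample data.frame (each row x parameter measurement
#'   is one test).
#' @param guidelines a guideline data.frame from [load_guidelines()].
#' @param scope parameters to include; defaults to every sample column
#'   with a guideline.
#' @return Object of class `cwqi_result`: `f1`, `f2`, `f3`, `nse`,
#'   `score`, `category`, counts and a per-failure `excursions`
#'   data.frame.
#' @export
cwqi <- function(samples, guidelines = load_guidelines(), scope = NULL) {
  if (nrow(samples) < 1) stop("cwqi needs at least one sample")
  if (is.null(scope))
    scope <- intersect(unique(guidelines$parameter), names(samples))
  scope <- intersect(scope, names(samples))
  g <- guidelines[guidelines$parameter %in% scope, ]
  if (nrow(g) == 0) stop("no guideline available for any in-scope parameter")
  if (any(g$objective <= 0 & g$direction == "ceiling"))
    stop("guideline objectives must be positive")

  n_tests <- 0L
  failed_params <- character(0)
  evaluated_params <- character(0)
  exc <- list()
  for (param in unique(g$parameter)) {
    vals <- samples[[param]]
    ok <- !is.na(vals)
    if (!any(ok)) next
    evaluated_params <- c(evaluated_params, param)
    n_tests <- n_tests + sum(ok)
    for (j in which(g$parameter == param)) {
      obj <- g$objective[j]
      if (g$direction[j] == "ceiling") {
        fail <- ok & vals > obj
        e <- abs(vals / obj) - 1
      } else {
        fail <- ok & vals < obj
        e <- abs(obj / vals) - 1
      }
      if (any(fail)) {
        failed_params <- union(failed_params, param)
        exc[[length(exc) + 1L]] <- data.frame(
          row = which(fail), parameter = param, value = vals[fail],
          objective = obj, direction = g$direction[j],
          excursion = e[fail], stringsAsFactors = FALSE)
      }
    }
  }
  excursions <- if (length(exc)) do.call(rbind, exc) else
    data.frame(row = integer(0), parameter = character(0),
               value = numeric(0), objective = numeric(0),
               direction = character(0), excursion = numeric(0))
  n_params <- length(evaluated_params)
  if (n_params == 0) stop("no in-scope parameter has any measurement")
  f1 <- 100 * length(failed_params) / n_params
  f2 <- 100 * nrow(excursions) / n_tests
  nse <- sum(excursions$excursion) / n_tests
  f3 <- nse / (0.01 * nse + 0.01)
  score <- max(0, 100 - sqrt(f1^2 + f2^2 + f3^2) / 1.732)
  structure(list(f1 = f1, f2 = f2, f3 = f3, nse = nse, score = score,
                 category = .cwqi_category(score),
                 n_parameters = n_params, n_tests = n_tests,
                 failed_parameters = failed_params,
                 failed_tests = nrow(excursions), excursions = excursions),
            class = "cwqi_result")
}

#' @export
print.cwqi_result <- function(x, ...) {
  cat(sprintf("CWQI %.2f (%s)\n", x$score, x$category))
  cat(sprintf("  F1 %.2f  F2 %.2f  F3 %.3f  (nse %.4f)\n",
              x$f1, x$f2, x$f3, x$nse))
  cat(sprintf("  %d/%d parameters failed, %d/%d tests failed\n",
              length(x$failed_parameters), x$n_parameters,
              x$failed_tests, x$n_tests))
  invisible(x)
}

.hpi_category <- function(hpi) {
  ifelse(hpi > 100, "Unsuitable",
         ifelse(hpi > 76, "Very Poor",
                ifelse(hpi > 30, "Poor",
                       ifelse(hpi >= 15, "Good", "Excellent"))))
}

#' Heavy metal pollution index
#'
#' Weighted mean of sub-indices Q_i = 100 C_i / S_i with weights
#' W_i = 1 / S_i (S_i the drinking-water standard):
#' \deqn{HPI = \sum W_i Q_i / \sum W_i}
#' Tiers (resolved to disjoint bands): <15 Excellent, 15-30 Good,
#' 30-76 Poor, 76-100 Very Poor, >100 Unsuitable. Invariant to metal
#' ordering and to consistent unit changes of C_i and S_i.
#'
#' @param concentrations named numeric vector of metal concentrations
#'   (mg/L).
#' @param standards named numeric vector of standards S_i, same units;
#'   defaults to the shipped guideline objectives.
#' @return Object of class `hpi_result` with `per_metal`, `hpi`,
#'   `category`.
#' @export
hpi <- function(concentrations, standards = metal_standards()) {
  metals <- names(concentrations)
  si <- standards[metals]
  if (anyNA(si)) stop("no standard for: ",
                      paste(metals[is.na(si)], collapse = ", "))
  if (any(si <= 0)) stop("standards S_i must be positive")
  qi <- 100 * concentrations / si
  wi <- 1 / si
  val <- sum(wi * qi) / sum(wi)
  structure(list(
    per_metal = data.frame(metal = metals, ci = as.numeric(concentrations),
                           si = as.numeric(si), qi = as.numeric(qi),
                           wi = as.numeric(wi), stringsAsFactors = FALSE),
    hpi = val, category = .hpi_category(val)), class = "hpi_result")
}

#' @export
print.hpi_result <- function(x, ...) {
  cat(sprintf("HPI %.2f (%s) over %d metals\n", x$hpi, x$category,
              nrow(x$per_metal)))
  invisible(x)
}

.hmi_category <- function(hmi) {
  ifelse(hmi >= 6, "Seriously Polluted",
         ifelse(hmi >= 4, "Highly Polluted",
                ifelse(hmi >= 2, "Moderately Polluted",
                       ifelse(hmi >= 1, "Somewhat Polluted",
                              ifelse(hmi >= 0.3, "Clean", "Very Clean")))))
}

#' Heavy metal index
#'
#' HMI = sum of concentration-to-allowable-limit ratios C_i / HAL_i.
#' Tiers: <0.3 Very Clean, 0.3-1 Clean, 1-2 Somewhat Polluted, 2-4
#' Moderately Polluted, 4-6 Highly Polluted, >6 Seriously Polluted.
#'
#' @param concentrations named numeric vector (mg/L).
#' @param hal named numeric vector of higher allowable limits, same
#'   units; defaults to the shipped guideline objectives.
#' @return Object of class `hmi_result` with `per_metal`, `hmi`,
#'   `category`.
#' @export
hmi <- function(concentrations, hal = metal_standards()) {
  metals <- names(concentrations)
  h <- hal[metals]
  if (anyNA(h)) stop("no allowable limit for: ",
                     paste(metals[is.na(h)], collapse = ", "))
  if (any(h <= 0)) stop("allowable limits must be positive")
  ratio <- as.numeric(concentrations) / as.numeric(h)
  val <- sum(ratio)
  structure(list(
    per_metal = stats::setNames(ratio, metals), hmi = val,
    category = .hmi_category(val)), class = "hmi_result")
}

#' @export
print.hmi_result <- function(x, ...) {
  cat(sprintf("HMI %.3f (%s)\n", x$hmi, x$category))
  invisible(x)
}

.eri_category <- function(eri) {
  ifelse(eri >= 120, "very high",
         ifelse(eri >= 60, "considerable",
                ifelse(eri >= 30, "moderate", "low")))
}

#' Hakanson potential ecological risk index
#'
#' Per-metal ecological risk factor E_r = T_r C_i / C_bg (toxic response
#' factor times the concentration-to-background ratio) summed into the
#' ERI. The ratio C_i / C_bg is taken directly between the water
#' concentration (mg/L) and the tabulated background value, the
#' convention of the reference background table shipped with the package.
#' Categories: <30 low, 30-60 moderate, 60-120 considerable, >120 very
#' high. Additive over disjoint metal sets.
#'
#' @param concentrations named numeric vector of metal concentrations.
#' @param toxicity a toxicity table from [load_toxicity()] supplying
#'   `tr` and `cbg` per metal (same concentration units as
#'   `concentrations`).
#' @return Object of class `eri_result` with `per_metal_er`, `eri`,
#'   `category`.
#' @export
eri <- function(concentrations, toxicity = load_toxicity()) {
  metals <- names(concentrations)
  missing <- setdiff(metals, rownames(toxicity))
  if (length(missing)) stop("no toxicity entry for: ",
                            paste(missing, collapse = ", "))
  tr <- toxicity[metals, "tr"]
  cbg <- toxicity[metals, "cbg"]
  if (any(cbg <= 0)) stop("background values C_bg must be positive")
  er <- tr * as.numeric(concentrations) / cbg
  val <- sum(er)
  structure(list(per_metal_er = stats::setNames(er, metals), eri = val,
                 category = .eri_category(val)), class = "eri_result")
}

#' @export
print.eri_result <- function(x, ...) {
  cat(sprintf("ERI %.3f (%s risk)\n", x$eri, x$category))
  invisible(x)
}
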