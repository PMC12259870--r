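# Monte-Carlo propagation of input uncertainty through the HQ/CR
# formulas. Draws are evaluated through the deterministic intake
# functions (one code path); summaries report mean, sd and the 5th/50th/
# 95th percentiles (type-7 linear interpolation) plus threshold
# exceedance fractions.

#' Distribution specification for a Monte-Carlo input
#'
#' Families: `point(value)`, `uniform(min, max)`,
#' `triangular(min, mode, max)` (inverse-CDF sampling),
#' `normal(mean, sd)` and `lognormal(meanlog, sdlog)`. All physical
#' parameters are non-negative, so draws are truncated at zero.
#'
#' @param family one of the five family names.
#' @param ... family-specific constants as named arguments.
#' @return Object of class `dist_spec`.
#' @export
dist_spec <- function(family = c("point", "uniform", "triangular",
                                 "normal", "lognormal"), ...) {
  family <- match.arg(family)
  p <- list(...)
  need <- switch(family,
                 point = "value", uniform = c("min", "max"),
                 triangular = c("min", "mode", "max"),
                 normal = c("mean", "sd"), lognormal = c("meanlog", "sdlog"))
  missing <- setdiff(need, names(p))
  if (length(missing))
    stop(sprintf("%s distribution needs: %s", family,
                 paste(missing, collapse = ", ")))
  if (family %in% c("uniform", "triangular") && p$min > p$max)
    stop("min > max in ", family, " distribution")
  if (family == "triangular" && (p$mode < p$min || p$mode > p$max))
    stop("triangular mode outside [min, max]")
  if (family == "normal" && p$sd < 0) stop("normal sd must be >= 0")
  structure(list(family = family, params = p), class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  cat(sprintf("%s(%s)\n", x$family,
              paste(sprintf("%s=%g", names(x$params),
                            unlist(x$params)), collapse = ", ")))
  invisible(x)
}

.sample_dist <- function(spec, n) {
  p <- spec$params
  x <- switch(spec$family,
    point = rep(p$value, n),
    uniform = stats::runif(n, p$min, p$max),
    triangular = {
      u <- stats::runif(n)
      w <- p$max - p$min
      if (w == 0) rep(p$min, n) else {
        fc <- (p$mode - p$min) / w
        ifelse(u < fc,
               p$min + sqrt(u * w * (p$mode - p$min)),
               p$max - sqrt((1 - u) * w * (p$max - p$mode)))
      }
    },
    normal = stats::rnorm(n, p$mean, p$sd),
    lognormal = stats::rlnorm(n, p$meanlog, p$sdlog))
  pmax(x, 0)
}

#' Monte-Carlo configuration
#'
#' @param n_iterations number of draws (default 10000).
#' @param seed integer RNG seed; fully determines the output.
#' @return Object of class `mc_config`.
#' @export
mc_config <- function(n_iterations = 10000, seed = 1) {
  stopifnot(n_iterations >= 1)
  structure(list(n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed)), class = "mc_config")
}

#' Default input distributions for one metal
#'
#' The study design never pins distribution families, so the defaults
#' are: triangular for the exposure factors (mode at the tabulated value,
#' +/-20 percent) and uniform over the observed min-max range for the
#' concentration; Kp is held at its tabulated point value. Everything is
#' overridable.
#'
#' @param c_range length-2 numeric, observed concentration range (mg/L).
#' @param profile an [exposure_profile()].
#' @param kp tabulated permeability coefficient (cm/h).
#' @param spread relative half-width of the triangular factors.
#' @return Named list of [dist_spec()] objects (`C`, `IR`, `EF`, `ED`,
#'   `BW`, `SA`, `ET`, `Kp`).
#' @export
default_mc_distributions <- function(c_range, profile, kp,
                                     spread = 0.2) {
  tri <- function(v) dist_spec("triangular", min = v * (1 - spread),
                               mode = v, max = v * (1 + spread))
  list(C = dist_spec("uniform", min = min(c_range), max = max(c_range)),
       IR = tri(profile$ir), EF = tri(profile$ef), ED = tri(profile$ed),
       BW = tri(profile$bw), SA = tri(profile$sa), ET = tri(profile$et),
       Kp = dist_spec("point", value = kp))
}

# draw all input parameters in a fixed order (seed-reproducible)
.mc_draw_inputs <- function(n, distributions, profile, kp, c_conc) {
  defaults <- list(C = c_conc, IR = profile$ir, EF = profile$ef,
                   ED = profile$ed, BW = profile$bw, SA = profile$sa,
                   ET = profile$et, Kp = kp, AT = NA_real_)
  unknown <- setdiff(names(distributions), names(defaults))
  if (length(unknown))
    stop("unknown Monte-Carlo parameter(s): ",
         paste(unknown, collapse = ", "))
  draws <- list()
  for (nm in names(defaults)) {
    draws[[nm]] <- if (nm %in% names(distributions))
      .sample_dist(distributions[[nm]], n)
    else defaults[[nm]]
  }
  draws
}

.mc_evaluate <- function(d, profile, pathway, horizon, rfd = NULL,
                         csf = NULL) {
  at <- if (all(is.na(d$AT)))
    .at_for(profile, horizon) else d$AT
  cdi <- if (pathway == "oral")
    cdi_oral(d$C, profile, horizon, ir = d$IR, ef = d$EF, ed = d$ED,
             bw = d$BW, at = at)
  else
    cdi_dermal(d$C, d$Kp, profile, horizon, et = d$ET, sa = d$SA,
               ef = d$EF, ed = d$ED, bw = d$BW, at = at)
  if (!is.null(rfd)) hazard_quotient(cdi, rfd) else cancer_risk(cdi, csf)
}

.mc_summarise <- function(x, threshold, endpoint, n, target = NULL) {
  x <- rep_len(x, n)   # all-point-mass runs give a scalar
  q <- stats::quantile(x, c(0.05, 0.5, 0.95), type = 7, names = FALSE)
  structure(list(mean = mean(x), sd = stats::sd(x), p5 = q[1], p50 = q[2],
                 p95 = q[3], fraction_exceeding = mean(x > threshold),
                 threshold = threshold, endpoint = endpoint, n = n,
                 target = target, draws = x), class = "mc_summary")
}

#' @export
print.mc_summary <- function(x, ...) {
  if (!is.null(x$target)) cat(x$target, "\n")
  cat(sprintf("%s over %d draws: mean %.4g (sd %.3g)\n",
              x$endpoint, x$n, x$mean, x$sd))
  cat(sprintf("  p5 %.4g  p50 %.4g  p95 %.4g  P(> %g) = %.4f\n",
              x$p5, x$p50, x$p95, x$threshold, x$fraction_exceeding))
  invisible(x)
}

#' Monte-Carlo hazard quotient / cancer risk for one target
#'
#' Draws every input of the target formula from its declared distribution
#' (point masses for anything undeclared), evaluates each draw through
#' the deterministic intake functions, and summarises. With all-point
#' distributions the summary collapses exactly onto the deterministic
#' value.
#'
#' @param config an [mc_config()].
#' @param metal metal name (row of the toxicity table).
#' @param pathway `"oral"` or `"dermal"`.
#' @param receptor `"adult"` or `"child"`.
#' @param endpoint `"HQ"` or `"CR"`.
#' @param c_conc deterministic concentration (mg/L), used when no `C`
#'   distribution is declared.
#' @param distributions named list of [dist_spec()] objects over
#'   `C, IR, EF, ED, BW, SA, ET, Kp, AT`.
#' @param toxicity a toxicity table from [load_toxicity()].
#' @param profile exposure profile; defaults to
#'   `exposure_profile(receptor)`.
#' @return An `mc_summary` with mean, sd, p5/p50/p95 and the fraction of
#'   draws exceeding the endpoint threshold (HQ > 1, CR > 1e-4).
#' @export
run_mc <- function(config, metal, pathway = c("oral", "dermal"),
                   receptor = c("adult", "child"),
                   endpoint = c("HQ", "CR"), c_conc = NULL,
                   distributions = list(), toxicity = load_toxicity(),
                   profile = NULL) {
  pathway <- match.arg(pathway)
  receptor <- match.arg(receptor)
  endpoint <- match.arg(endpoint)
  if (is.null(profile)) profile <- exposure_profile(receptor)
  if (!metal %in% rownames(toxicity)) stop("no toxicity entry for ", metal)
  tox <- toxicity[metal, ]
  if (is.null(c_conc) && !"C" %in% names(distributions))
    stop("a concentration is needed: pass c_conc or a 'C' distribution")
  if (is.null(c_conc)) c_conc <- NA_real_
  set.seed(config$seed)
  n <- config$n_iterations
  d <- .mc_draw_inputs(n, distributions, profile, tox$kp, c_conc)
  if (endpoint == "HQ") {
    rfd <- if (pathway == "oral") tox$rfd_oral else tox$rfd_dermal
    x <- .mc_evaluate(d, profile, pathway, "noncarcinogenic", rfd = rfd)
    threshold <- 1
  } else {
    csf <- if (pathway == "oral") tox$csf_oral else tox$csf_dermal
    x <- .mc_evaluate(d, profile, pathway, "carcinogenic", csf = csf)
    threshold <- cr_acceptable_band()[["upper"]]
  }
  .mc_summarise(x, threshold, endpoint, n,
                target = sprintf("%s %s %s %s", receptor, pathway, metal,
                                 endpoint))
}

#' Monte-Carlo cumulative carcinogenic risk
#'
#' Per-draw sum of the cancer risks of two or more carcinogens sharing a
#' pathway and receptor. Exposure-factor draws are shared across metals
#' within a draw; each metal may carry its own concentration (and Kp)
#' distribution via `metal_distributions`.
#'
#' @inheritParams run_mc
#' @param metals two or more carcinogen names.
#' @param c_conc named numeric vector of deterministic concentrations.
#' @param metal_distributions named list (by metal) of per-metal
#'   distribution lists (entries `C`, `Kp`).
#' @param distributions shared exposure-factor distributions.
#' @return An `mc_summary` of the cumulative risk (threshold 1e-4).
#' @export
cumulative_cr_mc <- function(config, metals, pathway = c("oral", "dermal"),
                             receptor = c("adult", "child"),
                             c_conc = NULL, distributions = list(),
                             metal_distributions = list(),
                             toxicity = load_toxicity(), profile = NULL) {
  pathway <- match.arg(pathway)
  receptor <- match.arg(receptor)
  if (length(metals) < 2)
    stop("cumulative risk needs at least two carcinogens")
  if (is.null(profile)) profile <- exposure_profile(receptor)
  set.seed(config$seed)
  n <- config$n_iterations
  shared <- .mc_draw_inputs(n, distributions, profile, kp = NA_real_,
                            c_conc = NA_real_)
  total <- numeric(n)
  for (metal in metals) {
    tox <- toxicity[metal, ]
    csf <- if (pathway == "oral") tox$csf_oral else tox$csf_dermal
    if (is.na(csf)) stop(metal, " has no slope factor for ", pathway)
    d <- shared
    md <- metal_distributions[[metal]]
    d$C <- if (!is.null(md$C)) .sample_dist(md$C, n)
           else if (!is.null(c_conc)) c_conc[[metal]]
           else stop("no concentration for ", metal)
    d$Kp <- if (!is.null(md$Kp)) .sample_dist(md$Kp, n) else tox$kp
    total <- total + .mc_evaluate(d, profile, pathway, "carcinogenic",
                                  csf = csf)
  }
  .mc_summarise(total, cr_acceptable_band()[["upper"]], "cumulative CR", n,
                target = sprintf("%s %s %s cumulative", receptor, pathway,
                                 paste(metals, collapse = "+")))
}
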