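# shared in-code fixtures

# one fully specified sample row (concentrations mg/L)
make_sample <- function(Ca = 60, Mg = 5, Na = 8, K = 1, HCO3 = 200,
                        Cl = 15, SO4 = 30, NO3 = 5, ph = 7.2,
                        temperature = 10, site_id = "S", campaign = "Feb",
                        ...) {
  water_samples(site_id = site_id, campaign = campaign,
                temperature = temperature, ph = ph,
                Ca = Ca, Mg = Mg, Na = Na, K = K, HCO3 = HCO3, Cl = Cl,
                SO4 = SO4, NO3 = NO3, ...)
}

# guideline table built in code (ceilings only unless stated)
make_guidelines <- function(params, objectives,
                            directions = rep("ceiling", length(params))) {
  data.frame(parameter = params, objective = objectives,
             direction = directions, stringsAsFactors = FALSE)
}

# independent brute-force CCME enumeration: loops over every test and
# bound, never shares code with cwqi()
brute_cwqi <- function(samples, guidelines) {
  params <- intersect(unique(guidelines$parameter), names(samples))
  failed_params <- character(0)
  n_tests <- 0; n_failed <- 0; exc_sum <- 0
  for (p in params) {
    for (i in seq_len(nrow(samples))) {
      v <- samples[[p]][i]
      if (is.na(v)) next
      n_tests <- n_tests + 1
      rows <- which(guidelines$parameter == p)
      for (j in rows) {
        obj <- guidelines$objective[j]
        if (guidelines$direction[j] == "ceiling" && v > obj) {
          n_failed <- n_failed + 1
          exc_sum <- exc_sum + (abs(v / obj) - 1)
          failed_params <- union(failed_params, p)
        } else if (guidelines$direction[j] == "floor" && v < obj) {
          n_failed <- n_failed + 1
          exc_sum <- exc_sum + (abs(obj / v) - 1)
          failed_params <- union(failed_params, p)
        }
      }
    }
  }
  f1 <- 100 * length(failed_params) / length(params)
  f2 <- 100 * n_failed / n_tests
  nse <- exc_sum / n_tests
  f3 <- nse / (0.01 * nse + 0.01)
  list(f1 = f1, f2 = f2, f3 = f3, nse = nse,
       score = max(0, 100 - sqrt(f1^2 + f2^2 + f3^2) / 1.732))
}
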