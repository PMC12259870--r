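test_that("CWQI returns 100/Excellent when nothing fails", {
  s <- make_sample()
  g <- make_guidelines(c("Ca", "Cl"), c(100, 100))
  res <- cwqi(s, g)
  expect_equal(res$f1, 0)
  expect_equal(res$f2, 0)
  expect_equal(res$f3, 0)
  expect_equal(res$score, 100)
  expect_equal(res$category, "Excellent")
})

test_that("CWQI reproduces the multi-failure worked example", {
  # 10 parameters x 4 samples = 40 tests; 2 failing parameters,
  # 3 failing tests, excursions 1.0 + 0.25 + 0.25 = 1.5
  params <- paste0("p", 1:10)
  s <- as.data.frame(stats::setNames(rep(list(rep(50, 4)), 10), params))
  s$site_id <- "S"; s$campaign <- c("Nov", "Feb", "May", "Aug")
  s$p1[1] <- 200; s$p1[2] <- 125; s$p2[1] <- 125
  g <- make_guidelines(params, rep(100, 10))
  res <- cwqi(s, g)
  expect_equal(res$f1, 20)
  expect_equal(res$f2, 7.5)
  expect_equal(res$nse, 0.0375)
  expect_equal(res$f3, 0.0375 / (0.0375 * 0.01 + 0.01))
  expect_equal(round(res$f3, 3), 3.614)
  expect_equal(round(res$score, 2), 87.49)
  expect_equal(res$category, "Good")
})

test_that("CWQI matches a brute-force enumeration oracle on random inputs", {
  set.seed(42)
  for (rep in 1:10) {
    n_par <- sample(3:8, 1); n_obs <- sample(2:6, 1)
    params <- paste0("q", seq_len(n_par))
    s <- as.data.frame(stats::setNames(
      lapply(seq_len(n_par), function(i) stats::runif(n_obs, 0, 200)),
      params))
    s$site_id <- "S"; s$campaign <- as.character(seq_len(n_obs))
    dirs <- sample(c("ceiling", "floor"), n_par, replace = TRUE)
    g <- make_guidelines(params, stats::runif(n_par, 40, 160), dirs)
    got <- cwqi(s, g)
    want <- brute_cwqi(s, g)
    expect_equal(got$f1, want$f1, tolerance = 1e-12)
    expect_equal(got$f2, want$f2, tolerance = 1e-12)
    expect_equal(got$f3, want$f3, tolerance = 1e-12)
    expect_equal(got$score, want$score, tolerance = 1e-12)
  }
})

test_that("CWQI is monotone in added failures and errors without guidelines", {
  s <- make_sample(Ca = 90)
  g <- make_guidelines("Ca", 100)
  base <- cwqi(s, g)$score
  s_fail <- make_sample(Ca = 150)
  expect_lt(cwqi(s_fail, g)$score, base)
  expect_error(cwqi(s, make_guidelines("Li", 1)), "no guideline")
})

test_that("CWQI banding follows the published classification table", {
  bands <- springrisk:::.cwqi_category
  expect_equal(bands(85.15), "Good")
  expect_equal(bands(96.52), "Excellent")
  expect_equal(bands(c(10, 50, 70, 94.9, 95)),
               c("Poor", "Marginal", "Fair", "Good", "Excellent"))
})

test_that("HPI matches the weighted-mean arithmetic and its tiers", {
  # all concentrations at standard: every Qi = 100, HPI = 100
  res <- hpi(c(A = 0.1, B = 2), c(A = 0.1, B = 2))
  expect_equal(res$hpi, 100)
  # hand-computed two-metal example
  res2 <- hpi(c(Pb = 0.02, Cd = 0.0015), c(Pb = 0.01, Cd = 0.003))
  expect_equal(res2$per_metal$qi, c(200, 50))
  expect_equal(res2$per_metal$wi, c(100, 1 / 0.003))
  expect_equal(res2$hpi, (100 * 200 + (1 / 0.003) * 50) / (100 + 1 / 0.003))
  expect_equal(round(res2$hpi, 2), 84.62)
  # order invariance and consistent-unit invariance
  res3 <- hpi(c(Cd = 0.0015, Pb = 0.02), c(Pb = 0.01, Cd = 0.003))
  expect_equal(res3$hpi, res2$hpi)
  res4 <- hpi(1000 * c(Pb = 0.02, Cd = 0.0015),
              1000 * c(Pb = 0.01, Cd = 0.003))
  expect_equal(res4$hpi, res2$hpi)
  expect_error(hpi(c(Pb = 1), c(Pb = 0)), "positive")
})

test_that("HMI sums limit ratios and classifies contamination levels", {
  res <- hmi(c(Pb = 0.02, Cd = 0.0015), c(Pb = 0.01, Cd = 0.003))
  expect_equal(res$hmi, 2.5)
  expect_equal(res$category, "Moderately Polluted")
  # Ci = HAL over n metals gives HMI = n
  res_n <- hmi(c(A = 1, B = 2, C = 3), c(A = 1, B = 2, C = 3))
  expect_equal(res_n$hmi, 3)
  expect_error(hmi(c(A = 1), c(A = -1)), "positive")
})

test_that("ERI applies toxic response factors over background and is additive", {
  tox <- load_toxicity()
  res <- eri(c(Hg = 0.00784, Pb = 0.002, Cd = 0.00025), tox)
  expect_equal(unname(res$per_metal_er),
               c(40 * 0.00784 / 0.8, 5 * 0.002 / 12.5, 30 * 0.00025 / 0.2),
               tolerance = 1e-12)
  expect_equal(round(res$eri, 3), 0.430)
  expect_equal(res$category, "low")
  # Ci = Cbg for every metal gives ERI = sum of Tr
  all_bg <- stats::setNames(tox$cbg, tox$metal)
  expect_equal(eri(all_bg, tox)$eri, sum(tox$tr))
  # additive over disjoint metal sets
  a <- eri(c(Hg = 0.005), tox)$eri
  b <- eri(c(Pb = 0.002), tox)$eri
  expect_equal(eri(c(Hg = 0.005, Pb = 0.002), tox)$eri, a + b)
})
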