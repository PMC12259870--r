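test_that("Piper percentages match hand meq arithmetic and sum to 100", {
  s <- make_sample(Ca = 60, Mg = 5, Na = 8, K = 1, HCO3 = 200, Cl = 15,
                   SO4 = 30, NO3 = 0)
  p <- piper_coordinates(s)
  # independent arithmetic on the fixed equivalent weights
  cat_meq <- c(60 / 20.04, 5 / 12.15, 8 / 22.99 + 1 / 39.10)
  an_meq <- c(200 / 61.02, 30 / 48.03, 15 / 35.45)
  expect_equal(p$Ca_pct, 100 * cat_meq[1] / sum(cat_meq), tolerance = 1e-12)
  expect_equal(p$Mg_pct, 100 * cat_meq[2] / sum(cat_meq), tolerance = 1e-12)
  expect_equal(p$NaK_pct, 100 * cat_meq[3] / sum(cat_meq), tolerance = 1e-12)
  expect_equal(p$HCO3_pct, 100 * an_meq[1] / sum(an_meq), tolerance = 1e-12)
  expect_equal(round(c(p$Ca_pct, p$Mg_pct, p$NaK_pct), 1),
               c(79.2, 10.9, 9.9))
  expect_equal(round(c(p$HCO3_pct, p$Cl_pct, p$SO4_pct), 1),
               c(75.8, 9.8, 14.4))
  expect_equal(p$Ca_pct + p$Mg_pct + p$NaK_pct, 100, tolerance = 1e-9)
  expect_equal(p$HCO3_pct + p$SO4_pct + p$Cl_pct, 100, tolerance = 1e-9)
  expect_equal(p$facies, "Ca-Mg-HCO3")
})

test_that("Piper handles the pure CaCO3 end member and degenerate input", {
  s <- make_sample(Ca = 40, Mg = 0, Na = 0, K = 0, HCO3 = 100, Cl = 0,
                   SO4 = 0, NO3 = 0)
  p <- piper_coordinates(s)
  expect_equal(p$Ca_pct, 100)
  expect_equal(p$HCO3_pct, 100)
  z <- make_sample(Ca = 0, Mg = 0, Na = 0, K = 0, HCO3 = 100, Cl = 0,
                   SO4 = 0, NO3 = 0)
  expect_error(piper_coordinates(z), "undefined")
})

test_that("Piper coordinates are invariant to uniform scaling", {
  s1 <- make_sample()
  s2 <- s1
  for (ion in major_ions()) s2[[ion]] <- 3.7 * s2[[ion]]
  p1 <- piper_coordinates(s1); p2 <- piper_coordinates(s2)
  num <- vapply(p1, is.numeric, TRUE)
  expect_equal(p2[num], p1[num], tolerance = 1e-12)
})

test_that("Chadha coordinates agree with hand arithmetic and with Piper", {
  s <- make_sample(Ca = 60, Mg = 5, Na = 8, K = 1, HCO3 = 200, Cl = 15,
                   SO4 = 30, NO3 = 0)
  ch <- chadha_coordinates(s)
  expect_equal(round(ch$x, 1), 80.2)
  expect_equal(round(ch$y, 1), 51.6)
  expect_equal(ch$field, "recharge Ca-Mg-HCO3")
  # cross-module identity: x == (%Ca + %Mg) - %NaK exactly
  p <- piper_coordinates(s)
  expect_equal(ch$x, p$Ca_pct + p$Mg_pct - p$NaK_pct, tolerance = 1e-12)
  # Na- and Cl-dominated water lands in the seawater quadrant
  sea <- make_sample(Ca = 5, Mg = 1, Na = 200, K = 5, HCO3 = 30, Cl = 300,
                     SO4 = 20, NO3 = 0)
  expect_equal(chadha_coordinates(sea)$field, "seawater-type Na-Cl")
})

test_that("Gibbs ratios use mass concentrations and label mechanisms", {
  s <- make_sample(Cl = 15, HCO3 = 200)
  g <- gibbs_ratios(s)
  expect_equal(g$anion_ratio, 15 / 215, tolerance = 1e-12)  # 0.0698
  s_eq <- make_sample(Cl = 100, HCO3 = 100)
  expect_equal(gibbs_ratios(s_eq)$anion_ratio, 0.5)
  # synthetic defaults, both groups: rock weathering
  syn <- generate_springs(generator_config(seed = 2))
  expect_true(all(gibbs_ratios(syn)$mechanism == "rock-weathering"))
  # zero denominators are flagged undefined, not propagated
  z <- make_sample(Ca = 0, Na = 0, Cl = 0, HCO3 = 0,
                   Mg = 10, K = 1, SO4 = 10, NO3 = 1)
  gz <- gibbs_ratios(z)
  expect_true(is.na(gz$anion_ratio))
  expect_equal(gz$mechanism, "undefined")
})

test_that("ionic ratios follow the molar and meq conventions", {
  s <- make_sample(Ca = 40, Na = 23)
  r <- ionic_ratios(s)
  expect_equal(r$ca_na, (40 / 40.08) / (23 / 22.99), tolerance = 1e-12)
  expect_equal(round(r$ca_na, 2), 1.00)
  # Na = Cl in meq sits on the 1:1 line
  s2 <- make_sample(Na = 22.99, Cl = 35.45)
  r2 <- ionic_ratios(s2)
  expect_equal(r2$na_meq, r2$cl_meq)
  # zero Na flags the Na-normalised set as undefined
  s3 <- make_sample(Na = 0)
  r3 <- ionic_ratios(s3)
  expect_true(r3$na_undefined)
  expect_true(is.na(r3$ca_na))
  # recharge-type synthetic means exceed the 0.5 carbonate threshold
  syn <- generate_springs(generator_config(seed = 4))
  rech <- syn[syn$site_id %in% c("R1", "R2", "R3"), ]
  expect_true(all(ionic_ratios(rech)$ca_mg_over_hco3 > 0.5))
})

test_that("chloro-alkaline indices and exchange labels follow the sign rules", {
  # balanced alkalis: both indices zero
  s0 <- make_sample(Cl = 35.45, Na = 22.99, K = 0)
  c0 <- chloro_alkaline(s0)
  expect_equal(c0$cai1, 0)
  expect_equal(c0$cai2, 0)
  expect_equal(c0$exchange, "none")
  # hand-computed positive case
  s1 <- make_sample(Cl = 25, Na = 7.05, K = 1.0)
  c1 <- chloro_alkaline(s1)
  cl <- 25 / 35.45; nak <- 7.05 / 22.99 + 1 / 39.10
  expect_equal(c1$cai1, (cl - nak) / cl, tolerance = 1e-12)
  expect_equal(round(c1$cai1, 2), 0.53)
  expect_equal(c1$exchange, "reverse")
  # zero chloride: CAI-I undefined, label from CAI-II
  s2 <- make_sample(Cl = 0, Na = 10, K = 1)
  c2 <- chloro_alkaline(s2)
  expect_true(is.na(c2$cai1))
  expect_equal(c2$exchange, "direct")
  # mixed-group synthetic springs are predominantly reverse-exchange
  syn <- generate_springs(generator_config(seed = 6))
  mixed <- syn[syn$site_id %in% c("M1", "M2", "M3"), ]
  cm <- chloro_alkaline(mixed)
  expect_gt(mean(cm$exchange == "reverse"), 0.5)
})

test_that("every valid sample receives exactly one label per diagram", {
  syn <- generate_springs(generator_config(seed = 8))
  expect_false(anyNA(piper_coordinates(syn)$facies))
  expect_false(anyNA(chadha_coordinates(syn)$field))
  expect_false(anyNA(gibbs_ratios(syn)$mechanism))
})
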