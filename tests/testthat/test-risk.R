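test_that("exposure profiles carry the receptor constants and the AT rule", {
  ad <- exposure_profile("adult")
  ch <- exposure_profile("child")
  expect_equal(ad$ir, 2.2); expect_equal(ch$ir, 1.8)
  expect_equal(ad$at_noncarcinogenic, 70 * 365)   # ED x 365 rule
  expect_equal(ch$at_noncarcinogenic, 6 * 365)
  # the tabulated literal remains available as an override
  ad_lit <- exposure_profile("adult", use_literal_at_nc = TRUE)
  expect_equal(ad_lit$at_noncarcinogenic, 10950)
  # field overrides
  expect_equal(exposure_profile("adult", bw = 80)$bw, 80)
})

test_that("toxicity table is internally consistent (RfD_dermal = RfD_oral x ABS)", {
  tox <- load_toxicity()
  expect_equal(nrow(tox), 10)
  expect_equal(tox$rfd_dermal, tox$rfd_oral * tox$abs, tolerance = 1e-6)
  expect_true(all(tox$kp > 0))
  expect_equal(sum(!is.na(tox$csf_oral)), 3)   # Cd, Cr, Pb
})

test_that("oral CDI matches the intake formula for both receptors", {
  ad <- exposure_profile("adult"); ch <- exposure_profile("child")
  expect_equal(cdi_oral(0, ad), 0)
  expect_equal(cdi_oral(1, ad), 350 * 2.2 * 70 / (70 * 25550))  # 0.030137
  expect_equal(cdi_oral(1, ch), 350 * 1.8 * 6 / (15 * 2190))    # 0.115068
  # carcinogenic horizon uses the lifetime averaging time
  expect_equal(cdi_oral(1, ch, "carcinogenic"),
               350 * 1.8 * 6 / (15 * 25550))
})

test_that("dermal CDI matches the intake formula and is zero at Kp = 0", {
  ad <- exposure_profile("adult"); ch <- exposure_profile("child")
  expect_equal(cdi_dermal(1, 0, ad), 0)
  expect_equal(cdi_dermal(1, 0.001, ad),
               350 * 0.58 * 70 * 0.001 * 18000 * 1e-3 / (70 * 25550))
  expect_equal(cdi_dermal(1, 0.001, ch),
               350 * 1 * 6 * 0.001 * 6600 * 1e-3 / (15 * 2190))
})

test_that("hazard quotients reproduce the published per-metal values", {
  ad <- exposure_profile("adult"); ch <- exposure_profile("child")
  tox <- load_toxicity()
  hq <- function(metal, c_conc, prof, pathway) {
    if (pathway == "oral")
      hazard_quotient(cdi_oral(c_conc, prof), tox[metal, "rfd_oral"])
    else
      hazard_quotient(cdi_dermal(c_conc, tox[metal, "kp"], prof),
                      tox[metal, "rfd_dermal"])
  }
  # published values carry three (truncated) significant digits, so the
  # match is to half a unit in the third digit (0.5 percent relative)
  expect_equal(hq("Hg", 0.00784, ad, "oral"), 0.787, tolerance = 5e-3)
  expect_equal(hq("Hg", 0.00784, ch, "oral"), 3.01, tolerance = 5e-3)
  expect_equal(hq("Hg", 0.00784, ad, "dermal"), 0.0534, tolerance = 5e-3)
  expect_equal(hq("Hg", 0.00784, ch, "dermal"), 0.157, tolerance = 5e-3)
  expect_equal(hq("Pb", 0.002, ad, "oral"), 0.0431, tolerance = 5e-3)
  expect_equal(hq("Pb", 0.002, ch, "oral"), 0.164, tolerance = 5e-3)
  expect_equal(hq("Cr", 0.0015, ch, "oral"), 0.0575, tolerance = 5e-3)
  expect_equal(hq("Cr", 0.0015, ch, "dermal"), 0.0169, tolerance = 5e-3)
  expect_equal(hq("Ni", 0.002, ch, "dermal"), 2.11e-4, tolerance = 5e-3)
  expect_error(hazard_quotient(1, 0), "positive")
  expect_equal(hazard_index(numeric(0)), 0)
})

test_that("risk quantities are linear in concentration", {
  ad <- exposure_profile("adult")
  expect_equal(cdi_oral(2, ad), 2 * cdi_oral(1, ad))
  expect_equal(cdi_dermal(2, 0.001, ad), 2 * cdi_dermal(1, 0.001, ad))
  expect_equal(hazard_quotient(cdi_oral(2, ad), 0.003),
               2 * hazard_quotient(cdi_oral(1, ad), 0.003))
})

test_that("cancer risk uses the lifetime horizon and sums cumulatively", {
  ad <- exposure_profile("adult")
  expect_equal(cancer_risk(cdi_oral(1, ad, "carcinogenic"), 0), 0)
  cr_cr <- cancer_risk(cdi_oral(0.0015, ad, "carcinogenic"), 0.5)
  expect_equal(signif(cr_cr, 3), 2.26e-5)
  cr_d_cr <- cancer_risk(cdi_dermal(0.0015, 0.002, ad, "carcinogenic"), 500)
  cr_d_pb <- cancer_risk(cdi_dermal(0.002, 0.0001, ad, "carcinogenic"), 500)
  expect_equal(signif(cumulative_cancer_risk(c(cr_d_cr, cr_d_pb)), 3),
               2.29e-4)
  expect_error(cancer_risk(1e-5, NA), "not treated as a carcinogen")
})

test_that("site_risk aggregates the reference worked example", {
  conc <- reference_site_metals()
  ad <- site_risk(conc, exposure_profile("adult"))
  ch <- site_risk(conc, exposure_profile("child"))
  expect_equal(signif(ad$hi[["oral"]], 3), 0.883)
  expect_equal(signif(ch$hi[["oral"]], 3), 3.37)
  # HI equals the sum of per-metal HQs by construction
  expect_equal(ad$hi[["oral"]], sum(ad$per_metal$hq_oral))
  # cumulative CR covers the Cr+Pb carcinogen set by default
  expect_equal(sort(ad$cancer$metal), c("Cr", "Pb"))
  expect_equal(signif(ad$cumulative_cr[["dermal"]], 3), 2.29e-4)
  expect_true(ad$cumulative_cr[["dermal"]] >
                cr_acceptable_band()[["upper"]])
})
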