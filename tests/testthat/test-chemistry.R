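test_that("mg/L to meq/L conversion uses the fixed equivalent weights", {
  s <- make_sample(Ca = 40, Mg = 0, Na = 0, K = 0, HCO3 = 0,
                   Cl = 35.45, SO4 = 0, NO3 = 0)
  eq <- to_equivalents(s)
  expect_equal(eq$Ca, 40 / 20.04)          # 1.996 meq/L
  expect_equal(eq$Cl, 1.0)                 # equivalent-weight identity
  expect_equal(eq$total_cations, 40 / 20.04)
  expect_equal(eq$total_anions, 1.0)

  z <- make_sample(Ca = 0, Mg = 0, Na = 0, K = 0, HCO3 = 0, Cl = 0,
                   SO4 = 0, NO3 = 0)
  eqz <- to_equivalents(z)
  expect_true(all(unlist(eqz) == 0))
})

test_that("conversion is linear and errors on a missing ion", {
  s1 <- make_sample()
  s2 <- s1
  for (ion in major_ions()) s2[[ion]] <- 2 * s2[[ion]]
  expect_equal(unlist(to_equivalents(s2)), 2 * unlist(to_equivalents(s1)))
  s3 <- s1; s3$SO4 <- NULL
  expect_error(to_equivalents(s3), "SO4")
})

test_that("charge balance error matches hand arithmetic and is antisymmetric", {
  # cations 5.0 meq (Ca 100.20 mg/L), anions 4.5 meq (Cl 159.525 mg/L)
  s <- make_sample(Ca = 5 * 20.04, Mg = 0, Na = 0, K = 0, HCO3 = 0,
                   Cl = 4.5 * 35.45, SO4 = 0, NO3 = 0)
  expect_equal(charge_balance_error(s), 100 * 0.5 / 9.5)   # +5.263%
  # swap totals -> sign flips
  s_swapped <- make_sample(Ca = 4.5 * 20.04, Mg = 0, Na = 0, K = 0,
                           HCO3 = 0, Cl = 5 * 35.45, SO4 = 0, NO3 = 0)
  expect_equal(charge_balance_error(s_swapped), -charge_balance_error(s))
  # symmetric case
  s_sym <- make_sample(Ca = 5 * 20.04, Mg = 0, Na = 0, K = 0, HCO3 = 0,
                       Cl = 5 * 35.45, SO4 = 0, NO3 = 0)
  expect_equal(charge_balance_error(s_sym), 0)
  # undefined when everything is zero
  z <- make_sample(Ca = 0, Mg = 0, Na = 0, K = 0, HCO3 = 0, Cl = 0,
                   SO4 = 0, NO3 = 0)
  expect_error(charge_balance_error(z), "undefined")
})

test_that("derived bulk properties match the CaCO3 conversions and are idempotent", {
  s <- make_sample(Ca = 40, Mg = 0, Na = 0, K = 0, HCO3 = 61.02, Cl = 0,
                   SO4 = 0, NO3 = 0)
  d <- derive_bulk_properties(s)
  expect_equal(d$ca_hardness_caco3, 40 * 100.09 / 40.08)  # 99.89 mg/L
  expect_equal(d$alkalinity_caco3, 50.04)
  expect_equal(d$tds, 40 + 61.02)
  expect_equal(d$total_hardness_caco3, (40 / 20.04) * 50.04)
  # idempotent
  expect_equal(derive_bulk_properties(d), d)
  # measured TDS is never overwritten
  s$tds <- 500
  expect_equal(derive_bulk_properties(s)$tds, 500)
  # zero ions give zero bulk properties
  z <- make_sample(Ca = 0, Mg = 0, Na = 0, K = 0, HCO3 = 0, Cl = 0,
                   SO4 = 0, NO3 = 0)
  dz <- derive_bulk_properties(z)
  expect_equal(dz$tds, 0)
  expect_equal(dz$total_hardness_caco3, 0)
})

test_that("sample validation enforces the physical invariants", {
  expect_error(make_sample(Ca = -1), "negative")
  expect_error(make_sample(ph = 15), "pH")
  expect_error(make_sample(temperature = 80), "temperature")
})

test_that("sample I/O round-trips values and below-detection flags", {
  s <- generate_springs(generator_config(seed = 7))
  path <- withr::local_tempfile(fileext = ".csv")
  write_samples(s, path)
  back <- read_samples(path)
  expect_equal(nrow(back), 24)
  for (col in names(s)) expect_equal(back[[col]], s[[col]], tolerance = 1e-12)
  expect_equal(bdl_flags(back)$Pb, bdl_flags(s)$Pb)
  expect_true(all(bdl_flags(back)$Pb))
  # the "<MDL" token parses to the substituted value with the flag set
  line <- "site_id,campaign,Pb\nS1,Feb,<0.002\n"
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(line, path2)
  parsed <- read_samples(path2)
  expect_equal(parsed$Pb, 0.002)
  expect_true(bdl_flags(parsed)$Pb)
})

test_that("reader handles 23-row files, empty files, bad cells and unknown columns", {
  s23 <- generate_springs(generator_config(seed = 3, drop_one = TRUE))
  expect_equal(nrow(s23), 23)
  path <- withr::local_tempfile(fileext = ".csv")
  write_samples(s23, path)
  expect_equal(nrow(read_samples(path)), 23)

  path_empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("site_id,campaign,Ca", path_empty)
  empty <- read_samples(path_empty)
  expect_equal(nrow(empty), 0)

  path_bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("site_id,campaign,Ca\nS1,Feb,oops", path_bad)
  expect_error(read_samples(path_bad), "non-numeric.*line 1")

  path_unknown <- withr::local_tempfile(fileext = ".csv")
  writeLines("site_id,campaign,Ca,flavour\nS1,Feb,40,sweet", path_unknown)
  expect_warning(got <- read_samples(path_unknown), "flavour")
  expect_false("flavour" %in% names(got))

  # a column map renames foreign headers
  path_map <- withr::local_tempfile(fileext = ".csv")
  writeLines("station,season,calcium\nS1,Feb,40", path_map)
  mapped <- read_samples(path_map, column_map = c(station = "site_id",
                                                  season = "campaign",
                                                  calcium = "Ca"))
  expect_equal(mapped$Ca, 40)
})

test_that("long-format export has one row per sample x parameter", {
  s <- make_sample()
  long <- samples_long(s)
  expect_equal(nrow(long), length(intersect(
    c(major_ions(), trace_metals()), names(s))))
  expect_equal(long$value[long$parameter == "Ca"], 60)
})
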