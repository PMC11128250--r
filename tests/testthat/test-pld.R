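test_that("protons-per-MU conversion is a validated ratio", {
  cf <- protons_per_mu(1e-9, 1e-2)
  expect_equal(cf$protons_per_mu, 1e7)
  expect_equal(1e-9 * cf$protons_per_mu, 1e-2)
  expect_equal(protons_per_mu(0.5e-9, 1e-2)$protons_per_mu, 2e7)
  expect_error(protons_per_mu(0, 1e-2), "dose_per_proton")
  expect_error(protons_per_mu(1e-9, -1), "dose_per_mu")
})

test_that("PLD emission writes one element per spot with trimmer fields", {
  pl <- small_plan()
  plu <- small_plan_uncoll()
  cf <- protons_per_mu(1e-9, 1e-2, energy = 78.3)
  f1 <- withr::local_tempfile(fileext = ".pld")
  f2 <- withr::local_tempfile(fileext = ".pld")
  write_pld(pl, cf, f1)
  write_pld(plu, cf, f2)
  lines <- readLines(f1)
  el <- grep("^spot,", lines, value = TRUE)
  expect_length(el, nrow(pl$spots))
  # uncollimated plan: every element ends with four Out tokens
  elu <- grep("^spot,", readLines(f2), value = TRUE)
  expect_true(all(grepl(",Out,Out,Out,Out$", elu)))
  # collimated plan carries real trimmer coordinates on trimmed elements
  expect_true(any(!grepl(",Out,Out,Out,Out$", el)))
  # total MU consistency with the optimized proton weights
  pld <- read_pld(f1)
  expect_equal(sum(pld$elements$mu) * cf$protons_per_mu, sum(pl$weights),
               tolerance = 1e-6)
})

test_that("PLD round trip is byte-identical and strict about its dialect", {
  pl <- small_plan()
  cf <- protons_per_mu(1e-9, 1e-2)
  f1 <- withr::local_tempfile(fileext = ".pld")
  f2 <- withr::local_tempfile(fileext = ".pld")
  write_pld(pl, cf, f1)
  write_pld(read_pld(f1), path = f2)
  expect_identical(readLines(f1), readLines(f2))
  # legacy element line without trimmer fields is a dialect error
  legacy <- c("pld,1", "beam,78.3,5,NRS,reference", "layer,78.3,1",
              "spot,0.000,0.000,1.5")
  f3 <- withr::local_tempfile()
  writeLines(legacy, f3)
  expect_error(read_pld(f3), "dialect")
  bad_mu <- c("pld,1", "beam,78.3,5,NRS,reference", "layer,78.3,1",
              "spot,0.000,0.000,-1.5,Out,Out,Out,Out")
  writeLines(bad_mu, f3)
  expect_error(read_pld(f3), "negative MU")
  writeLines(c("pld,1", "beam,78.3,5,NRS,reference", "layer,78.3,1",
               "nonsense,1,2"), f3)
  expect_error(read_pld(f3), "line 4")
  writeLines(c("not a pld"), f3)
  expect_error(read_pld(f3), "version")
})

test_that("total MU scales linearly with the prescription", {
  tg <- small_target()
  obj5 <- objective_spec(prescription = 5, rind_weight = 0.01)
  obj25 <- objective_spec(prescription = 2.5, rind_weight = 0.01)
  p5 <- dc_plan(tg, beam78(), library = lib78(), objective = obj5, tune = FALSE)
  p25 <- dc_plan(tg, beam78(), library = lib78(), objective = obj25, tune = FALSE)
  expect_equal(sum(p25$weights), sum(p5$weights) / 2, tolerance = 1e-6)
})
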