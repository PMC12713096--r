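test_that("straw inputs match hand arithmetic with the standard coefficients", {
  co <- crop_coefficients()
  # wheat: 1000 * 0.86 * 399/1000
  expect_equal(straw_nutrient(1000, "wheat", "c", co), 1000 * 0.86 * 399 / 1000)
  expect_equal(straw_nutrient(1000, "wheat", "c", co), 343.14)
  # maize: 10000 * 0.86 * 444/1000 = 3818.4
  expect_equal(straw_nutrient(10000, "maize", "c", co), 3818.4)
  expect_equal(straw_nutrient(0, "rice", "c", co), 0)
  # partial incorporation scales linearly
  expect_equal(straw_nutrient(1000, "wheat", "c", co, return_frac = 0.5),
               343.14 / 2)
  expect_error(straw_nutrient(100, "barley", "c", co), "unknown crop")
})

test_that("residue inputs: corrected mode is dimensionally coherent, literal reproduces the printed form", {
  co <- crop_coefficients()
  # wheat, grain 3000, straw 3000:
  # roots (6000 * 0.30 * 0.753) + stubble (3000 * 0.15), then * 0.86 * 399/1000
  hand <- (6000 * 0.30 * 0.753 + 3000 * 0.15) * 0.86 * 399 / 1000
  expect_equal(residue_nutrient(3000, 3000, "wheat", "c", co), hand)
  expect_equal(hand, 619.505316, tolerance = 1e-6)

  lit <- 6000 * 0.30 * 0.753 + 3000 * 0.15 * 0.86 * 399
  expect_equal(residue_nutrient(3000, 3000, "wheat", "c", co, mode = "literal"), lit)
  expect_false(residue_nutrient(3000, 3000, "wheat", "c", co) ==
                 residue_nutrient(3000, 3000, "wheat", "c", co, mode = "literal"))
  expect_equal(residue_nutrient(0, 0, "maize", "c", co), 0)
  expect_equal(residue_nutrient(0, 0, "maize", "c", co, mode = "literal"), 0)
})

test_that("manure inputs follow conc * (1 - water) * weight / 1000", {
  expect_equal(manure_nutrient(1000, 0.7, 300), 90)
  expect_equal(manure_nutrient(0, 0.7, 300), 0)
  expect_equal(manure_nutrient(1000, 1, 300), 0) # pure water
  expect_error(manure_nutrient(1000, 1.2, 300), "\\[0, 1\\]")
})

test_that("mineral N/P split and the P2O5 conversion factor", {
  expect_equal(unname(mineral_np_split(0, 0.6, 0.2)), c(0, 0))
  expect_equal(unname(mineral_np_split(100, 0.6, 0.2)), c(60, 20))
  p <- mineral_np_split(100, 0, 1, p_oxide_basis = TRUE)[["p_mineral"]]
  expect_equal(p, 100 * 61.948 / 141.943, tolerance = 1e-4)
  expect_equal(p, 43.64, tolerance = 1e-3)
})

test_that("annual totals are additive in their components; N/P include mineral terms", {
  rec <- data.frame(
    year = 2000, crop = "maize", grain_kgha = 5000, straw_kgha = 6000,
    straw_return_frac = 0.5, manure_kgha_fresh = 8000, manure_water_frac = 0.7,
    manure_c_gkg = 350, manure_n_gkg = 25, manure_p_gkg = 8,
    mineral_n_kgha = 100, mineral_p_kgha = 0
  )
  ann <- annual_inputs(rec)
  expect_equal(ann$c_input, ann$c_straw + ann$c_residue + ann$c_manure)
  expect_equal(ann$n_input, ann$n_straw + ann$n_residue + ann$n_manure + 100)
  expect_equal(ann$p_input, ann$p_straw + ann$p_residue + ann$p_manure)

  # mineral-only record
  rec0 <- rec
  rec0[c("grain_kgha", "straw_kgha", "manure_kgha_fresh")] <- 0
  ann0 <- annual_inputs(rec0)
  expect_equal(ann0$n_input, 100)
  expect_equal(ann0$c_input, 0)
  expect_equal(ann0$p_input, 0)
})

test_that("cumulative inputs equal brute-force accumulation and are order-invariant", {
  set.seed(31)
  n <- 44
  led <- data.frame(
    year = 1980:2023, crop = sample(c("wheat", "maize", "rice"), n, TRUE),
    grain_kgha = runif(n, 0, 8000), straw_kgha = runif(n, 0, 9000),
    straw_return_frac = runif(n), manure_kgha_fresh = runif(n, 0, 15000),
    manure_water_frac = 0.7, manure_c_gkg = 350, manure_n_gkg = 25,
    manure_p_gkg = 8, mineral_n_kgha = runif(n, 0, 300),
    mineral_p_kgha = runif(n, 0, 50)
  )
  cum <- cumulative_inputs(led)$cumulative
  # independent accumulation: year-by-year loop over single records
  brute <- Reduce(`+`, lapply(seq_len(n), function(i) {
    a <- annual_inputs(led[i, ])
    unlist(a[setdiff(names(a), "year")])
  }))
  expect_equal(cum, brute, tolerance = 1e-9)
  perm <- cumulative_inputs(led[sample(n), ])$cumulative
  expect_equal(perm, cum, tolerance = 1e-9)
  # constant annual C over 44 years -> 44 * c
  led_const <- led
  led_const[c("grain_kgha", "straw_kgha", "manure_kgha_fresh",
              "mineral_n_kgha", "mineral_p_kgha")] <- 0
  led_const$crop <- "wheat"
  led_const$straw_kgha <- 1000
  led_const$straw_return_frac <- 1
  cc <- cumulative_inputs(led_const)$cumulative
  expect_equal(cc[["c_straw"]], 44 * 343.14, tolerance = 1e-9)
})

test_that("scaling all yields scales straw and residue inputs in both modes", {
  co <- crop_coefficients()
  for (mode in c("corrected", "literal")) {
    base <- residue_nutrient(2000, 3000, "rice", "c", co, mode = mode)
    expect_equal(residue_nutrient(2 * 2000, 2 * 3000, "rice", "c", co, mode = mode),
                 2 * base, tolerance = 1e-12)
  }
  expect_equal(straw_nutrient(2 * 1200, "rice", "n", co),
               2 * straw_nutrient(1200, "rice", "n", co), tolerance = 1e-12)
})
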