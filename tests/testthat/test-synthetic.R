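test_that("zero-noise generation evaluates the truth at horizon midpoints", {
  cfg <- synth_config(n_sites = 3, noise_sd = c(soc = 0, tn = 0, tp = 0),
                      modern_noise_factor = 0, seed = 61)
  ds <- generate_dataset(cfg)
  for (s in names(ds$truth)) {
    leg <- ds$profiles[ds$profiles$site_id == s & ds$profiles$era == "legacy", ]
    mids <- (leg$top_cm + leg$bottom_cm) / 2
    for (el in c("soc", "tn", "tp")) {
      expect_equal(leg[[paste0(el, "_gkg")]], ds$truth[[s]][[el]]$f1980(mids),
                   tolerance = 1e-12)
    }
    mod <- ds$profiles[ds$profiles$site_id == s & ds$profiles$era == "modern", ]
    expect_equal(mod$soc_gkg, ds$truth[[s]]$soc$f2023(c(10, 30, 50, 80)),
                 tolerance = 1e-12)
  }
})

test_that("generation is deterministic and stable under site addition", {
  cfg <- synth_config(n_sites = 4, seed = 62)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$profiles, d2$profiles)
  expect_identical(d1$management, d2$management)
  expect_identical(d1$climate, d2$climate)
  # split RNG streams: site 1-4 draws unchanged when sites are added
  d6 <- generate_dataset(synth_config(n_sites = 6, seed = 62))
  expect_identical(d6$profiles[d6$profiles$site_id %in% d1$profiles$site_id, ],
                   d1$profiles)
})

test_that("identity era effect yields zero true change everywhere", {
  eff1 <- list(soc = function(d) rep(1, length(d)),
               tn = function(d) rep(1, length(d)),
               tp = function(d) rep(1, length(d)))
  ds <- generate_dataset(synth_config(n_sites = 3, era_effect = eff1, seed = 63))
  for (s in names(ds$truth)) {
    expect_equal(max(abs(unlist(ds$truth[[s]]$true_change_rel[c("cn", "cp", "np")]))),
                 0, tolerance = 1e-12)
  }
})

test_that("horizon structure respects the count range and tiles 0-100", {
  cfg <- synth_config(n_sites = 10, horizon_count_range = c(4, 4), seed = 64)
  ds <- generate_dataset(cfg)
  for (s in unique(ds$profiles$site_id)) {
    leg <- ds$profiles[ds$profiles$site_id == s & ds$profiles$era == "legacy", ]
    expect_equal(nrow(leg), 4)
    expect_equal(leg$top_cm[1], 0)
    expect_equal(leg$bottom_cm[4], 100)
    expect_equal(leg$top_cm[-1], leg$bottom_cm[-4]) # contiguous
    expect_gte(min(leg$bottom_cm - leg$top_cm), 8)  # minimum thickness
  }
})

test_that("profile pair honors an explicit truth: 20 exp(-0.03 d) at d = 30", {
  tr <- list(
    soc = list(f1980 = function(d) 20 * exp(-0.03 * d),
               f2023 = function(d) 20 * exp(-0.03 * d)),
    tn = list(f1980 = function(d) rep(1, length(d)),
              f2023 = function(d) rep(1, length(d))),
    tp = list(f1980 = function(d) rep(0.6, length(d)),
              f2023 = function(d) rep(0.6, length(d)))
  )
  set.seed(65)
  pair <- generate_profile_pair("X", tr, c(soc = 0, tn = 0, tp = 0),
                                modern_noise_factor = 0)
  mids <- (pair$legacy$top_cm + pair$legacy$bottom_cm) / 2
  expect_equal(pair$legacy$soc_gkg, 20 * exp(-0.03 * mids), tolerance = 1e-12)
  # the documented spot value
  expect_equal(20 * exp(-0.03 * 30), 8.1312, tolerance = 1e-4)
  expect_equal(nrow(pair$modern), 4)
  bad <- tr
  bad$soc$f1980 <- function(d) 5 - 0.1 * d # negative beyond 50 cm
  expect_error(generate_profile_pair("X", bad, c(soc = 0, tn = 0, tp = 0)),
               "non-positive")
})

test_that("the additive noise model has the configured spread", {
  cfg <- synth_config(n_sites = 150, horizon_count_range = c(7, 7),
                      noise_sd = c(soc = 0.5, tn = 0.05, tp = 0.03),
                      site_param_cv = 0, seed = 66)
  ds <- generate_dataset(cfg)
  leg <- ds$profiles[ds$profiles$era == "legacy", ]
  devs <- unlist(lapply(names(ds$truth), function(s) {
    h <- leg[leg$site_id == s, ]
    h$soc_gkg - ds$truth[[s]]$soc$f1980((h$top_cm + h$bottom_cm) / 2)
  }))
  expect_gt(length(devs), 1000)
  expect_gt(sd(devs), 0.45)
  expect_lt(sd(devs), 0.55)
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(n_sites = 0), "n_sites")
  expect_error(synth_config(years = integer(0)), "empty year")
  expect_error(synth_config(noise_sd = c(soc = -1, tn = 0.1, tp = 0.1)),
               "noise_sd")
  expect_error(synth_config(horizon_count_range = c(4, 20)), "infeasible")
  bad_eff <- default_era_effect()
  bad_eff$soc <- function(d) 1 - 0.02 * d
  expect_error(synth_config(era_effect = bad_eff), "must be > 0")
})

test_that("management generator supports the all-zero and deterministic contracts", {
  set.seed(67)
  led0 <- generate_management_series("S1", 1980:2023, yield_scale = 0,
                                     manure_prob = 0, mineral_scale = 0)
  expect_true(all(led0$grain_kgha == 0))
  expect_true(all(led0$manure_kgha_fresh == 0))
  expect_true(all(led0$mineral_n_kgha == 0))
  cum <- cumulative_inputs(led0)$cumulative
  expect_true(all(cum == 0))

  set.seed(68); l1 <- generate_management_series("S1", 1980:2023)
  set.seed(68); l2 <- generate_management_series("S1", 1980:2023)
  expect_identical(l1, l2)
  expect_true(all(l1$grain_kgha >= 0))
  expect_true(all(l1$crop %in% c("wheat", "maize", "rice")))
})

test_that("written datasets round-trip through the CSV schemas", {
  dir <- tempfile("synthds")
  ds <- generate_dataset(synth_config(n_sites = 2, seed = 69))
  write_dataset(ds, dir)
  expect_true(all(file.exists(file.path(
    dir, c("profiles.csv", "management.csv", "climate.csv", "aet.csv",
           "metadata.csv", "truth.json")))))
  prof <- read.csv(file.path(dir, "profiles.csv"))
  expect_equal(nrow(prof), nrow(ds$profiles))
  expect_equal(prof$soc_gkg, ds$profiles$soc_gkg, tolerance = 1e-12)
  tr <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(tr$S001$soc$layer_1980[[1]], ds$truth$S001$soc$layer_1980[1],
               tolerance = 1e-12)
})
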