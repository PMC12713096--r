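#' Default era-effect functions
#'
#' Depth-dependent multiplicative shifts applied to the 1980s truth
#' functions to obtain the 2023 truth. The defaults plant the
#' qualitative pattern reported for intensively managed croplands:
#' strong topsoil carbon enrichment fading to subsoil depletion
#' (C:P about +40% at 10 cm declining to about -25% at 80 cm against a
#' uniform +10% phosphorus accumulation), with a uniform +25% nitrogen
#' accumulation.
#'
#' @return Named list of functions of depth (cm), one per element,
#'   returning a multiplicative factor (> 0 on \[0, 100\]).
#' @export
default_era_effect <- function() {
  list(
    soc = function(d) 1.54 - 0.0102 * (d - 10),
    tn = function(d) rep(1.25, length(d)),
    tp = function(d) rep(1.10, length(d))
  )
}

#' Configuration for the synthetic-data generator
#'
#' Bundles and validates every knob of the generator: number of sites,
#' year range, legacy horizon structure, the per-element 1980s
#' depth-concentration truth functions, the era effect (a depth-dependent
#' multiplicative change field per element), measurement noise, and bulk
#' density bounds. Defaults emulate a temperate-to-subtropical cropland
#' resampling design: exponentially depth-decaying SOC and TN, nearly
#' uniform TP, additive Gaussian laboratory noise, and modern composite
#' samples whose effective noise is reduced by within-site compositing
#' (`modern_noise_factor`, default \eqn{1/\sqrt{21}} for 7 pooled
#' subsamples x 3 replicate plots).
#'
#' @param n_sites Number of sites (>= 1).
#' @param years Inclusive year range of the management/climate ledgers.
#' @param horizon_count_range Integer pair: min/max legacy horizons.
#' @param depth_form Named list: functional form per element.
#' @param truth_params_1980 Named list of `c(a, b)` per element.
#' @param era_effect Named list of positive functions of depth.
#' @param noise_sd Named vector of additive noise SDs (g/kg).
#' @param modern_noise_factor Multiplier on `noise_sd` for modern-era
#'   composite samples.
#' @param bd_range Bulk density bounds (g/cm3).
#' @param site_param_cv Lognormal CV of the per-site jitter on the `a`
#'   truth parameters.
#' @param min_thickness Minimum legacy horizon thickness (cm, default 8
#'   so +/-2 cm boundary perturbations stay well-posed).
#' @param seed Integer RNG seed.
#' @return Validated list of class `synth_config`.
#' @export
synth_config <- function(n_sites = 100,
                         years = 1980:2023,
                         horizon_count_range = c(4, 7),
                         depth_form = list(soc = "exponential",
                                           tn = "exponential",
                                           tp = "linear"),
                         truth_params_1980 = list(soc = c(a = 16, b = -0.025),
                                                  tn = c(a = 1.35, b = -0.02),
                                                  tp = c(a = 0.68, b = -0.0015)),
                         era_effect = default_era_effect(),
                         noise_sd = c(soc = 0.6, tn = 0.06, tp = 0.03),
                         modern_noise_factor = 1 / sqrt(21),
                         bd_range = c(1.1, 1.6),
                         site_param_cv = 0.15,
                         min_thickness = 8,
                         seed = 1) {
  if (length(n_sites) != 1 || n_sites < 1) stop("n_sites must be >= 1")
  if (length(years) < 1) stop("empty year range")
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0")
  stopifnot(length(horizon_count_range) == 2,
            horizon_count_range[1] >= 1,
            horizon_count_range[2] >= horizon_count_range[1])
  if (horizon_count_range[2] * min_thickness > 100) {
    stop("horizon_count_range infeasible for 100 cm with min_thickness ",
         min_thickness)
  }
  stopifnot(length(bd_range) == 2, bd_range[1] > 0, bd_range[2] >= bd_range[1])
  for (el in ELEMENTS) {
    if (!depth_form[[el]] %in% DEPTH_FORMS) {
      stop("unknown depth form for ", el, ": ", depth_form[[el]])
    }
    grid <- seq(1, 100, by = 1)
    if (any(era_effect[[el]](grid) <= 0)) {
      stop("era_effect for ", el, " must be > 0 on [0, 100]")
    }
    f <- .depth_eval(depth_form[[el]], truth_params_1980[[el]]["a"],
                     truth_params_1980[[el]]["b"], grid)
    if (any(f <= 0)) stop("1980s truth for ", el, " non-positive on [0, 100]")
  }
  structure(
    list(n_sites = as.integer(n_sites), years = years,
         horizon_count_range = as.integer(horizon_count_range),
         depth_form = depth_form, truth_params_1980 = truth_params_1980,
         era_effect = era_effect, noise_sd = noise_sd,
         modern_noise_factor = modern_noise_factor, bd_range = bd_range,
         site_param_cv = site_param_cv, min_thickness = min_thickness,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

# Per-site, per-component seeding so adding sites or skipping a component
# never shifts another site's draws. Offsets: 0 truth, 1 profiles,
# 2 management, 3 climate, 4 metadata.
.site_seed <- function(base, site_index, offset) {
  as.integer((base + site_index * 1009L + offset * 97L) %% 2147483647L)
}

# Variable-thickness contiguous horizons tiling [0, 100]: the excess beyond
# k * min_thickness is shared by a uniform stick-break (Dirichlet(1,...,1)).
.draw_horizons <- function(k, min_thickness) {
  excess <- 100 - k * min_thickness
  e <- stats::rexp(k)
  gaps <- min_thickness + excess * e / sum(e)
  bounds <- c(0, cumsum(gaps))
  bounds[k + 1] <- 100 # guard against accumulation error
  data.frame(top_cm = bounds[-(k + 1)], bottom_cm = bounds[-1])
}

#' Generate a paired legacy/modern profile for one site
#'
#' The legacy profile has variable-thickness contiguous genetic horizons
#' spanning 0-100 cm; the modern profile has exactly the four standard
#' layers. Each measured value is the era's truth function evaluated at
#' the horizon or layer midpoint plus additive Gaussian noise, floored at
#' 0.01 g/kg so concentrations stay positive for log/power fits.
#'
#' Draws from the current RNG state; seed management is the caller's
#' responsibility (see [generate_dataset()]).
#'
#' @param site_id Site identifier.
#' @param truth Named list per element with functions `f1980`, `f2023`.
#' @param noise_sd Named noise SD vector (g/kg).
#' @param modern_noise_factor Noise multiplier for the modern composite.
#' @param bd Named list with scalars `legacy`, `modern` (g/cm3).
#' @param horizon_count_range,min_thickness Legacy horizon structure.
#' @return List with data frames `legacy` and `modern` (profiles.csv
#'   schema rows).
#' @export
generate_profile_pair <- function(site_id, truth, noise_sd,
                                  modern_noise_factor = 1 / sqrt(21),
                                  bd = list(legacy = 1.3, modern = 1.35),
                                  horizon_count_range = c(4, 7),
                                  min_thickness = 8) {
  grid <- seq(1, 100, by = 1)
  for (el in ELEMENTS) {
    if (any(truth[[el]]$f1980(grid) <= 0) || any(truth[[el]]$f2023(grid) <= 0)) {
      stop("truth function for ", el, " non-positive on [0, 100]")
    }
  }
  k <- if (horizon_count_range[1] == horizon_count_range[2]) {
    horizon_count_range[1]
  } else {
    sample(horizon_count_range[1]:horizon_count_range[2], 1)
  }
  leg <- .draw_horizons(k, min_thickness)
  leg_mid <- (leg$top_cm + leg$bottom_cm) / 2
  layers <- std_layers()
  legacy <- data.frame(site_id = site_id, era = "legacy", leg,
                       stringsAsFactors = FALSE)
  modern <- data.frame(site_id = site_id, era = "modern",
                       top_cm = layers$top_cm, bottom_cm = layers$bottom_cm,
                       stringsAsFactors = FALSE)
  for (el in ELEMENTS) {
    v_leg <- truth[[el]]$f1980(leg_mid) + stats::rnorm(k, 0, noise_sd[[el]])
    v_mod <- truth[[el]]$f2023(layers$midpoint_cm) +
      stats::rnorm(4, 0, noise_sd[[el]] * modern_noise_factor)
    legacy[[paste0(el, "_gkg")]] <- pmax(v_leg, 0.01)
    modern[[paste0(el, "_gkg")]] <- pmax(v_mod, 0.01)
  }
  legacy$bd_gcm3 <- bd$legacy
  modern$bd_gcm3 <- bd$modern
  list(legacy = legacy, modern = modern)
}

#' Generate a per-site annual management ledger
#'
#' One record per year with a site-constant staple crop (wheat, maize or
#' rice), yields following the secular intensification trend of Chinese
#' croplands (roughly linear growth from 1980 levels with multiplicative
#' noise), a straw-return fraction ramping from 0.15 to 0.85 over the
#' period, intermittent manure applications, and rising mineral N and P
#' rates.
#'
#' @param site_id Site identifier.
#' @param years Year vector.
#' @param yield_scale Multiplier on grain and straw yields (0 disables
#'   crop-derived inputs).
#' @param manure_prob Annual probability of a manure application.
#' @param mineral_scale Multiplier on mineral fertilizer rates.
#' @return Data frame in the management.csv schema.
#' @export
generate_management_series <- function(site_id, years, yield_scale = 1,
                                       manure_prob = 0.6, mineral_scale = 1) {
  crop <- sample(c("wheat", "maize", "rice"), 1)
  base_grain <- c(wheat = 2500, maize = 3500, rice = 4000)[[crop]]
  straw_ratio <- c(wheat = 1.1, maize = 1.2, rice = 0.9)[[crop]]
  ny <- length(years)
  t_rel <- (years - years[1]) / max(1, diff(range(years)))
  grain <- yield_scale * base_grain * (1 + 1.5 * t_rel) *
    exp(stats::rnorm(ny, 0, 0.08))
  straw <- grain * straw_ratio * exp(stats::rnorm(ny, 0, 0.05))
  return_frac <- 0.15 + 0.70 * t_rel
  manure_on <- stats::rbinom(ny, 1, manure_prob)
  manure <- manure_on * stats::runif(ny, 2000, 15000)
  data.frame(
    site_id = site_id, year = years, crop = crop,
    grain_kgha = grain, straw_kgha = straw,
    straw_return_frac = return_frac,
    manure_kgha_fresh = manure, manure_water_frac = 0.70,
    manure_c_gkg = 350, manure_n_gkg = 25, manure_p_gkg = 8,
    mineral_n_kgha = mineral_scale *
      pmax(0, 60 + 160 * t_rel + stats::rnorm(ny, 0, 10)),
    mineral_p_kgha = mineral_scale *
      pmax(0, 8 + 27 * t_rel + stats::rnorm(ny, 0, 3)),
    stringsAsFactors = FALSE
  )
}

#' Generate per-site monthly climate and annual AET series
#'
#' Monthly temperature follows a sinusoidal seasonal cycle (peak in
#' July) around a site-level mean with additive noise; monthly
#' precipitation follows a summer-concentrated sinusoid clamped at zero.
#' Annual AET combines a site baseline with a weak positive trend.
#'
#' @param site_id Site identifier.
#' @param years Year vector.
#' @param base_t,amp_t Site mean temperature and seasonal amplitude
#'   (degrees C); drawn if `NULL`.
#' @param base_p Site mean monthly precipitation (mm); drawn if `NULL`.
#' @param t_noise_sd,p_noise_sd Monthly noise SDs.
#' @return List with data frames `climate` (site_id, year, month,
#'   temp_c, precip_mm) and `aet` (site_id, year, aet_mm).
#' @export
generate_climate_series <- function(site_id, years, base_t = NULL,
                                    amp_t = NULL, base_p = NULL,
                                    t_noise_sd = 1.0, p_noise_sd = 25) {
  if (is.null(base_t)) base_t <- stats::runif(1, 4, 18)
  if (is.null(amp_t)) amp_t <- stats::runif(1, 6, 14)
  if (is.null(base_p)) base_p <- stats::runif(1, 30, 120)
  ny <- length(years)
  grid <- expand.grid(month = 1:12, year = years)
  season <- sin(2 * pi * (grid$month - 4) / 12) # peak in July
  temp <- base_t + amp_t * season + stats::rnorm(nrow(grid), 0, t_noise_sd)
  precip <- pmax(0, base_p * (1 + 0.9 * season) +
                   stats::rnorm(nrow(grid), 0, p_noise_sd))
  climate <- data.frame(site_id = site_id, year = grid$year,
                        month = grid$month, temp_c = temp,
                        precip_mm = precip, stringsAsFactors = FALSE)
  base_aet <- stats::runif(1, 400, 800)
  aet <- data.frame(
    site_id = site_id, year = years,
    aet_mm = base_aet + 0.8 * (years - years[1]) + stats::rnorm(ny, 0, 20),
    stringsAsFactors = FALSE
  )
  list(climate = climate, aet = aet)
}

#' Generate a full synthetic dataset with ground truth
#'
#' Produces, for each site: a legacy genetic-horizon profile and a
#' modern fixed-layer profile (paired eras), an annual management
#' ledger, monthly climate and annual AET series, categorical site
#' metadata, and a ground-truth record holding the generating depth
#' functions of both eras, the true layer-midpoint concentrations, and
#' the true relative change of every molar ratio per layer. RNG streams
#' are split per site and per component, so the output is deterministic
#' given the seed and adding sites does not perturb existing ones.
#'
#' @param config A [synth_config()].
#' @return List of class `synth_dataset`: `profiles`, `management`,
#'   `climate`, `aet`, `metadata` (data frames), `truth` (list), and the
#'   `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  profiles <- list(); management <- list(); climate <- list()
  aet <- list(); metadata <- list(); truth <- list()
  masses <- atomic_masses()
  layers <- std_layers()
  zones <- c("temperate", "warm-temperate", "subtropical")
  orders <- c("Alfisol", "Inceptisol", "Entisol", "Mollisol")
  materials <- c("loess", "alluvium", "residuum", "lacustrine")

  for (i in seq_len(config$n_sites)) {
    sid <- sprintf("S%03d", i)

    set.seed(.site_seed(config$seed, i, 0)) # per-site truth
    tr <- list()
    for (el in ELEMENTS) {
      pars <- config$truth_params_1980[[el]]
      a_site <- pars[["a"]] * exp(stats::rnorm(1, 0, config$site_param_cv))
      form <- config$depth_form[[el]]
      eff <- config$era_effect[[el]]
      f1980 <- local({
        a0 <- a_site; b0 <- pars[["b"]]; fm <- form
        function(d) .depth_eval(fm, a0, b0, d)
      })
      f2023 <- local({
        f0 <- f1980; e0 <- eff
        function(d) f0(d) * e0(d)
      })
      tr[[el]] <- list(
        form = form, a = a_site, b = pars[["b"]],
        f1980 = f1980, f2023 = f2023,
        layer_1980 = f1980(layers$midpoint_cm),
        layer_2023 = f2023(layers$midpoint_cm)
      )
    }
    r80 <- molar_ratios(tr$soc$layer_1980, tr$tn$layer_1980, tr$tp$layer_1980, masses)
    r23 <- molar_ratios(tr$soc$layer_2023, tr$tn$layer_2023, tr$tp$layer_2023, masses)
    tr$true_change_rel <- data.frame(
      layer = layers$layer,
      cn = 100 * (r23$cn / r80$cn - 1),
      cp = 100 * (r23$cp / r80$cp - 1),
      np = 100 * (r23$np / r80$np - 1),
      stringsAsFactors = FALSE
    )
    bd <- list(legacy = stats::runif(1, config$bd_range[1], config$bd_range[2]),
               modern = stats::runif(1, config$bd_range[1], config$bd_range[2]))
    tr$bd <- bd
    truth[[sid]] <- tr

    set.seed(.site_seed(config$seed, i, 1)) # profiles
    pair <- generate_profile_pair(
      sid, tr, config$noise_sd, config$modern_noise_factor, bd,
      config$horizon_count_range, config$min_thickness
    )
    profiles[[sid]] <- rbind(pair$legacy, pair$modern)

    set.seed(.site_seed(config$seed, i, 2)) # management
    management[[sid]] <- generate_management_series(sid, config$years)

    set.seed(.site_seed(config$seed, i, 3)) # climate
    cl <- generate_climate_series(sid, config$years)
    climate[[sid]] <- cl$climate
    aet[[sid]] <- cl$aet

    set.seed(.site_seed(config$seed, i, 4)) # metadata
    metadata[[sid]] <- data.frame(
      site_id = sid,
      latitude = stats::runif(1, 20, 48), longitude = stats::runif(1, 85, 130),
      climate_zone = sample(zones, 1), soil_order = sample(orders, 1),
      parent_material = sample(materials, 1),
      ph = stats::runif(1, 5, 8.5), sand_pct = stats::runif(1, 15, 70),
      clay_pct = stats::runif(1, 8, 40),
      stringsAsFactors = FALSE
    )
  }
  structure(
    list(
      profiles = do.call(rbind, c(profiles, make.row.names = FALSE)),
      management = do.call(rbind, c(management, make.row.names = FALSE)),
      climate = do.call(rbind, c(climate, make.row.names = FALSE)),
      aet = do.call(rbind, c(aet, make.row.names = FALSE)),
      metadata = do.call(rbind, c(metadata, make.row.names = FALSE)),
      truth = truth, config = config
    ),
    class = "synth_dataset"
  )
}

#' Write a synthetic dataset to delimited text files
#'
#' Writes `profiles.csv`, `management.csv`, `climate.csv`, `aet.csv`,
#' `metadata.csv` and `truth.json` (generating parameters and true layer
#' values; the functions themselves are not serialized) into a
#' directory.
#'
#' @param dataset A `synth_dataset` from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("profiles", "management", "climate", "aet", "metadata")) {
    utils::write.csv(dataset[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  truth_ser <- lapply(dataset$truth, function(tr) {
    out <- lapply(ELEMENTS, function(el) {
      t_el <- tr[[el]]
      list(form = t_el$form, a = t_el$a, b = t_el$b,
           layer_1980 = t_el$layer_1980, layer_2023 = t_el$layer_2023)
    })
    names(out) <- ELEMENTS
    out$true_change_rel <- tr$true_change_rel
    out$bd <- tr$bd
    out
  })
  jsonlite::write_json(truth_ser, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
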