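#' Annual climate summary from monthly values
#'
#' Mean annual temperature is the mean of the 12 monthly means. Annual
#' precipitation is likewise reported as the mean of the 12 monthly
#' values by default (`map_mode = "monthly_mean"`); the conventional
#' annual total is available with `map_mode = "annual_total"`.
#'
#' @param temp_c,precip_mm Numeric vectors of exactly 12 monthly values.
#' @param map_mode How to summarize precipitation.
#' @return Named vector `c(mat, map)`.
#' @export
annual_climate <- function(temp_c, precip_mm,
                           map_mode = c("monthly_mean", "annual_total")) {
  map_mode <- match.arg(map_mode)
  if (length(temp_c) != 12 || length(precip_mm) != 12) {
    stop("exactly 12 monthly values required per variable")
  }
  map <- if (map_mode == "monthly_mean") mean(precip_mm) else sum(precip_mm)
  c(mat = mean(temp_c), map = map)
}

#' Accumulated temperature and precipitation over a year range
#'
#' \eqn{AT = \sum_i MAT_i} and \eqn{AP = \sum_i MAP_i} over the study
#' years, quantifying cumulative climatic exposure. (`literal_ap = TRUE`
#' reproduces, for audit, the variant in which the temperature series is
#' summed for both quantities.)
#'
#' @param mat_by_year,map_by_year Annual MAT and MAP vectors (same length).
#' @param literal_ap Sum MAT for AP as well (audit mode; default `FALSE`).
#' @return Named vector `c(at, ap)`.
#' @export
accumulated_climate <- function(mat_by_year, map_by_year, literal_ap = FALSE) {
  if (length(mat_by_year) < 1) stop("at least one year required")
  stopifnot(length(mat_by_year) == length(map_by_year))
  c(at = sum(mat_by_year), ap = sum(if (literal_ap) mat_by_year else map_by_year))
}

#' Temperature and precipitation seasonality (Bio4 / Bio15)
#'
#' Temperature seasonality is the sample standard deviation of the 12
#' monthly mean temperatures multiplied by 100 (bioclimatic variable
#' Bio4). Precipitation seasonality is the coefficient of variation of
#' monthly precipitation in percent (Bio15). A zero mean precipitation
#' leaves Bio15 undefined (returned as `NA` with a warning).
#'
#' @param temp_clim,precip_clim Monthly climatology: 12 mean values each.
#' @return Named vector `c(t_season, p_season)`.
#' @export
seasonality <- function(temp_clim, precip_clim) {
  if (length(temp_clim) != 12 || length(precip_clim) != 12) {
    stop("monthly climatology must have 12 values per variable")
  }
  t_season <- stats::sd(temp_clim) * 100
  pm <- mean(precip_clim)
  if (pm == 0) {
    warning("zero mean precipitation: Bio15 undefined")
    p_season <- NA_real_
  } else {
    p_season <- 100 * stats::sd(precip_clim) / pm
  }
  c(t_season = t_season, p_season = p_season)
}

#' Relative change in actual evapotranspiration
#'
#' Percent change of mean annual AET from a baseline window to a recent
#' window: \eqn{100 (\bar{AET}_{recent} - \bar{AET}_{base}) /
#' \bar{AET}_{base}}. Defaults compare 1981-1985 with 2019-2023.
#'
#' @param aet Data frame with columns `year` and `aet_mm` (or a named
#'   numeric vector with years as names).
#' @param baseline,recent Year vectors of the two windows.
#' @return Percent change (scalar).
#' @export
aet_relative_change <- function(aet, baseline = 1981:1985,
                                recent = 2019:2023) {
  if (is.data.frame(aet)) {
    years <- aet$year
    vals <- aet$aet_mm
  } else {
    years <- as.integer(names(aet))
    vals <- as.numeric(aet)
  }
  if (!all(baseline %in% years) || !all(recent %in% years)) {
    stop("AET series missing years of the comparison windows")
  }
  m0 <- mean(vals[years %in% baseline])
  m1 <- mean(vals[years %in% recent])
  100 * (m1 - m0) / m0
}

#' Per-site climate summary table
#'
#' Collapses monthly temperature/precipitation series and annual AET
#' series into the per-site climate covariates used by the driver
#' analysis: accumulated temperature (AT) and precipitation (AP),
#' temperature and precipitation seasonality of the long-term monthly
#' climatology (Bio4/Bio15), and the relative AET change.
#'
#' @param climate Data frame with `site_id`, `year`, `month`, `temp_c`,
#'   `precip_mm`.
#' @param aet Data frame with `site_id`, `year`, `aet_mm`.
#' @param map_mode Passed to [annual_climate()].
#' @param baseline,recent AET comparison windows.
#' @return Data frame with one row per site: `site_id`, `at`, `ap`,
#'   `t_season`, `p_season`, `daet_pct`.
#' @export
climate_summary <- function(climate, aet, map_mode = "monthly_mean",
                            baseline = 1981:1985, recent = 2019:2023) {
  sites <- unique(climate$site_id)
  rows <- lapply(sites, function(s) {
    cl <- climate[climate$site_id == s, , drop = FALSE]
    yrs <- sort(unique(cl$year))
    ann <- t(vapply(yrs, function(y) {
      m <- cl[cl$year == y, , drop = FALSE]
      m <- m[order(m$month), , drop = FALSE]
      annual_climate(m$temp_c, m$precip_mm, map_mode)
    }, c(mat = 0, map = 0)))
    acc <- accumulated_climate(ann[, "mat"], ann[, "map"])
    clim <- vapply(1:12, function(mo) {
      c(mean(cl$temp_c[cl$month == mo]), mean(cl$precip_mm[cl$month == mo]))
    }, c(0, 0))
    seas <- seasonality(clim[1, ], clim[2, ])
    daet <- aet_relative_change(aet[aet$site_id == s, , drop = FALSE],
                                baseline, recent)
    data.frame(site_id = s, at = acc[["at"]], ap = acc[["ap"]],
               t_season = seas[["t_season"]], p_season = seas[["p_season"]],
               daet_pct = daet, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
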