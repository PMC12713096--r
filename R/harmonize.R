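# Fit -> select for one element of one legacy profile, honouring the
# minimum-n fallbacks: n == 2 forces the linear form, n == 1 falls back to a
# constant (zero-slope linear) extrapolation with a warning flag.
.fit_select_element <- function(horizons, element) {
  col <- paste0(element, "_gkg")
  ok <- is.finite(horizons[[col]]) & horizons[[col]] > 0
  n <- sum(ok)
  if (n == 0) return(NULL)
  if (n == 1) {
    h <- horizons[ok, , drop = FALSE]
    d <- (h$top_cm + h$bottom_cm) / 2
    fit <- structure(
      list(
        form = "linear", a = h[[col]], b = 0, r2 = NA_real_,
        fitted = h[[col]], residuals = 0, midpoints = d,
        observed = h[[col]], n = 1L, degenerate = TRUE, element = element,
        fallback = "constant"
      ),
      class = "depth_model_fit"
    )
    return(fit)
  }
  forms <- if (n == 2) "linear" else DEPTH_FORMS
  fits <- fit_depth_models(horizons, element, forms = forms)
  fit <- select_best_model(fits)
  if (n == 2) fit$fallback <- "linear"
  fit
}

#' Harmonize a soil profile to the standardized depth layers
#'
#' Converts a legacy genetic-horizon profile to the four standardized
#' depth intervals: for each element, the candidate depth-concentration
#' models are fitted, the best (highest original-scale \eqn{R^2}) is
#' selected, and the chosen function is evaluated at the layer midpoints.
#' Modern-era profiles, already measured at the standardized layers, pass
#' through unchanged (their `form` is reported as `"measured"`).
#'
#' Profiles with exactly two usable horizons for an element fall back to
#' the linear form; a single horizon yields constant extrapolation. Both
#' fallbacks are flagged in the output. An element missing from all
#' horizons is skipped; the remaining elements proceed.
#'
#' @param profile Data frame of one profile's horizons with columns
#'   `top_cm`, `bottom_cm`, `soc_gkg`, `tn_gkg`, `tp_gkg` and optionally
#'   `site_id`, `era`, `bd_gcm3`.
#' @param era `"legacy"` (fit and predict) or `"modern"` (pass-through).
#'   Defaults to the profile's `era` column if present, else `"legacy"`.
#' @param elements Elements to harmonize.
#' @param floor Concentration floor in g/kg passed to
#'   [predict_layer_concentrations()].
#' @return A data frame with one row per layer x element: `site_id`,
#'   `era`, `layer`, `midpoint_cm`, `element`, `value_gkg`, `form`, `r2`,
#'   `clamped`, `fallback`. Selected fits are attached as attribute
#'   `"fits"` (a named list, legacy era only).
#' @export
harmonize_profile <- function(profile, era = NULL,
                              elements = ELEMENTS, floor = 0.01) {
  if (is.null(era)) {
    era <- if ("era" %in% names(profile)) as.character(profile$era[1]) else "legacy"
  }
  site_id <- if ("site_id" %in% names(profile)) profile$site_id[1] else NA
  layers <- std_layers()

  if (era == "modern") {
    # already on the standard layers: pass measured values through
    m <- profile[order(profile$top_cm), , drop = FALSE]
    if (nrow(m) != 4 || any(m$top_cm != layers$top_cm) ||
        any(m$bottom_cm != layers$bottom_cm)) {
      stop("modern profile must consist of exactly the four standard layers")
    }
    out <- do.call(rbind, lapply(elements, function(el) {
      data.frame(
        site_id = site_id, era = era, layer = layers$layer,
        midpoint_cm = layers$midpoint_cm, element = el,
        value_gkg = m[[paste0(el, "_gkg")]], form = "measured",
        r2 = NA_real_, clamped = FALSE, fallback = NA_character_,
        stringsAsFactors = FALSE
      )
    }))
    rownames(out) <- NULL
    return(out)
  }

  fits <- list()
  rows <- list()
  for (el in elements) {
    col <- paste0(el, "_gkg")
    if (!col %in% names(profile)) next
    fit <- .fit_select_element(profile, el)
    if (is.null(fit)) next # element absent everywhere
    fits[[el]] <- fit
    pred <- predict_layer_concentrations(fit, floor = floor)
    rows[[el]] <- data.frame(
      site_id = site_id, era = era, layer = pred$layer,
      midpoint_cm = pred$midpoint_cm, element = el,
      value_gkg = pred$value_gkg, form = fit$form, r2 = fit$r2,
      clamped = pred$clamped,
      fallback = if (is.null(fit$fallback)) NA_character_ else fit$fallback,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}

#' Harmonize a table of profiles from both eras
#'
#' Applies [harmonize_profile()] to every `site_id` x `era` combination of
#' a long profile table (the `profiles.csv` schema).
#'
#' @param profiles Data frame with columns `site_id`, `era`, `top_cm`,
#'   `bottom_cm`, `soc_gkg`, `tn_gkg`, `tp_gkg`, `bd_gcm3`.
#' @inheritParams harmonize_profile
#' @return A data frame stacking the per-profile harmonized tables.
#' @export
harmonize_profiles <- function(profiles, elements = ELEMENTS, floor = 0.01) {
  keys <- unique(profiles[c("site_id", "era")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    p <- profiles[profiles$site_id == keys$site_id[i] &
                    profiles$era == keys$era[i], , drop = FALSE]
    harmonize_profile(p, elements = elements, floor = floor)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
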