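#' Atomic masses for molar conversion
#'
#' IUPAC standard atomic weights by default; integer masses (12/14/31)
#' can be supplied for exact-arithmetic checks.
#'
#' @param mC,mN,mP Atomic masses of C, N, P in g/mol.
#' @return Named numeric vector `c(mC, mN, mP)`.
#' @export
atomic_masses <- function(mC = 12.011, mN = 14.007, mP = 30.974) {
  stopifnot(mC > 0, mN > 0, mP > 0)
  c(mC = mC, mN = mN, mP = mP)
}

#' Molar C:N, C:P and N:P ratios
#'
#' Converts mass concentrations (g/kg) of soil organic carbon, total
#' nitrogen and total phosphorus to molar element ratios:
#' \eqn{C\!:\!N = (SOC/m_C)/(TN/m_N)} and analogously for C:P and N:P.
#' The identity \eqn{C\!:\!P = C\!:\!N \times N\!:\!P} holds by
#' construction.
#'
#' @param soc_gkg,tn_gkg,tp_gkg Concentrations in g/kg; vectors recycle.
#' @param masses Atomic masses, see [atomic_masses()].
#' @return Data frame with columns `cn`, `cp`, `np`.
#' @export
molar_ratios <- function(soc_gkg, tn_gkg, tp_gkg, masses = atomic_masses()) {
  if (any(soc_gkg <= 0 | tn_gkg <= 0 | tp_gkg <= 0, na.rm = TRUE)) {
    stop("molar ratios undefined: all concentrations must be > 0")
  }
  c_mol <- soc_gkg / masses[["mC"]]
  n_mol <- tn_gkg / masses[["mN"]]
  p_mol <- tp_gkg / masses[["mP"]]
  data.frame(cn = c_mol / n_mol, cp = c_mol / p_mol, np = n_mol / p_mol)
}

#' Absolute and relative change between two stoichiometric records
#'
#' Absolute change is the plain difference (modern minus baseline);
#' relative change is the proportional difference against the baseline,
#' \eqn{(X_{modern} - X_{baseline})/X_{baseline} \times 100}, in percent.
#' Delta-named quantities throughout the package denote relative changes.
#'
#' @param r_baseline,r_modern Data frames with columns `cn`, `cp`, `np`
#'   (e.g. from [molar_ratios()]); rows are matched positionally.
#' @return Data frame with columns `<ratio>_abs` and `<ratio>_rel` for
#'   each of `cn`, `cp`, `np`.
#' @export
change_record <- function(r_baseline, r_modern) {
  out <- list()
  for (r in c("cn", "cp", "np")) {
    out[[paste0(r, "_abs")]] <- r_modern[[r]] - r_baseline[[r]]
    out[[paste0(r, "_rel")]] <- 100 * (r_modern[[r]] - r_baseline[[r]]) / r_baseline[[r]]
  }
  as.data.frame(out)
}

#' Element stock of a soil layer
#'
#' \eqn{stock = conc \times BD \times thickness \times 0.1} converts
#' g/kg, g/cm3 and cm to Mg/ha.
#'
#' @param conc_gkg Concentration (g/kg).
#' @param bd_gcm3 Bulk density (g/cm3).
#' @param thickness_cm Layer thickness (cm).
#' @return Stock in Mg/ha.
#' @export
layer_stock <- function(conc_gkg, bd_gcm3, thickness_cm) {
  stopifnot(all(conc_gkg >= 0), all(bd_gcm3 >= 0), all(thickness_cm >= 0))
  conc_gkg * bd_gcm3 * thickness_cm * 0.1
}

# Cumulative soil-mass (Mg/ha) and element-mass (Mg/ha) curves at layer
# boundaries, from a per-layer table.
.cumulative_curves <- function(layers, element) {
  l <- layers[order(layers$top_cm), , drop = FALSE]
  thick <- l$bottom_cm - l$top_cm
  soil <- cumsum(l$bd_gcm3 * thick * 100) # Mg/ha per cm of BD 1: 100
  elem <- cumsum(layer_stock(l[[paste0(element, "_gkg")]], l$bd_gcm3, thick))
  list(depth = c(l$top_cm[1], l$bottom_cm),
       soil = c(0, soil), elem = c(0, elem))
}

# Linear interpolation with linear extrapolation from the end segments.
.interp_extrap <- function(x, y, xout) {
  n <- length(x)
  out <- stats::approx(x, y, xout = xout, rule = 2)$y
  lo <- xout < x[1]
  hi <- xout > x[n]
  if (any(lo)) out[lo] <- y[1] + (xout[lo] - x[1]) * (y[2] - y[1]) / (x[2] - x[1])
  if (any(hi)) out[hi] <- y[n] + (xout[hi] - x[n]) * (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  out
}

#' Equivalent-soil-mass comparison of element stocks
#'
#' Fixed-depth (FD) comparisons of element stocks between eras are
#' confounded by bulk-density change: the same depth interval holds
#' different soil masses. The equivalent soil mass (ESM) method compares
#' element masses at equal cumulative soil mass instead. Cumulative soil
#' mass and cumulative element mass are accumulated over the standardized
#' layers (piecewise linear in depth); the non-reference era's cumulative
#' element mass is then evaluated at the reference era's layer-boundary
#' soil masses by monotone linear interpolation (linearly extrapolated
#' beyond the profile).
#'
#' When bulk density is identical in both eras the ESM layer masses equal
#' the FD layer masses exactly.
#'
#' @param legacy,modern Per-layer tables with columns `top_cm`,
#'   `bottom_cm`, `bd_gcm3` and `<element>_gkg` for each element.
#' @param elements Elements to adjust.
#' @param reference Which era's cumulative soil masses define the common
#'   basis: `"legacy"` (default), `"modern"`, or `"lighter"` (the era with
#'   the smaller total 0-100 cm soil mass).
#' @return Data frame with columns `layer`, `element`, `era`,
#'   `mass_fd_mgha` (fixed-depth layer mass) and `mass_esm_mgha` (layer
#'   mass on the common soil-mass basis).
#' @export
esm_adjust <- function(legacy, modern, elements = ELEMENTS,
                       reference = c("legacy", "modern", "lighter")) {
  reference <- match.arg(reference)
  eras <- list(legacy = legacy, modern = modern)
  lg <- legacy[order(legacy$top_cm), , drop = FALSE]
  md <- modern[order(modern$top_cm), , drop = FALSE]
  if (nrow(lg) != nrow(md) || any(lg$top_cm != md$top_cm) ||
      any(lg$bottom_cm != md$bottom_cm)) {
    stop("both eras must share the same fixed-depth layer scheme")
  }
  labels <- paste0(lg$top_cm, "-", lg$bottom_cm)
  out <- list()
  for (el in elements) {
    curves <- lapply(eras, .cumulative_curves, element = el)
    for (cv in curves) {
      if (any(diff(cv$soil) <= 0)) stop("cumulative soil mass must be strictly increasing")
    }
    ref <- switch(reference,
      legacy = "legacy", modern = "modern",
      lighter = names(which.min(vapply(curves, function(cv) max(cv$soil), 1)))
    )
    ref_mass <- curves[[ref]]$soil
    for (era in names(eras)) {
      cv <- curves[[era]]
      cum_esm <- .interp_extrap(cv$soil, cv$elem, ref_mass)
      out[[paste(el, era)]] <- data.frame(
        layer = labels, element = el, era = era,
        mass_fd_mgha = diff(cv$elem), mass_esm_mgha = diff(cum_esm),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Whole-profile stoichiometric aggregation
#'
#' Collapses the four standardized layers into one profile-level
#' stoichiometric record. The default pools element masses
#' (concentration x BD x thickness) over the layers and forms molar
#' ratios of the pooled masses; `thickness_weighted` averages
#' concentrations weighted by thickness only, and `mean_of_layers`
#' averages the per-layer molar ratios.
#'
#' @param layers Per-layer table with `top_cm`, `bottom_cm`, `bd_gcm3`,
#'   `soc_gkg`, `tn_gkg`, `tp_gkg` (all four layers present).
#' @param mode Aggregation rule.
#' @param masses Atomic masses.
#' @return One-row data frame with `cn`, `cp`, `np`.
#' @export
profile_aggregate <- function(layers,
                              mode = c("mass_weighted", "thickness_weighted",
                                       "mean_of_layers"),
                              masses = atomic_masses()) {
  mode <- match.arg(mode)
  if (nrow(layers) != 4) stop("all four standard layers required")
  thick <- layers$bottom_cm - layers$top_cm
  if (mode == "mean_of_layers") {
    r <- molar_ratios(layers$soc_gkg, layers$tn_gkg, layers$tp_gkg, masses)
    return(data.frame(cn = mean(r$cn), cp = mean(r$cp), np = mean(r$np)))
  }
  w <- if (mode == "mass_weighted") layers$bd_gcm3 * thick else thick
  molar_ratios(
    sum(layers$soc_gkg * w), sum(layers$tn_gkg * w), sum(layers$tp_gkg * w),
    masses
  )
}
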