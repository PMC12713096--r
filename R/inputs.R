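#' Crop coefficient table for input accounting
#'
#' National-mean coefficients used to convert yields to element inputs:
#' straw moisture content `W` (fraction), straw C concentration `Cs`
#' (g/kg dry matter; 399, 444 and 418 for wheat, maize and rice),
#' root-to-aboveground biomass ratio `Rr` (0.30, 0.26, 0.30), topsoil
#' root fraction `Rb` (0.753 wheat, 0.851 maize; not available for rice,
#' default 1.0 and configurable), and stubble-to-straw ratio `Sr` (0.15,
#' 0.03, 0.056). Straw N and P concentrations (`Ns`, `Ps`) are not fixed
#' by a national standard; the defaults here are literature-typical
#' values and should be overridden when site-specific data exist.
#'
#' @param W Straw moisture fraction (default 0.14 for all crops).
#' @param Cs,Ns,Ps Straw element concentrations (g/kg dry matter), named
#'   or positional by crop (wheat, maize, rice).
#' @param Rr Root biomass : aboveground biomass ratio.
#' @param Rb Fraction of root biomass in the top 20 cm.
#' @param Sr Stubble : straw biomass ratio.
#' @return Data frame with one row per crop, class `crop_coefficients`.
#' @export
crop_coefficients <- function(W = 0.14,
                              Cs = c(wheat = 399, maize = 444, rice = 418),
                              Ns = c(wheat = 6.5, maize = 9.2, rice = 9.1),
                              Ps = c(wheat = 0.8, maize = 1.5, rice = 1.3),
                              Rr = c(wheat = 0.30, maize = 0.26, rice = 0.30),
                              Rb = c(wheat = 0.753, maize = 0.851, rice = 1.0),
                              Sr = c(wheat = 0.15, maize = 0.03, rice = 0.056)) {
  crops <- c("wheat", "maize", "rice")
  tab <- data.frame(
    crop = crops, W = rep_len(W, 3),
    Cs = unname(Cs[crops]), Ns = unname(Ns[crops]), Ps = unname(Ps[crops]),
    Rr = unname(Rr[crops]), Rb = unname(Rb[crops]), Sr = unname(Sr[crops]),
    stringsAsFactors = FALSE
  )
  stopifnot(all(tab$W >= 0 & tab$W <= 1), all(tab$Rr >= 0 & tab$Rr <= 1),
            all(tab$Rb >= 0 & tab$Rb <= 1), all(tab$Sr >= 0),
            all(tab$Cs > 0), all(tab$Ns > 0), all(tab$Ps > 0))
  class(tab) <- c("crop_coefficients", "data.frame")
  tab
}

.coef_lookup <- function(crop, coeffs) {
  i <- match(crop, coeffs$crop)
  if (anyNA(i)) stop("unknown crop: ", paste(unique(crop[is.na(i)]), collapse = ", "))
  i
}

.straw_conc <- function(coeffs, i, element) {
  switch(element, c = coeffs$Cs[i], n = coeffs$Ns[i], p = coeffs$Ps[i],
         stop("element must be one of c, n, p"))
}

#' Element input from incorporated straw
#'
#' \eqn{X_{straw} = Y_{straw} \times f_{return} \times (1 - W) \times
#' X_s / 1000} where \eqn{Y_{straw}} is fresh straw yield (kg/ha), `W`
#' the moisture fraction and \eqn{X_s} the straw element concentration
#' (g/kg dry matter). Result in kg/ha of the element.
#'
#' @param y_straw Straw yield (kg/ha).
#' @param crop Crop label(s): `"wheat"`, `"maize"`, `"rice"`.
#' @param element `"c"`, `"n"` or `"p"`.
#' @param coeffs Coefficient table from [crop_coefficients()].
#' @param return_frac Fraction of straw incorporated (default 1).
#' @return Input in kg/ha.
#' @export
straw_nutrient <- function(y_straw, crop, element = "c",
                           coeffs = crop_coefficients(), return_frac = 1) {
  element <- match.arg(element, c("c", "n", "p"))
  i <- .coef_lookup(crop, coeffs)
  y_straw * return_frac * (1 - coeffs$W[i]) * .straw_conc(coeffs, i, element) / 1000
}

#' Element input from roots and stubble residues
#'
#' Root biomass is estimated from total aboveground biomass
#' \eqn{(Y_{grain} + Y_{straw}) \times R_r}, of which the fraction
#' \eqn{R_b} resides in the topsoil; stubble biomass is
#' \eqn{Y_{straw} \times S_r}. In the default `"corrected"` mode both
#' biomass pools are converted to element input with the moisture and
#' concentration factors, \eqn{[(Y_g + Y_s) R_r R_b + Y_s S_r] (1 - W)
#' X_s / 1000}, keeping the expression dimensionally consistent. The
#' `"literal"` mode evaluates the published form verbatim, in which the
#' root term is raw biomass and the stubble term carries the
#' concentration without the 1/1000 unit conversion; it is provided for
#' audit only.
#'
#' @param y_grain,y_straw Grain and straw yields (kg/ha).
#' @inheritParams straw_nutrient
#' @param mode `"corrected"` (default) or `"literal"`.
#' @return Input in kg/ha (corrected mode).
#' @export
residue_nutrient <- function(y_grain, y_straw, crop, element = "c",
                             coeffs = crop_coefficients(),
                             mode = c("corrected", "literal")) {
  mode <- match.arg(mode)
  element <- match.arg(element, c("c", "n", "p"))
  i <- .coef_lookup(crop, coeffs)
  conc <- .straw_conc(coeffs, i, element)
  root_biomass <- (y_grain + y_straw) * coeffs$Rr[i] * coeffs$Rb[i]
  stubble_biomass <- y_straw * coeffs$Sr[i]
  if (mode == "corrected") {
    (root_biomass + stubble_biomass) * (1 - coeffs$W[i]) * conc / 1000
  } else {
    root_biomass + stubble_biomass * (1 - coeffs$W[i]) * conc
  }
}

#' Element input from applied manure
#'
#' \eqn{X_{manure} = X_m \times (1 - W) \times Weight / 1000} with
#' \eqn{X_m} the element concentration of manure dry matter (g/kg), `W`
#' the water fraction and `Weight` the fresh application rate (kg/ha).
#'
#' @param fresh_kgha Fresh manure weight applied (kg/ha).
#' @param water_frac Water content fraction in \[0, 1\].
#' @param conc_gkg Element concentration of the dry matter (g/kg).
#' @return Input in kg/ha.
#' @export
manure_nutrient <- function(fresh_kgha, water_frac, conc_gkg) {
  if (any(water_frac < 0 | water_frac > 1)) {
    stop("manure water fraction must lie in [0, 1]")
  }
  conc_gkg * (1 - water_frac) * fresh_kgha / 1000
}

#' Split a total mineral fertilizer quantity into N and P
#'
#' When only total mineral fertilizer application is recorded, elemental
#' N and P are estimated from long-run N and P shares of the total.
#' If the P share is reported on the oxide (P2O5) basis, the
#' stoichiometric factor 2P/P2O5 = 61.948/141.945 = 0.4364 converts it to
#' elemental P.
#'
#' @param total_kgha Total mineral fertilizer (kg/ha).
#' @param n_share,p_share Long-run N and P shares of the total.
#' @param p_oxide_basis Is the P share on the P2O5 basis?
#' @return Named vector `c(n_mineral, p_mineral)` in kg/ha.
#' @export
mineral_np_split <- function(total_kgha, n_share, p_share,
                             p_oxide_basis = FALSE) {
  stopifnot(n_share >= 0, p_share >= 0)
  p <- total_kgha * p_share
  if (p_oxide_basis) p <- p * (2 * 30.974) / (2 * 30.974 + 5 * 15.999)
  c(n_mineral = total_kgha * n_share, p_mineral = p)
}

#' Annual C, N and P inputs from a management record
#'
#' Annual C input sums straw, residue and manure terms; annual N and P
#' inputs additionally include mineral fertilizer. Components are
#' retained alongside the totals.
#'
#' @param records Data frame of management years with columns `year`,
#'   `crop`, `grain_kgha`, `straw_kgha`, `straw_return_frac`,
#'   `manure_kgha_fresh`, `manure_water_frac`, `manure_c_gkg`,
#'   `manure_n_gkg`, `manure_p_gkg`, `mineral_n_kgha`, `mineral_p_kgha`.
#' @param coeffs Coefficient table from [crop_coefficients()].
#' @param residue_mode Passed to [residue_nutrient()].
#' @return Data frame with per-year component columns
#'   (`<el>_straw`, `<el>_residue`, `<el>_manure`, `n_mineral`,
#'   `p_mineral`) and totals `c_input`, `n_input`, `p_input` (kg/ha).
#' @export
annual_inputs <- function(records, coeffs = crop_coefficients(),
                          residue_mode = "corrected") {
  out <- data.frame(year = records$year)
  manure_conc <- list(c = records$manure_c_gkg, n = records$manure_n_gkg,
                      p = records$manure_p_gkg)
  for (el in c("c", "n", "p")) {
    straw <- straw_nutrient(records$straw_kgha, records$crop, el, coeffs,
                            return_frac = records$straw_return_frac)
    residue <- residue_nutrient(records$grain_kgha, records$straw_kgha,
                                records$crop, el, coeffs, mode = residue_mode)
    manure <- manure_nutrient(records$manure_kgha_fresh,
                              records$manure_water_frac, manure_conc[[el]])
    out[[paste0(el, "_straw")]] <- straw
    out[[paste0(el, "_residue")]] <- residue
    out[[paste0(el, "_manure")]] <- manure
    total <- straw + residue + manure
    if (el == "n") total <- total + records$mineral_n_kgha
    if (el == "p") total <- total + records$mineral_p_kgha
    out[[paste0(el, "_input")]] <- total
  }
  out$n_mineral <- records$mineral_n_kgha
  out$p_mineral <- records$mineral_p_kgha
  out
}

#' Cumulative inputs over a management ledger
#'
#' Sums the annual per-component and total inputs over all ledger years
#' (the four-decade accumulation when the ledger spans 1980-2023).
#'
#' @inheritParams annual_inputs
#' @return A list with `annual` (the [annual_inputs()] table) and
#'   `cumulative` (named numeric vector of column sums, kg/ha).
#' @export
cumulative_inputs <- function(records, coeffs = crop_coefficients(),
                              residue_mode = "corrected") {
  if (nrow(records) < 1) stop("ledger must contain at least one year")
  ann <- annual_inputs(records, coeffs, residue_mode)
  cum <- colSums(ann[setdiff(names(ann), "year")])
  list(annual = ann, cumulative = cum)
}
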