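# Refit a single form to a matrix of pseudo-responses (n x B) and predict at
# the standard layer midpoints. Vectorized over replicates via one linear
# solve; log-transform forms clamp pseudo-responses at the floor so the
# transform stays defined.
.refit_predict_matrix <- function(form, d, ystar, midpoints, floor) {
  uses_log_c <- form %in% c("exponential", "power")
  Y <- if (uses_log_c) log(pmax(ystar, floor)) else ystar
  X <- .depth_design(d, form)
  beta <- solve(crossprod(X), crossprod(X, Y)) # 2 x B
  Xp <- .depth_design(midpoints, form)
  P <- Xp %*% beta # 4 x B
  if (uses_log_c) P <- exp(P)
  P[P < floor | !is.finite(P)] <- floor
  t(P) # B x 4
}

#' Residual bootstrap of the horizon-to-layer conversion
#'
#' Quantifies the uncertainty introduced by converting a genetic-horizon
#' profile to fixed depth layers. Residuals of the selected
#' depth-concentration regression (original scale) are resampled with
#' replacement, added to the fitted values at the original horizon
#' midpoints, the originally selected functional form is refitted, and the
#' four layer midpoints are re-predicted. The replicate matrix is the
#' sampling distribution of the harmonized layer values.
#'
#' By default residuals are inflated by \eqn{\sqrt{n/(n-2)}} before
#' resampling, correcting the downward bias of raw regression residuals
#' relative to the error standard deviation; without the correction,
#' percentile intervals are systematically narrow at the small horizon
#' counts typical of legacy profiles. Set `scale_residuals = FALSE` for
#' the uncorrected scheme. Optionally the full model selection can be
#' repeated per replicate (`reselect = TRUE`); the default keeps the
#' originally selected form, reading the conversion uncertainty
#' conditional on that choice.
#'
#' @param horizons Legacy profile data frame (columns `top_cm`,
#'   `bottom_cm`, `<element>_gkg`).
#' @param element `"soc"`, `"tn"` or `"tp"`.
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Integer seed; the replicate matrix is deterministic given it.
#' @param floor Concentration floor (g/kg).
#' @param scale_residuals Apply the \eqn{\sqrt{n/(n-p)}} variance
#'   correction (default `TRUE`).
#' @param reselect Re-run model selection within each replicate.
#' @return List with `replicates` (a `B x 4` matrix of layer values,
#'   columns named by layer), `point` (the point-estimate predictions),
#'   `fit` (the selected `depth_model_fit`), `skipped` (`TRUE` with a
#'   warning when fewer than 3 usable horizons make the CI undefined).
#' @export
residual_bootstrap <- function(horizons, element, B = 1000, seed = NULL,
                               floor = 0.01, scale_residuals = TRUE,
                               reselect = FALSE) {
  fit <- .fit_select_element(horizons, element)
  if (is.null(fit)) stop("element ", element, " absent from all horizons")
  layers <- std_layers()
  point <- predict_layer_concentrations(fit, floor = floor)$value_gkg
  names(point) <- layers$layer
  if (fit$n < 3) {
    warning("residual bootstrap skipped: fewer than 3 horizons for ",
            element, " (CI undefined)")
    return(list(replicates = NULL, point = point, fit = fit, skipped = TRUE))
  }
  if (!is.null(seed)) set.seed(seed)
  n <- fit$n
  res <- fit$residuals
  if (scale_residuals) res <- res * sqrt(n / (n - 2))
  idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n)
  R <- matrix(res[idx], nrow = n)
  ystar <- fit$fitted + R

  if (reselect) {
    reps <- matrix(NA_real_, B, 4)
    h <- data.frame(top_cm = fit$midpoints, bottom_cm = fit$midpoints)
    col <- paste0(element, "_gkg")
    for (b in seq_len(B)) {
      h[[col]] <- pmax(ystar[, b], floor)
      f <- select_best_model(fit_depth_models(h, element))
      reps[b, ] <- predict_layer_concentrations(f, floor = floor)$value_gkg
    }
  } else {
    reps <- .refit_predict_matrix(fit$form, fit$midpoints, ystar,
                                  layers$midpoint_cm, floor)
  }
  colnames(reps) <- layers$layer
  list(replicates = reps, point = point, fit = fit, skipped = FALSE)
}

#' Per-replicate stoichiometric changes against fixed modern values
#'
#' For each bootstrap replicate of the legacy layer concentrations, forms
#' the molar C:N, C:P and N:P ratios and the relative change (%) against
#' the fixed modern-era layer values. Only the legacy side carries
#' conversion uncertainty; modern fixed-depth measurements are treated as
#' fixed.
#'
#' @param legacy_reps Named list with elements `soc`, `tn`, `tp`, each a
#'   `B x 4` replicate matrix from [residual_bootstrap()] (same layer
#'   order).
#' @param modern Named list (or data frame) with numeric length-4 vectors
#'   `soc`, `tn`, `tp` of modern layer concentrations (g/kg).
#' @param masses Atomic masses, see [atomic_masses()].
#' @return Named list (`cn`, `cp`, `np`) of `B x 4` matrices of relative
#'   changes (%), plus attribute `"n_excluded"` counting replicates with a
#'   non-positive legacy ratio (excluded as `NA`).
#' @export
site_change_replicates <- function(legacy_reps, modern,
                                   masses = atomic_masses()) {
  stopifnot(all(c("soc", "tn", "tp") %in% names(legacy_reps)),
            all(c("soc", "tn", "tp") %in% names(modern)))
  mod <- molar_ratios(modern$soc, modern$tn, modern$tp, masses)
  B <- nrow(legacy_reps$soc)
  out <- list()
  n_excluded <- 0L
  for (r in c("cn", "cp", "np")) {
    leg <- switch(r,
      cn = (legacy_reps$soc / masses["mC"]) / (legacy_reps$tn / masses["mN"]),
      cp = (legacy_reps$soc / masses["mC"]) / (legacy_reps$tp / masses["mP"]),
      np = (legacy_reps$tn / masses["mN"]) / (legacy_reps$tp / masses["mP"])
    )
    bad <- !is.finite(leg) | leg <= 0
    if (any(bad)) {
      n_excluded <- n_excluded + sum(rowSums(bad) > 0)
      leg[bad] <- NA_real_
    }
    ch <- sweep(1 / leg, 2, mod[[r]], `*`) # modern/legacy per layer
    out[[r]] <- 100 * (ch - 1)
    colnames(out[[r]]) <- colnames(legacy_reps$soc)
  }
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Directional stability of a bootstrap change estimate
#'
#' The percentage of bootstrap replicates whose (cross-site mean) change
#' shares the sign of the point estimate. Replicates exactly at zero count
#' as consistent only with a zero point estimate.
#'
#' @param replicate_means Numeric vector of per-replicate change estimates.
#' @param point_estimate The point estimate of the change.
#' @return A percentage in \[0, 100\].
#' @export
directional_stability <- function(replicate_means, point_estimate) {
  x <- replicate_means[is.finite(replicate_means)]
  if (length(x) == 0) stop("no finite replicates")
  100 * mean(sign(x) == sign(point_estimate))
}

#' Summarize a bootstrap replicate vector
#'
#' Mean, percentile 95% confidence interval and directional stability of a
#' vector of per-replicate change estimates.
#'
#' @inheritParams directional_stability
#' @return List with `mean`, `ci_lo`, `ci_hi`, `dir_stability_pct`, `B`.
#' @export
bootstrap_summary <- function(replicate_means, point_estimate) {
  x <- replicate_means[is.finite(replicate_means)]
  ci <- unname(stats::quantile(x, c(0.025, 0.975), type = 7))
  list(
    mean = mean(x), ci_lo = ci[1], ci_hi = ci[2],
    dir_stability_pct = directional_stability(x, point_estimate),
    B = length(x)
  )
}

# Shift all internal horizon boundaries of a legacy profile by delta_cm,
# keeping the outer 0 and 100 cm boundaries fixed. A shift that would leave a
# horizon thinner than 1 cm is truncated and flagged.
.shift_boundaries <- function(horizons, delta_cm) {
  h <- horizons[order(horizons$top_cm), , drop = FALSE]
  k <- nrow(h)
  if (k < 2) return(list(horizons = h, truncated = FALSE))
  bounds <- c(h$top_cm[1], h$bottom_cm)
  inner <- bounds[-c(1, k + 1)] + delta_cm
  truncated <- FALSE
  all_b <- c(bounds[1], inner, bounds[k + 1])
  for (i in 2:(k + 1)) { # enforce >= 1 cm thickness left to right
    if (all_b[i] < all_b[i - 1] + 1 && i <= k) {
      all_b[i] <- all_b[i - 1] + 1
      truncated <- TRUE
    }
  }
  for (i in k:2) { # and right to left against the fixed bottom
    if (all_b[i] > all_b[i + 1] - 1) {
      all_b[i] <- all_b[i + 1] - 1
      truncated <- TRUE
    }
  }
  h$top_cm <- all_b[-(k + 1)]
  h$bottom_cm <- all_b[-1]
  list(horizons = h, truncated = truncated)
}

#' Sensitivity of harmonized values to horizon-boundary placement
#'
#' Re-runs the fit/select/predict conversion after shifting every internal
#' horizon boundary of a legacy profile systematically by `+delta_cm` and
#' by `-delta_cm` (outer 0 and 100 cm boundaries fixed), recomputing
#' horizon midpoints. The reported `boundary_delta` is the maximum
#' absolute change of the summary statistic over the two scenarios; when a
#' bootstrap CI half-width is supplied, the ratio of the two and a
#' qualitative impact flag (negligible < 0.5, moderate < 1, substantial
#' otherwise) are added.
#'
#' @param horizons Legacy profile data frame.
#' @param element Element to convert.
#' @param delta_cm Boundary shift in cm (default 2).
#' @param statistic Function mapping the 4 predicted layer values to the
#'   quantity whose sensitivity is of interest; default identity (the
#'   layer values themselves).
#' @param half_ci Optional half-width of the corresponding bootstrap 95%
#'   CI, for `boundary_ratio`.
#' @param floor Concentration floor (g/kg).
#' @return List with `boundary_delta` (scalar), `per_scenario` (statistic
#'   under `-delta`, `0`, `+delta`), `boundary_ratio` and `impact_flag`
#'   (when `half_ci` given), `truncated` (any shift truncated to preserve
#'   1 cm thickness).
#' @export
boundary_sensitivity <- function(horizons, element, delta_cm = 2,
                                 statistic = identity, half_ci = NULL,
                                 floor = 0.01) {
  run <- function(h) {
    fit <- .fit_select_element(h, element)
    statistic(predict_layer_concentrations(fit, floor = floor)$value_gkg)
  }
  base <- run(horizons)
  minus <- .shift_boundaries(horizons, -delta_cm)
  plus <- .shift_boundaries(horizons, +delta_cm)
  s_minus <- run(minus$horizons)
  s_plus <- run(plus$horizons)
  delta <- max(abs(s_minus - base), abs(s_plus - base))
  out <- list(
    boundary_delta = delta,
    per_scenario = list(minus = s_minus, base = base, plus = s_plus),
    truncated = minus$truncated || plus$truncated
  )
  if (!is.null(half_ci)) {
    out$boundary_ratio <- if (half_ci > 0) delta / half_ci else Inf
    out$impact_flag <- impact_flag(out$boundary_ratio)
  }
  out
}

#' Qualitative impact flag for a boundary-sensitivity ratio
#'
#' @param boundary_ratio Boundary delta divided by the bootstrap CI
#'   half-width.
#' @return `"negligible"` (< 0.5), `"moderate"` (< 1) or `"substantial"`.
#' @export
impact_flag <- function(boundary_ratio) {
  ifelse(boundary_ratio < 0.5, "negligible",
         ifelse(boundary_ratio < 1, "moderate", "substantial"))
}
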