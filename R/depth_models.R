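#' @keywords internal
"_PACKAGE"

# Standard fixed layers used throughout: 0-20, 20-40, 40-60, 60-100 cm,
# represented by their midpoints.
STD_LAYERS <- data.frame(
  layer = c("0-20", "20-40", "40-60", "60-100"),
  top_cm = c(0, 20, 40, 60),
  bottom_cm = c(20, 40, 60, 100),
  midpoint_cm = c(10, 30, 50, 80),
  stringsAsFactors = FALSE
)

DEPTH_FORMS <- c("linear", "logarithmic", "exponential", "power")
ELEMENTS <- c("soc", "tn", "tp")

#' Standard depth layers
#'
#' The four standardized depth intervals (0-20, 20-40, 40-60, 60-100 cm)
#' with their midpoints (10, 30, 50, 80 cm), at which harmonized
#' concentrations are predicted.
#'
#' @return A data frame with columns `layer`, `top_cm`, `bottom_cm`,
#'   `midpoint_cm`.
#' @export
std_layers <- function() STD_LAYERS

# Design matrix for the (possibly transformed) two-parameter regression of a
# depth-concentration form. Depths must be > 0 for logarithmic/power forms.
.depth_design <- function(d, form) {
  switch(form,
    linear = cbind(1, d),
    logarithmic = cbind(1, log(d)),
    exponential = cbind(1, d),
    power = cbind(1, log(d)),
    stop("unknown form: ", form)
  )
}

# Evaluate a fitted depth function at depths d.
.depth_eval <- function(form, a, b, d) {
  switch(form,
    linear = a + b * d,
    logarithmic = a + b * log(d),
    exponential = a * exp(b * d),
    power = a * d^b,
    stop("unknown form: ", form)
  )
}

# Closed-form two-parameter least squares: y = X beta. Returns c(intercept,
# slope). X is n x 2 with an intercept column.
.ols2 <- function(X, y) {
  xtx <- crossprod(X)
  det <- xtx[1, 1] * xtx[2, 2] - xtx[1, 2]^2
  if (det <= .Machine$double.eps * xtx[1, 1] * xtx[2, 2] || !is.finite(det)) {
    return(NULL) # degenerate design (e.g. all depths equal)
  }
  drop(solve(xtx, crossprod(X, y)))
}

.fit_one_form <- function(d, conc, form) {
  n <- length(d)
  uses_log_c <- form %in% c("exponential", "power")
  uses_log_d <- form %in% c("logarithmic", "power")
  if (uses_log_c && any(conc <= 0)) return(NULL)
  if (uses_log_d && any(d <= 0)) return(NULL)

  y <- if (uses_log_c) log(conc) else conc
  X <- .depth_design(d, form)
  beta <- .ols2(X, y)
  if (is.null(beta)) return(NULL)
  a <- if (uses_log_c) exp(beta[1]) else beta[1]
  b <- beta[2]

  fitted <- .depth_eval(form, a, b, d)
  resid <- conc - fitted
  sse <- sum(resid^2)
  sst <- sum((conc - mean(conc))^2)
  degenerate <- sst == 0
  r2 <- if (degenerate) {
    if (sse <= 1e-24) 1 else -Inf
  } else {
    1 - sse / sst
  }
  structure(
    list(
      form = form, a = unname(a), b = unname(b), r2 = r2,
      fitted = fitted, residuals = resid, midpoints = d, observed = conc,
      n = n, degenerate = degenerate
    ),
    class = "depth_model_fit"
  )
}

#' @export
print.depth_model_fit <- function(x, ...) {
  cat(sprintf(
    "Depth-concentration fit: %s  a = %.6g  b = %.6g  R2 = %.6g  (n = %d)\n",
    x$form, x$a, x$b, x$r2, x$n
  ))
  invisible(x)
}

#' Fit candidate depth-concentration models to horizon data
#'
#' Fits up to four regression forms relating concentration to horizon
#' midpoint depth: linear \eqn{c = a + b d}, logarithmic
#' \eqn{c = a + b \ln d}, exponential \eqn{c = a e^{b d}} and power
#' \eqn{c = a d^b}. The exponential and power forms are fitted by ordinary
#' least squares after log-transforming the concentration (and, for power,
#' the depth), then back-transformed; all four report a coefficient of
#' determination computed on the original concentration scale
#' (\eqn{R^2 = 1 - SSE/SST}) so the forms are directly comparable. Forms
#' whose transform is undefined for the data (non-positive concentrations
#' or depths) are omitted.
#'
#' The measured value of a horizon is taken to represent the concentration
#' at the horizon midpoint, so depths passed here are midpoints
#' \eqn{(top + bottom)/2}.
#'
#' @param horizons Data frame with columns `top_cm`, `bottom_cm` and a
#'   concentration column for `element` (`soc_gkg`, `tn_gkg` or `tp_gkg`).
#' @param element One of `"soc"`, `"tn"`, `"tp"`.
#' @param forms Candidate forms to try; default all four.
#' @return A list of `depth_model_fit` objects (possibly fewer than
#'   `length(forms)`), each with elements `form`, `a`, `b`, `r2`,
#'   `residuals` (original scale), `n`.
#' @export
fit_depth_models <- function(horizons, element,
                             forms = DEPTH_FORMS) {
  element <- match.arg(tolower(element), ELEMENTS)
  forms <- match.arg(forms, DEPTH_FORMS, several.ok = TRUE)
  col <- paste0(element, "_gkg")
  if (!col %in% names(horizons)) stop("column ", col, " not found")
  ok <- is.finite(horizons[[col]]) & horizons[[col]] > 0
  h <- horizons[ok, , drop = FALSE]
  if (nrow(h) < 2) {
    stop("insufficient data: need >= 2 horizons with positive ", element,
         " concentrations, got ", nrow(h))
  }
  d <- (h$top_cm + h$bottom_cm) / 2
  conc <- h[[col]]
  fits <- lapply(forms, function(f) .fit_one_form(d, conc, f))
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (length(fits) == 0) stop("no candidate form could be fitted")
  for (i in seq_along(fits)) fits[[i]]$element <- element
  fits
}

#' Select the best-fitting depth model
#'
#' Returns the fit with the highest coefficient of determination on the
#' original concentration scale. Exact ties are broken by a fixed
#' precedence: linear > logarithmic > exponential > power (simplest and
#' most numerically stable form first).
#'
#' @param fits A list of `depth_model_fit` objects, as from
#'   [fit_depth_models()].
#' @return The selected `depth_model_fit`.
#' @export
select_best_model <- function(fits) {
  if (length(fits) == 0) stop("empty fit list")
  prec <- match(vapply(fits, `[[`, character(1), "form"), DEPTH_FORMS)
  fits <- fits[order(prec)]
  r2 <- vapply(fits, `[[`, numeric(1), "r2")
  fits[[which.max(r2)]] # which.max returns the first maximum -> precedence
}

#' Predict concentrations at standardized layer midpoints
#'
#' Evaluates a fitted depth-concentration function at the midpoints of the
#' four standardized layers (10, 30, 50, 80 cm). Predictions below the
#' concentration floor are clamped to the floor and flagged; molar ratio
#' computation downstream requires strictly positive values.
#'
#' @param fit A `depth_model_fit`.
#' @param floor Minimum admissible concentration in g/kg (default 0.01).
#' @param layers Layer table as returned by [std_layers()].
#' @return A data frame with columns `layer`, `midpoint_cm`, `value_gkg`,
#'   `clamped`.
#' @export
predict_layer_concentrations <- function(fit, floor = 0.01,
                                         layers = std_layers()) {
  v <- .depth_eval(fit$form, fit$a, fit$b, layers$midpoint_cm)
  clamped <- !is.finite(v) | v < floor
  v[clamped] <- floor
  data.frame(
    layer = layers$layer, midpoint_cm = layers$midpoint_cm,
    value_gkg = v, clamped = clamped, stringsAsFactors = FALSE
  )
}
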