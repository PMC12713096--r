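# Profile builders used across test files. All fixtures are generated in
# code; nothing is read from disk.

# Horizons at given boundaries with concentrations from a function of the
# midpoint (plus optional Gaussian noise drawn from the current RNG state).
make_profile <- function(bounds, f, element = "soc", noise_sd = 0,
                         site_id = "T1", era = "legacy", bd = 1.3) {
  mids <- (head(bounds, -1) + tail(bounds, -1)) / 2
  p <- data.frame(site_id = site_id, era = era,
                  top_cm = head(bounds, -1), bottom_cm = tail(bounds, -1),
                  bd_gcm3 = bd, stringsAsFactors = FALSE)
  p[[paste0(element, "_gkg")]] <- f(mids) + rnorm(length(mids), 0, noise_sd)
  p
}

# Full three-element profile from per-element truth functions.
make_profile3 <- function(bounds, fns, noise_sd = c(soc = 0, tn = 0, tp = 0),
                          site_id = "T1", era = "legacy", bd = 1.3) {
  mids <- (head(bounds, -1) + tail(bounds, -1)) / 2
  p <- data.frame(site_id = site_id, era = era,
                  top_cm = head(bounds, -1), bottom_cm = tail(bounds, -1),
                  stringsAsFactors = FALSE)
  for (el in names(fns)) {
    p[[paste0(el, "_gkg")]] <- fns[[el]](mids) +
      rnorm(length(mids), 0, noise_sd[[el]])
  }
  p$bd_gcm3 <- bd
  p
}

# The four candidate depth functions with parameters positive on [0, 100].
candidate_truths <- function() {
  list(
    linear = list(f = function(d) 18 - 0.12 * d, a = 18, b = -0.12),
    logarithmic = list(f = function(d) 25 - 4 * log(d), a = 25, b = -4),
    exponential = list(f = function(d) 20 * exp(-0.03 * d), a = 20, b = -0.03),
    power = list(f = function(d) 30 * d^-0.4, a = 30, b = -0.4)
  )
}

# Independent least-squares oracle built on lm(), kept separate from the
# package's closed-form fitting path.
oracle_fit <- function(d, conc, form) {
  fit <- switch(form,
    linear = lm(conc ~ d),
    logarithmic = lm(conc ~ log(d)),
    exponential = lm(log(conc) ~ d),
    power = lm(log(conc) ~ log(d))
  )
  cf <- unname(coef(fit))
  if (form %in% c("exponential", "power")) cf[1] <- exp(cf[1])
  cf
}
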