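#' Grouped change summaries with ANOVA letters
#'
#' Per-group mean, standard error and n of a change variable, with
#' one-way ANOVA and Tukey HSD compact letters across groups (groups
#' with a single observation are dropped by [layer_anova()]).
#'
#' @param values Numeric change values.
#' @param group Grouping vector (layer, climate zone, soil order, ...).
#' @return List with `summary` (data frame: group, mean, se, n, letter)
#'   and `anova` (the [layer_anova()] result).
#' @export
group_summaries <- function(values, group) {
  group <- as.character(group)
  keep <- is.finite(values)
  values <- values[keep]; group <- group[keep]
  an <- layer_anova(values, group)
  tab <- do.call(rbind, lapply(unique(group), function(g) {
    v <- values[group == g]
    data.frame(group = g, mean = mean(v),
               se = stats::sd(v) / sqrt(length(v)), n = length(v),
               stringsAsFactors = FALSE)
  }))
  tab$letter <- unname(an$letters[tab$group])
  tab <- tab[order(-tab$mean), ]
  rownames(tab) <- NULL
  list(summary = tab, anova = an)
}

# Point-estimate relative changes (%) per site x layer x ratio from a
# harmonized table (both eras). Returns a long data frame.
.point_changes <- function(harmonized, masses = atomic_masses()) {
  wide <- function(era) {
    h <- harmonized[harmonized$era == era, ]
    stats::reshape(h[c("site_id", "layer", "element", "value_gkg")],
                   idvar = c("site_id", "layer"), timevar = "element",
                   direction = "wide")
  }
  leg <- wide("legacy"); mod <- wide("modern")
  names(leg) <- sub("value_gkg\\.", "", names(leg))
  names(mod) <- sub("value_gkg\\.", "", names(mod))
  m <- merge(leg, mod, by = c("site_id", "layer"), suffixes = c("_1980", "_2023"))
  r80 <- molar_ratios(m$soc_1980, m$tn_1980, m$tp_1980, masses)
  r23 <- molar_ratios(m$soc_2023, m$tn_2023, m$tp_2023, masses)
  ch <- change_record(r80, r23)
  cbind(m[c("site_id", "layer")],
        stats::setNames(r80, paste0(names(r80), "_1980")),
        stats::setNames(r23, paste0(names(r23), "_2023")),
        ch)
}

# Cross-site mean relative change per layer x ratio of a harmonized table.
.mean_change_matrix <- function(harmonized, masses = atomic_masses()) {
  pc <- .point_changes(harmonized, masses)
  out <- matrix(NA_real_, 4, 3,
                dimnames = list(std_layers()$layer, c("cn", "cp", "np")))
  for (r in c("cn", "cp", "np")) {
    m <- tapply(pc[[paste0(r, "_rel")]], pc$layer, mean)
    out[, r] <- m[rownames(out)]
  }
  out
}

#' Run the full stoichiometry-change pipeline
#'
#' Orchestrates the stages end to end on a synthetic dataset (or one
#' supplied in the same structure): depth harmonization of legacy
#' profiles, per-site residual bootstrap of the conversion, molar
#' stoichiometry and era changes, equivalent-soil-mass stocks,
#' management-input and climate accounting, boundary-perturbation
#' sensitivity of the cross-site mean changes, grouped summaries, and
#' (optionally) the driver analysis. Fully deterministic given `seed`;
#' per-site bootstrap streams are split so results do not depend on
#' processing order.
#'
#' @param config A [synth_config()] (ignored when `dataset` is given).
#' @param dataset Optional pre-built `synth_dataset`-shaped list.
#' @param B Bootstrap replicates per site per element.
#' @param seed Integer seed for the bootstrap streams.
#' @param boundary_delta Boundary perturbation (cm).
#' @param aggregation Profile aggregation mode, see [profile_aggregate()].
#' @param esm Compute equivalent-soil-mass stocks?
#' @param run_drivers Run the random-forest driver analysis (the slow
#'   stage)?
#' @param response_ratio Ratio whose relative change drives the driver
#'   analysis (`"cp"` default).
#' @param n_trees,n_perm Forest size and permutation count for
#'   [rf_permutation_importance()].
#' @param out_dir Optional directory; when given, stage tables are
#'   written as CSV and the report as `report.json`.
#' @param masses Atomic masses.
#' @return List of class `stoich_report`; key components:
#'   `layer_changes` (per layer x ratio: point mean, bootstrap mean, 95%
#'   CI, directional stability, boundary delta/ratio/flag),
#'   `profile_changes` (whole-profile aggregates), `site_changes` (per
#'   site x layer point estimates), `stocks_esm`, `inputs`, `climate`,
#'   `groups`, `drivers`, `warnings`, `provenance`.
#' @export
run_pipeline <- function(config = synth_config(), dataset = NULL,
                         B = 1000, seed = 1, boundary_delta = 2,
                         aggregation = "mass_weighted", esm = TRUE,
                         run_drivers = FALSE, response_ratio = "cp",
                         n_trees = 500, n_perm = 100,
                         out_dir = NULL, masses = atomic_masses()) {
  if (is.null(dataset)) dataset <- generate_dataset(config)
  profiles <- dataset$profiles
  sites <- unique(profiles$site_id)
  n_sites <- length(sites)
  layers <- std_layers()
  warn <- list(clamped = 0L, fallbacks = 0L, skipped_bootstrap = 0L,
               excluded_replicates = 0L)

  ## 1. harmonization ------------------------------------------------------
  harmonized <- harmonize_profiles(profiles)
  warn$clamped <- sum(harmonized$clamped)
  warn$fallbacks <- sum(!is.na(harmonized$fallback))
  site_changes <- .point_changes(harmonized, masses)
  point_mat <- .mean_change_matrix(harmonized, masses)

  ## 2. per-site residual bootstrap + change replicates ---------------------
  rep_arrays <- lapply(c(cn = "cn", cp = "cp", np = "np"),
                       function(r) array(NA_real_, c(B, 4, n_sites)))
  for (i in seq_along(sites)) {
    s <- sites[i]
    leg <- profiles[profiles$site_id == s & profiles$era == "legacy", ]
    modh <- harmonized[harmonized$site_id == s & harmonized$era == "modern", ]
    modern <- lapply(stats::setNames(ELEMENTS, ELEMENTS), function(el) {
      v <- modh$value_gkg[modh$element == el]
      v[match(layers$layer, modh$layer[modh$element == el])]
    })
    reps <- list()
    ok <- TRUE
    for (j in seq_along(ELEMENTS)) {
      el <- ELEMENTS[j]
      bt <- residual_bootstrap(leg, el, B = B,
                               seed = .site_seed(seed, i, 10L + j))
      if (bt$skipped) { ok <- FALSE; break }
      reps[[el]] <- bt$replicates
    }
    if (!ok) {
      warn$skipped_bootstrap <- warn$skipped_bootstrap + 1L
      next
    }
    ch <- site_change_replicates(reps, modern, masses)
    warn$excluded_replicates <- warn$excluded_replicates +
      attr(ch, "n_excluded")
    for (r in c("cn", "cp", "np")) rep_arrays[[r]][, , i] <- ch[[r]]
  }

  ## 3. cross-site summaries ------------------------------------------------
  layer_changes <- list()
  for (r in c("cn", "cp", "np")) {
    cross <- apply(rep_arrays[[r]], c(1, 2), mean, na.rm = TRUE) # B x 4
    for (l in seq_len(4)) {
      pe <- point_mat[l, r]
      bs <- bootstrap_summary(cross[, l], pe)
      layer_changes[[length(layer_changes) + 1L]] <- data.frame(
        ratio = r, layer = layers$layer[l], point_mean = pe,
        boot_mean = bs$mean, ci_lo = bs$ci_lo, ci_hi = bs$ci_hi,
        dir_stability_pct = bs$dir_stability_pct, B = bs$B,
        stringsAsFactors = FALSE
      )
    }
  }
  layer_changes <- do.call(rbind, layer_changes)

  ## 4. boundary perturbation of the cross-site mean ------------------------
  shift_mean <- function(delta) {
    shifted <- do.call(rbind, lapply(sites, function(s) {
      leg <- profiles[profiles$site_id == s & profiles$era == "legacy", ]
      .shift_boundaries(leg, delta)$horizons
    }))
    shifted$era <- "legacy"
    modern_rows <- profiles[profiles$era == "modern", ]
    .mean_change_matrix(harmonize_profiles(rbind(shifted, modern_rows)), masses)
  }
  m_plus <- shift_mean(boundary_delta)
  m_minus <- shift_mean(-boundary_delta)
  bdelta <- pmax(abs(m_plus - point_mat), abs(m_minus - point_mat))
  half_ci <- (layer_changes$ci_hi - layer_changes$ci_lo) / 2
  layer_changes$boundary_delta <- mapply(function(r, l) bdelta[l, r],
                                         layer_changes$ratio, layer_changes$layer)
  layer_changes$boundary_ratio <- ifelse(half_ci > 0,
                                         layer_changes$boundary_delta / half_ci,
                                         Inf)
  layer_changes$impact_flag <- impact_flag(layer_changes$boundary_ratio)

  ## 5. whole-profile aggregation ------------------------------------------
  bd_tab <- unique(profiles[c("site_id", "era", "bd_gcm3")])
  prof_rows <- lapply(sites, function(s) {
    agg <- lapply(c(legacy = "legacy", modern = "modern"), function(era) {
      h <- harmonized[harmonized$site_id == s & harmonized$era == era, ]
      w <- stats::reshape(h[c("layer", "element", "value_gkg")],
                          idvar = "layer", timevar = "element",
                          direction = "wide")
      names(w) <- sub("value_gkg\\.", "", names(w))
      w <- merge(layers, w, by = "layer")
      w$bd_gcm3 <- bd_tab$bd_gcm3[bd_tab$site_id == s & bd_tab$era == era][1]
      names(w)[names(w) %in% ELEMENTS] <- paste0(
        names(w)[names(w) %in% ELEMENTS], "_gkg")
      profile_aggregate(w, aggregation, masses)
    })
    cbind(data.frame(site_id = s), change_record(agg$legacy, agg$modern),
          stats::setNames(agg$legacy, paste0(names(agg$legacy), "_1980")),
          stats::setNames(agg$modern, paste0(names(agg$modern), "_2023")))
  })
  profile_changes <- do.call(rbind, prof_rows)

  ## 6. ESM stocks ----------------------------------------------------------
  stocks_esm <- NULL
  if (esm) {
    stocks_esm <- do.call(rbind, lapply(sites, function(s) {
      tabs <- lapply(c(legacy = "legacy", modern = "modern"), function(era) {
        h <- harmonized[harmonized$site_id == s & harmonized$era == era, ]
        w <- stats::reshape(h[c("layer", "element", "value_gkg")],
                            idvar = "layer", timevar = "element",
                            direction = "wide")
        names(w) <- sub("value_gkg\\.", "", names(w))
        w <- merge(layers, w, by = "layer")
        w$bd_gcm3 <- bd_tab$bd_gcm3[bd_tab$site_id == s & bd_tab$era == era][1]
        names(w)[names(w) %in% ELEMENTS] <- paste0(
          names(w)[names(w) %in% ELEMENTS], "_gkg")
        w
      })
      cbind(site_id = s, esm_adjust(tabs$legacy, tabs$modern))
    }))
  }

  ## 7. inputs and climate --------------------------------------------------
  inputs <- do.call(rbind, lapply(sites, function(s) {
    led <- dataset$management[dataset$management$site_id == s, ]
    cum <- cumulative_inputs(led)$cumulative
    cbind(data.frame(site_id = s), as.data.frame(as.list(cum)))
  }))
  climate <- climate_summary(dataset$climate, dataset$aet,
                             baseline = dataset$config$years[1:5] + 1,
                             recent = utils::tail(dataset$config$years, 5))

  ## 8. grouped summaries ---------------------------------------------------
  resp_col <- paste0(response_ratio, "_rel")
  site_meta <- merge(site_changes, dataset$metadata, by = "site_id")
  groups <- list(layer = group_summaries(site_meta[[resp_col]], site_meta$layer))
  for (key in c("climate_zone", "soil_order", "parent_material")) {
    top <- site_meta[site_meta$layer == "0-20", ]
    groups[[key]] <- group_summaries(top[[resp_col]], top[[key]])
  }

  ## 9. drivers (optional) --------------------------------------------------
  drivers <- NULL
  if (run_drivers) {
    drivers <- list()
    for (l in layers$layer) {
      tab <- site_changes[site_changes$layer == l, ]
      tab <- merge(tab, inputs[c("site_id", "c_input", "n_input", "p_input")],
                   by = "site_id")
      tab <- merge(tab, climate, by = "site_id")
      tab <- merge(tab, dataset$metadata[c("site_id", "ph", "sand_pct",
                                           "clay_pct")], by = "site_id")
      preds <- c("c_input", "n_input", "p_input", "at", "ap", "daet_pct",
                 "t_season", "p_season", "ph", "sand_pct", "clay_pct",
                 paste0(response_ratio, "_1980"))
      vif <- vif_screen(tab[preds])
      rf <- rf_permutation_importance(
        tab[c(resp_col, vif$retained)], resp_col, vif$retained,
        n_trees = n_trees, n_perm = n_perm,
        seed = .site_seed(seed, match(l, layers$layer), 50L)
      )
      thr <- log_threshold(tab[[paste0(response_ratio, "_1980")]], tab[[resp_col]])
      drivers[[l]] <- list(vif = vif, importance = rf, threshold = thr)
    }
  }

  report <- structure(
    list(layer_changes = layer_changes, profile_changes = profile_changes,
         site_changes = site_changes, stocks_esm = stocks_esm,
         inputs = inputs, climate = climate, groups = groups,
         drivers = drivers, warnings = warn,
         provenance = list(
           seed = seed, B = B, boundary_delta = boundary_delta,
           aggregation = aggregation, n_sites = n_sites,
           generator_seed = dataset$config$seed,
           package_version = as.character(utils::packageVersion("soilstoich"))
         )),
    class = "stoich_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.stoich_report <- function(x, ...) {
  cat("Soil C:N:P stoichiometry change report (", x$provenance$n_sites,
      " sites, B = ", x$provenance$B, ")\n\n", sep = "")
  cat("Cross-site mean relative changes (%) by layer:\n")
  print(x$layer_changes[c("ratio", "layer", "point_mean", "ci_lo", "ci_hi",
                          "dir_stability_pct", "impact_flag")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Persists each tabular stage output as CSV plus a consolidated
#' `report.json` (layer changes, group summaries, warnings tally,
#' provenance).
#'
#' @param report A `stoich_report` from [run_pipeline()].
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("layer_changes", "profile_changes", "site_changes",
               "stocks_esm", "inputs", "climate")) {
    if (!is.null(report[[nm]])) {
      utils::write.csv(report[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
  }
  js <- list(
    layer_changes = report$layer_changes,
    groups = lapply(report$groups, `[[`, "summary"),
    warnings = report$warnings,
    provenance = report$provenance
  )
  jsonlite::write_json(js, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out_dir)
}
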