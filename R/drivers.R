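# VIF of every column of a numeric predictor matrix: VIF_j = 1/(1 - R2_j)
# from regressing column j on the others. Exact collinearity yields Inf.
.vif_all <- function(X) {
  p <- ncol(X)
  vapply(seq_len(p), function(j) {
    y <- X[, j]
    Z <- cbind(1, X[, -j, drop = FALSE])
    fit <- stats::lm.fit(Z, y)
    sst <- sum((y - mean(y))^2)
    if (sst == 0) return(Inf)
    r2 <- 1 - sum(fit$residuals^2) / sst
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Iterative variance-inflation-factor screening
#'
#' Assesses multicollinearity among predictors with the variance
#' inflation factor, \eqn{VIF_j = 1/(1 - R^2_j)} from regressing
#' predictor j on all others, and removes predictors one at a time —
#' always the one with the largest VIF (ties broken by column order;
#' exact collinearity counts as infinite) — until every remaining VIF is
#' at or below the threshold.
#'
#' @param predictors Data frame or matrix of numeric predictors (>= 2
#'   columns, more rows than columns).
#' @param threshold VIF threshold (default 5).
#' @return List of class `vif_report`: `vif_initial`, `removed` (in
#'   removal order), `retained`, `vif_final` (named, all <= threshold).
#' @export
vif_screen <- function(predictors, threshold = 5) {
  X <- as.matrix(predictors)
  if (ncol(X) < 2) stop("need at least 2 predictors")
  if (nrow(X) <= ncol(X)) stop("need more observations than predictors")
  vif0 <- .vif_all(X)
  names(vif0) <- colnames(X)
  removed <- character(0)
  repeat {
    if (ncol(X) < 2) break
    v <- .vif_all(X)
    names(v) <- colnames(X)
    if (all(v <= threshold)) break
    worst <- which.max(v) # first maximum -> column-order tie-break
    removed <- c(removed, colnames(X)[worst])
    X <- X[, -worst, drop = FALSE]
  }
  v_final <- if (ncol(X) >= 2) {
    stats::setNames(.vif_all(X), colnames(X))
  } else {
    stats::setNames(rep(1, ncol(X)), colnames(X))
  }
  structure(
    list(vif_initial = vif0, removed = removed,
         retained = colnames(X), vif_final = v_final,
         threshold = threshold),
    class = "vif_report"
  )
}

#' @export
print.vif_report <- function(x, ...) {
  cat("VIF screening (threshold ", x$threshold, ")\n", sep = "")
  cat("removed:", if (length(x$removed)) paste(x$removed, collapse = ", ")
      else "none", "\n")
  print(round(x$vif_final, 3))
  invisible(x)
}

#' Partial correlation by double residualization
#'
#' Both variables are regressed on the confounders (ordinary least
#' squares with intercept); the partial correlation is the Pearson
#' correlation of the two residual vectors, reflecting the association
#' between x and y once the linear influence of the confounders is
#' removed. With no confounders this reduces exactly to the plain
#' Pearson correlation. The p-value comes from the t statistic
#' \eqn{r\sqrt{(n - 2 - k)/(1 - r^2)}} on \eqn{n - 2 - k} degrees of
#' freedom, k the number of confounders.
#'
#' @param x,y Numeric vectors.
#' @param z Optional confounders: numeric vector, matrix or data frame.
#' @return List of class `partial_cor`: `r_partial`, `p`, `n`, `k`.
#' @export
partial_correlation <- function(x, y, z = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  k <- 0L
  if (!is.null(z)) {
    Z <- as.matrix(z)
    stopifnot(nrow(Z) == n)
    k <- ncol(Z)
    D <- cbind(1, Z)
    x <- stats::lm.fit(D, x)$residuals
    y <- stats::lm.fit(D, y)$residuals
  }
  if (n <= k + 2) stop("need n > k + 2 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant residuals: partial correlation undefined")
    return(structure(list(r_partial = NA_real_, p = NA_real_, n = n, k = k),
                     class = "partial_cor"))
  }
  r <- stats::cor(x, y)
  df <- n - 2 - k
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df)
  structure(list(r_partial = r, p = p, n = n, k = k), class = "partial_cor")
}

#' @export
print.partial_cor <- function(x, ...) {
  cat(sprintf("partial r = %.4f (p = %.4g, n = %d, k = %d confounders)\n",
              x$r_partial, x$p, x$n, x$k))
  invisible(x)
}

#' Random-forest permutation importance with significance testing
#'
#' Fits a regression random forest (500 trees grown to full depth by
#' default) and reports two complementary importance measures per
#' predictor: mean decrease in impurity (MDI) and permutation importance
#' (the increase in out-of-bag MSE when the predictor is shuffled,
#' unscaled). Statistical significance is assessed against a null
#' distribution built by refitting the forest on `n_perm` random
#' permutations of the response; the p-value is
#' \eqn{(1 + \#\{null \ge observed\})/(n_{perm} + 1)} so it is never
#' exactly zero. `perm_scheme = "predictor"` instead permutes each
#' predictor column to build its null.
#'
#' Model quality is summarized by the out-of-bag \eqn{R^2} (percent
#' variance explained), the OOB RMSE, and RMSE normalized by the
#' response range (NRMSE) and by its standard deviation (CV(RMSE)).
#'
#' @param data Data frame containing response and predictors.
#' @param response Name of the numeric response column.
#' @param predictors Predictor column names (default: all others).
#' @param n_trees Trees per forest (default 500).
#' @param n_perm Permutations for the null (default 100).
#' @param seed Integer seed; results deterministic given it.
#' @param perm_scheme `"response"` (default) or `"predictor"`.
#' @return List of class `rf_importance`: `importance` (data frame with
#'   `predictor`, `mdi`, `perm_imp`, `norm_imp` summing to 1, `p_value`),
#'   `metrics` (`oob_r2` in percent, `rmse`, `nrmse_range`, `cv_rmse`),
#'   `forest` (the fitted `randomForest` object).
#' @export
rf_permutation_importance <- function(data, response,
                                      predictors = setdiff(names(data), response),
                                      n_trees = 500, n_perm = 100,
                                      seed = NULL,
                                      perm_scheme = c("response", "predictor")) {
  perm_scheme <- match.arg(perm_scheme)
  y <- data[[response]]
  if (!is.numeric(y)) stop("response must be numeric")
  if (stats::sd(y) == 0) stop("constant response")
  X <- data[predictors]
  n <- length(y)
  if (n < 20) stop("need at least 20 observations")
  if (!is.null(seed)) set.seed(seed)

  rf <- randomForest::randomForest(x = X, y = y, ntree = n_trees,
                                   importance = TRUE)
  imp <- randomForest::importance(rf, scale = FALSE)
  obs_perm <- imp[, "%IncMSE"]
  mdi <- imp[, "IncNodePurity"]

  null_imp <- matrix(NA_real_, n_perm, length(predictors),
                     dimnames = list(NULL, predictors))
  for (b in seq_len(n_perm)) {
    if (perm_scheme == "response") {
      rf_b <- randomForest::randomForest(x = X, y = sample(y),
                                         ntree = n_trees, importance = TRUE)
      null_imp[b, ] <- randomForest::importance(rf_b, scale = FALSE)[, "%IncMSE"]
    } else {
      for (j in seq_along(predictors)) {
        Xp <- X
        Xp[[j]] <- sample(Xp[[j]])
        rf_b <- randomForest::randomForest(x = Xp, y = y, ntree = n_trees,
                                           importance = TRUE)
        null_imp[b, j] <- randomForest::importance(rf_b, scale = FALSE)[predictors[j], "%IncMSE"]
      }
    }
  }
  p_vals <- vapply(seq_along(predictors), function(j) {
    (1 + sum(null_imp[, j] >= obs_perm[j])) / (n_perm + 1)
  }, numeric(1))

  pos <- pmax(obs_perm, 0)
  norm_imp <- if (sum(pos) > 0) pos / sum(pos) else rep(1 / length(pos), length(pos))

  mse_oob <- mean((y - rf$predicted)^2)
  rmse <- sqrt(mse_oob)
  metrics <- list(
    oob_r2 = 100 * (1 - mse_oob / mean((y - mean(y))^2)),
    rmse = rmse,
    nrmse_range = rmse / diff(range(y)),
    cv_rmse = rmse / stats::sd(y)
  )
  structure(
    list(
      importance = data.frame(
        predictor = predictors, mdi = unname(mdi),
        perm_imp = unname(obs_perm), norm_imp = unname(norm_imp),
        p_value = p_vals, stringsAsFactors = FALSE
      ),
      metrics = metrics, forest = rf
    ),
    class = "rf_importance"
  )
}

#' @export
print.rf_importance <- function(x, ...) {
  cat(sprintf("Random-forest importance (OOB R2 = %.1f%%, RMSE = %.4g)\n",
              x$metrics$oob_r2, x$metrics$rmse))
  tab <- x$importance[order(-x$importance$perm_imp), ]
  print(tab, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Logarithmic baseline-dependence threshold
#'
#' Fits \eqn{\Delta = a + b \ln(x)} of a relative change against its
#' baseline value, and reports the zero-crossing
#' \eqn{x^* = \exp(-a/b)} — the baseline value separating soils
#' predicted to increase from those predicted to decrease. The threshold
#' is reported only for a declining relationship with a positive
#' intercept (`b < 0`, `a > 0`) whose crossing lies within the observed
#' baseline range; otherwise `x_star` is `NA` with `in_range_flag`
#' `FALSE`.
#'
#' @param x Baseline values (> 0).
#' @param delta Relative changes (%).
#' @return List of class `threshold_fit`: `a`, `b`, `r2`, `p` (slope
#'   t-test), `x_star`, `in_range_flag`, `n`.
#' @export
log_threshold <- function(x, delta) {
  if (any(x <= 0)) stop("baseline values must be > 0")
  n <- length(x)
  if (n < 5) stop("need at least 5 observations")
  fit <- stats::lm(delta ~ log(x))
  cf <- stats::coef(fit)
  a <- unname(cf[1]); b <- unname(cf[2])
  sm <- suppressWarnings(summary(fit)) # perfect fits are legitimate here
  p <- sm$coefficients[2, 4]
  r2 <- sm$r.squared
  x_star <- NA_real_
  in_range <- FALSE
  if (is.finite(b) && b < 0 && a > 0) {
    cand <- exp(-a / b)
    if (cand >= min(x) && cand <= max(x)) {
      x_star <- cand
      in_range <- TRUE
    }
  }
  structure(list(a = a, b = b, r2 = r2, p = p, x_star = x_star,
                 in_range_flag = in_range, n = n),
            class = "threshold_fit")
}

#' @export
print.threshold_fit <- function(x, ...) {
  cat(sprintf("delta = %.4g %+.4g ln(x)   R2 = %.3f, p = %.3g\n",
              x$a, x$b, x$r2, x$p))
  if (x$in_range_flag) {
    cat(sprintf("threshold x* = %.4g (zero crossing within data range)\n", x$x_star))
  } else cat("no in-range threshold\n")
  invisible(x)
}

# Insert-absorb compact letter display from a logical "significantly
# different" matrix, groups ordered by descending mean.
.compact_letters <- function(sig, order_names) {
  g <- order_names
  cols <- list(g) # each column: set of groups sharing a letter
  pairs <- which(sig & upper.tri(sig), arr.ind = TRUE)
  for (idx in seq_len(nrow(pairs))) {
    gi <- rownames(sig)[pairs[idx, 1]]
    gj <- colnames(sig)[pairs[idx, 2]]
    newcols <- list()
    for (col in cols) {
      if (gi %in% col && gj %in% col) {
        newcols <- c(newcols, list(setdiff(col, gi)), list(setdiff(col, gj)))
      } else {
        newcols <- c(newcols, list(col))
      }
    }
    # absorb: drop any column contained in another (duplicates keep the first)
    keep <- rep(TRUE, length(newcols))
    for (i in seq_along(newcols)) {
      for (j in seq_along(newcols)) {
        if (i == j || !keep[i] || !keep[j]) next
        if (all(newcols[[i]] %in% newcols[[j]]) &&
            (length(newcols[[i]]) < length(newcols[[j]]) || i > j)) {
          keep[i] <- FALSE
          break
        }
      }
    }
    cols <- newcols[keep]
  }
  # order columns by position of their top-mean member, assign letters
  first_pos <- vapply(cols, function(col) min(match(col, g)), numeric(1))
  cols <- cols[order(first_pos)]
  letters_out <- stats::setNames(rep("", length(g)), g)
  for (i in seq_along(cols)) {
    for (grp in cols[[i]]) {
      letters_out[grp] <- paste0(letters_out[grp], letters[i])
    }
  }
  letters_out
}

#' One-way ANOVA across groups with Tukey HSD letter groupings
#'
#' Tests for differences in a change variable among groups (e.g. soil
#' layers) with one-way ANOVA, followed by Tukey's HSD at alpha = 0.05.
#' Groups that do not differ significantly share a lowercase letter;
#' letters are assigned by the insert-absorb algorithm with groups
#' ordered by descending mean, so `"a"` marks the highest-mean group.
#' Groups with fewer than 2 observations are excluded with a warning.
#'
#' @param values Numeric response vector.
#' @param group Grouping factor (or coercible).
#' @param alpha Significance level for the letter display.
#' @return List of class `layer_anova`: `f`, `p`, `df`, `tukey` (data
#'   frame of pairwise comparisons), `letters` (named by group, ordered
#'   by descending mean), `group_means`.
#' @export
layer_anova <- function(values, group, alpha = 0.05) {
  group <- factor(group)
  cnt <- table(group)
  if (any(cnt < 2)) {
    drop <- names(cnt)[cnt < 2]
    warning("excluding groups with < 2 observations: ",
            paste(drop, collapse = ", "))
    keep <- !group %in% drop
    values <- values[keep]
    group <- droplevels(group[keep])
  }
  means <- sort(tapply(values, group, mean), decreasing = TRUE)
  if (nlevels(group) < 2) {
    return(structure(list(f = NA_real_, p = NA_real_, df = c(NA, NA),
                          tukey = NULL,
                          letters = stats::setNames("a", names(means)),
                          group_means = means),
                     class = "layer_anova"))
  }
  fit <- stats::aov(values ~ group)
  av <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  labs <- rownames(tk)
  # TukeyHSD rows follow combn() over the factor levels as "second-first";
  # reconstruct the pairs from the levels (labels themselves may contain "-")
  pr <- utils::combn(levels(group), 2)
  gnames <- names(means)
  sig <- matrix(FALSE, length(gnames), length(gnames),
                dimnames = list(gnames, gnames))
  for (i in seq_along(labs)) {
    g1 <- pr[2, i]; g2 <- pr[1, i]
    s <- tk[i, "p adj"] < alpha
    sig[g1, g2] <- s
    sig[g2, g1] <- s
  }
  letters_out <- .compact_letters(sig, gnames)
  structure(
    list(f = av[1, "F value"], p = av[1, "Pr(>F)"],
         df = c(av[1, "Df"], av[2, "Df"]),
         tukey = data.frame(comparison = labs, diff = tk[, "diff"],
                            p_adj = tk[, "p adj"], row.names = NULL),
         letters = letters_out, group_means = means),
    class = "layer_anova"
  )
}

#' @export
print.layer_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%s, %s) = %.3f, p = %.3g\n",
              x$df[1], x$df[2], x$f, x$p))
  tab <- data.frame(group = names(x$group_means), mean = as.numeric(x$group_means),
                    letter = x$letters[names(x$group_means)])
  print(tab, row.names = FALSE, digits = 4)
  invisible(x)
}
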