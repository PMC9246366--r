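# Per-fish aggregation and the population-level statistical battery:
# weighted regression with a unity-slope test, paired/unpaired t-tests,
# one-way ANOVA over population x treatment x period cells with Tukey HSD
# post-hoc letter groupings, and the mean-variance log-transform screen.

#' Per-fish summary of bout-level variables
#'
#' Averages the bout-level variables over retained bouts for one fish. The
#' regression weight is `sqrt(n_swims)` (precision of a per-fish mean grows
#' with the number of swims).
#'
#' @param bout_rates Output of [score_bouts()] for this fish.
#' @param spontaneous_rate Spontaneous rate for this fish, events/s.
#' @param metadata A [session_metadata()].
#' @return A one-row data.frame: `fish_id`, `population`, `treatment`,
#'   `n_swims`, `mean_pre_rate`, `mean_swim_rate`, `mean_post_rate`,
#'   `mean_spontaneous_rate`, `mean_inhibition` (per-bout mean),
#'   `pooled_inhibition` (consistent pooled estimate), `mean_duration_s`,
#'   `weight`.
#' @export
summarize_fish <- function(bout_rates, spontaneous_rate, metadata) {
  kept <- bout_rates[!is.na(bout_rates$retained) & bout_rates$retained, ]
  n <- nrow(kept)
  if (n == 0) {
    stop(errorCondition(
      sprintf("fish %s excluded: no retained bouts", metadata$fish_id),
      class = c("lateralline_no_retained_bouts", "error")))
  }
  data.frame(fish_id = metadata$fish_id, population = metadata$population,
             treatment = metadata$treatment, n_swims = n,
             mean_pre_rate = mean(kept$pre_rate),
             mean_swim_rate = mean(kept$swim_rate),
             mean_post_rate = mean(kept$post_rate),
             mean_spontaneous_rate = spontaneous_rate,
             mean_inhibition = mean(kept$inhibition),
             pooled_inhibition = inhibition_estimate(bout_rates, "pooled"),
             mean_duration_s = mean(kept$duration_s),
             weight = sqrt(n),
             stringsAsFactors = FALSE)
}

#' Run the bout pipeline over a simulated cohort
#'
#' Scores every fish of a [simulate_cohort()] output (bout windows, rates,
#' retention, inhibition), computes the per-fish spontaneous rate with bout
#' intervals excluded, and stacks the per-fish summaries.
#'
#' @param cohort Output of [simulate_cohort()].
#' @return A data.frame with one [summarize_fish()] row per fish (fish with
#'   zero retained bouts are dropped), plus a `true_inhibition` column with
#'   the generator's ground truth.
#' @export
summarize_cohort <- function(cohort) {
  rows <- lapply(cohort, function(fish) {
    dur <- fish$truth$config$session_duration
    br <- score_bouts(fish$truth$spike_times, fish$truth$bouts, dur)
    sp <- spontaneous_rate(fish$truth$spike_times, fish$truth$bouts, dur)
    row <- tryCatch(summarize_fish(br, sp, fish$metadata),
                    lateralline_no_retained_bouts = function(e) NULL)
    if (!is.null(row)) row$true_inhibition <- fish$truth$inhibition_fraction
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Screen variables for a mean-variance relation and log-transform
#'
#' For each variable, group means and variances are computed across the
#' grouping factor; when their Spearman rank correlation is significantly
#' positive (at `alpha`), the variable is replaced by its natural log (adding
#' half the smallest positive value when zeros are present).
#'
#' @param data Data.frame of numeric variables.
#' @param groups Grouping factor (>= 4 groups required to assess the
#'   relation).
#' @param alpha Significance level for the rank-correlation test.
#' @return A list: `data` (transformed copy), `transformed` (named logical),
#'   `offset` (named numeric, 0 where no offset was needed).
#' @export
maybe_log_transform <- function(data, groups, alpha = 0.05) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 4) {
    stop("need at least 4 groups to assess the mean-variance relation")
  }
  out <- data
  flags <- setNames(logical(ncol(data)), names(data))
  offsets <- setNames(numeric(ncol(data)), names(data))
  for (v in names(data)) {
    x <- data[[v]]
    m <- tapply(x, groups, mean)
    s2 <- tapply(x, groups, var)
    ok <- is.finite(m) & is.finite(s2)
    if (sum(ok) < 4 || length(unique(s2[ok])) < 2 || length(unique(m[ok])) < 2) next
    ct <- suppressWarnings(cor.test(m[ok], s2[ok], method = "spearman",
                                    exact = FALSE))
    if (is.finite(ct$p.value) && ct$p.value < alpha && ct$estimate > 0) {
      off <- 0
      if (any(x <= 0)) {
        pos <- x[x > 0]
        off <- if (length(pos)) 0.5 * min(pos) else 1
        off <- off - min(x, 0)  # reduces to the half-minimum rule for zeros
      }
      out[[v]] <- log(x + off)
      flags[v] <- TRUE
      offsets[v] <- off
    }
  }
  list(data = out, transformed = flags, offset = offsets)
}

#' Weighted regression of swim on pre-swim rates with a unity-slope test
#'
#' Weighted least squares of per-fish swim rates on pre-swim rates; the 95%
#' slope confidence interval comes from the t distribution with n - 2 degrees
#' of freedom. A CI that excludes 1 (the line of unity) indicates significant
#' swim-locked suppression (slope < 1) of afferent activity.
#'
#' @param x Per-fish pre-swim rates (events/s).
#' @param y Per-fish swim rates (events/s).
#' @param weights Positive regression weights (default all 1, reducing to
#'   OLS); the convention is `sqrt(n_swims)` per fish.
#' @param level Confidence level (default 0.95).
#' @return An object of class `unity_test`: `slope`, `intercept`,
#'   `slope_ci_low`, `slope_ci_high`, `excludes_unity`, `n_fish`, `level`,
#'   and the underlying `fit`.
#' @export
weighted_unity_test <- function(x, y, weights = NULL, level = 0.95) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3) stop("need at least 3 fish for a slope confidence interval")
  if (var(x) == 0) stop("zero variance in x: slope undefined")
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights <= 0)) stop("weights must be positive")
  df <- data.frame(x = x, y = y)
  fit <- lm(y ~ x, data = df, weights = weights)
  ci <- confint(fit, "x", level = level)
  slope <- unname(coef(fit)["x"])
  structure(list(slope = slope, intercept = unname(coef(fit)[1]),
                 slope_ci_low = ci[1], slope_ci_high = ci[2],
                 excludes_unity = (ci[1] > 1) || (ci[2] < 1),
                 n_fish = n, level = level, fit = fit),
            class = "unity_test")
}

#' @export
print.unity_test <- function(x, ...) {
  cat("<unity_test> weighted regression of swim on pre-swim rate\n")
  cat(sprintf("  slope %.3g (%.0f%% CI %.3g to %.3g), intercept %.3g, n = %d fish\n",
              x$slope, 100 * x$level, x$slope_ci_low, x$slope_ci_high,
              x$intercept, x$n_fish))
  cat(sprintf("  CI %s the line of unity -> %s\n",
              if (x$excludes_unity) "excludes" else "includes",
              if (x$excludes_unity) "significant swim-locked change in rate"
              else "no detectable swim-locked change"))
  invisible(x)
}

#' Paired t-test of swim vs nonswim rates
#'
#' Two-tailed paired Student's t-test of per-fish afferent rates during
#' swimming against nonswimming periods.
#'
#' @param swim,nonswim Equal-length paired per-fish rate vectors (n >= 2).
#' @return An object of class `htest` (see [stats::t.test()]).
#' @export
paired_swim_test <- function(swim, nonswim) {
  if (length(swim) != length(nonswim)) stop("paired samples must have equal length")
  if (length(swim) < 2) stop("need at least 2 pairs")
  d <- swim - nonswim
  if (sd(d) == 0 && mean(d) == 0) {
    # identical pairs: no difference, by convention t = 0, p = 1
    return(structure(list(statistic = c(t = 0),
                          parameter = c(df = length(d) - 1),
                          p.value = 1, estimate = c(`mean difference` = 0),
                          alternative = "two.sided",
                          method = "Paired t-test",
                          data.name = "swim and nonswim"),
                     class = "htest"))
  }
  t.test(swim, nonswim, paired = TRUE)
}

#' Unpaired two-sample t-test
#'
#' Two-tailed two-sample Student's t-test with pooled variance.
#'
#' @param a,b Numeric samples (each n >= 2).
#' @return An object of class `htest`.
#' @export
unpaired_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each sample needs at least 2 values")
  t.test(a, b, var.equal = TRUE)
}

#' One-way ANOVA over combined factor cells with Tukey letter groupings
#'
#' Fits a one-way ANOVA of `response` across the cells of the combined
#' grouping factors (e.g. population x treatment x period), runs Tukey's HSD
#' on all pairwise cell differences, and derives a compact letter display
#' (groups sharing no letter differ at `alpha`). An optional full factorial
#' decomposition is available.
#'
#' @param data Data.frame holding the response and factor columns.
#' @param response Name of the numeric response column.
#' @param factors Character vector of factor column names combined into cells.
#' @param alpha Significance level for the letter display.
#' @param factorial If `TRUE`, also return the full-factorial ANOVA table.
#' @return A list: `anova` (one-way table as data.frame), `tukey` (data.frame
#'   of pairwise comparisons), `letters` (named character vector, one entry
#'   per cell, ordered by decreasing cell mean), `means` (cell means),
#'   `factorial` (optional full-factorial table).
#' @export
group_comparison <- function(data, response, factors, alpha = 0.05,
                             factorial = FALSE) {
  y <- data[[response]]
  if (!is.numeric(y)) stop("response must be numeric")
  cell <- interaction(data[factors], drop = TRUE, sep = ":")
  counts <- table(cell)
  if (length(counts) < 2) stop("need at least 2 groups")
  if (any(counts < 2)) {
    stop(sprintf("singleton group(s): %s",
                 paste(names(counts)[counts < 2], collapse = ", ")))
  }
  d <- data.frame(y = y, cell = cell)
  fit <- aov(y ~ cell, data = d)
  tab <- as.data.frame(summary(fit)[[1]])
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$cell
  tk_df <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  means <- tapply(y, cell, mean)
  letters <- cld_letters(names(sort(means, decreasing = TRUE)),
                         tk_df$comparison, tk_df$p_adj, alpha)
  out <- list(anova = tab, tukey = tk_df, letters = letters,
              means = means[names(letters)])
  if (factorial) {
    ff <- data[factors]
    ff[] <- lapply(ff, as.factor)
    dfull <- cbind(y = y, ff)
    form <- stats::as.formula(paste("y ~", paste(factors, collapse = " * ")))
    out$factorial <- as.data.frame(summary(aov(form, data = dfull))[[1]])
  }
  out
}

# Compact letter display by insert-and-absorb on pairwise p-values.
# `groups` must be ordered (by decreasing mean); comparisons are
# "a-b" strings with matching p-values.
cld_letters <- function(groups, comparisons, p_values, alpha = 0.05) {
  sets <- list(groups)
  parts <- strsplit(comparisons, "-", fixed = TRUE)
  sig <- which(p_values < alpha)
  for (k in sig) {
    g1 <- parts[[k]][1]
    g2 <- parts[[k]][2]
    i <- 1
    while (i <= length(sets)) {
      s <- sets[[i]]
      if (g1 %in% s && g2 %in% s) {
        sets[[i]] <- setdiff(s, g1)
        sets <- append(sets, list(setdiff(s, g2)), after = i)
        i <- i + 1
      }
      i <- i + 1
    }
    # absorb sets that are subsets of another
    keep <- rep(TRUE, length(sets))
    for (a in seq_along(sets)) {
      for (b in seq_along(sets)) {
        if (a != b && keep[a] && all(sets[[a]] %in% sets[[b]]) &&
            length(sets[[a]]) < length(sets[[b]])) {
          keep[a] <- FALSE
        }
      }
    }
    sets <- sets[keep]
    sets <- unique(sets)
  }
  # order sets by first member's position, assign letters
  first_pos <- vapply(sets, function(s) min(match(s, groups)), numeric(1))
  sets <- sets[order(first_pos)]
  out <- setNames(rep("", length(groups)), groups)
  for (i in seq_along(sets)) {
    for (g in sets[[i]]) out[g] <- paste0(out[g], letters[i])
  }
  out
}
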