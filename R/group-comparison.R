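#' Compare a trajectory metric between groups with a mixed model and Tukey
#' contrasts
#'
#' Fits `response ~ group + period` with a per-individual random intercept
#' (\code{nlme::lme}) and returns all pairwise group contrasts with
#' family-wise (Tukey) adjusted p-values (\pkg{multcomp}). When the mixed
#' model is singular or cannot be fitted (e.g. one observation per individual),
#' falls back to a one-way ANOVA on individual means with Tukey HSD, flagged
#' in the `method` column. An optional AR(1) residual correlation across
#' periods within individuals can be switched on for serially correlated
#' responses (environmental variables sampled along a track).
#'
#' @param stats data frame of per-period statistics (see
#'   [period_stats_table()]) or any long-format table with one row per
#'   individual x period.
#' @param response name of the response column.
#' @param group name of the grouping factor column (e.g. "species").
#' @param individual name of the individual-id column.
#' @param period name of the period column (fixed categorical covariate);
#'   `NULL` omits it.
#' @param ar1 logical; add an AR(1) correlation over periods within
#'   individuals (default `FALSE`).
#' @return data frame of class `contrast_table`: one row per group pair with
#'   `group_a`, `group_b`, `estimate`, `se`, `adjusted_p`, `method`.
#' @export
compare_groups <- function(stats, response, group = "species",
                           individual = "individual_id",
                           period = "period_index", ar1 = FALSE) {
  df <- stats[, c(response, group, individual, period[!is.null(period)]),
              drop = FALSE]
  names(df)[1:3] <- c(".y", ".g", ".id")
  if (!is.null(period)) names(df)[4] <- ".p"
  df <- df[stats::complete.cases(df), , drop = FALSE]
  df$.g <- factor(df$.g)
  df$.id <- factor(df$.id)
  if (nlevels(df$.g) < 2) stop("need at least 2 groups", call. = FALSE)
  counts <- tapply(df$.id, df$.g, function(x) length(unique(x)))
  if (any(counts < 2)) stop("need at least 2 individuals per group", call. = FALSE)

  fit_mixed <- function() {
    fixed <- if (!is.null(period) && length(unique(df$.p)) > 1) {
      df$.p <- factor(df$.p)
      .y ~ .g + .p
    } else {
      .y ~ .g
    }
    cor_struct <- if (ar1) nlme::corAR1(form = ~ as.numeric(.p) | .id) else NULL
    m <- nlme::lme(fixed, random = ~ 1 | .id, data = df,
                   correlation = cor_struct, method = "REML")
    g <- multcomp::glht(m, linfct = multcomp::mcp(.g = "Tukey"))
    s <- summary(g)
    labs <- strsplit(rownames(s$linfct), " - ")
    data.frame(group_a = vapply(labs, `[`, "", 1),
               group_b = vapply(labs, `[`, "", 2),
               estimate = as.numeric(s$test$coefficients),
               se = as.numeric(s$test$sigma),
               adjusted_p = as.numeric(s$test$pvalues),
               method = if (ar1) "lme+Tukey (AR1)" else "lme+Tukey",
               stringsAsFactors = FALSE)
  }

  fit_fallback <- function() {
    agg <- stats::aggregate(.y ~ .g + .id, data = df, FUN = mean)
    a <- stats::aov(.y ~ .g, data = agg)
    tk <- stats::TukeyHSD(a)$`.g`
    labs <- strsplit(rownames(tk), "-")
    data.frame(group_a = vapply(labs, `[`, "", 1),
               group_b = vapply(labs, `[`, "", 2),
               estimate = tk[, "diff"],
               se = NA_real_,
               adjusted_p = tk[, "p adj"],
               method = "individual-means aov+TukeyHSD",
               stringsAsFactors = FALSE)
  }

  out <- tryCatch(fit_mixed(), error = function(e) fit_fallback())
  rownames(out) <- NULL
  class(out) <- c("contrast_table", class(out))
  out
}

#' Compare month-3 latitudes between juveniles and adults
#'
#' Two-sided Wilcoxon rank-sum test on per-individual mean latitudes: exact
#' null distribution when the combined sample size is at most 20 and the data
#' are tie-free, otherwise the normal approximation with tie correction.
#'
#' @param juv_lats per-individual mean latitudes, juveniles (n >= 3).
#' @param adult_lats per-individual mean latitudes, adults (n >= 3).
#' @return list with `p_value`, `direction` (`"juveniles_higher"`,
#'   `"adults_higher"` or `"none"`; higher = closer to the north pole),
#'   `statistic` (the rank-sum W), `method`.
#' @export
compare_age_latitude <- function(juv_lats, adult_lats) {
  juv_lats <- juv_lats[is.finite(juv_lats)]
  adult_lats <- adult_lats[is.finite(adult_lats)]
  if (length(juv_lats) < 3 || length(adult_lats) < 3) {
    stop("need at least 3 individuals per age class", call. = FALSE)
  }
  if (length(unique(c(juv_lats, adult_lats))) == 1) {
    return(list(p_value = 1, direction = "none", statistic = NA_real_,
                method = "degenerate (all values identical)"))
  }
  n <- length(juv_lats) + length(adult_lats)
  ties <- any(duplicated(c(juv_lats, adult_lats)))
  exact <- n <= 20 && !ties
  wt <- suppressWarnings(stats::wilcox.test(juv_lats, adult_lats,
                                            exact = exact, correct = TRUE))
  med_diff <- stats::median(juv_lats) - stats::median(adult_lats)
  list(p_value = wt$p.value,
       direction = if (med_diff > 0) "juveniles_higher"
                   else if (med_diff < 0) "adults_higher" else "none",
       statistic = unname(wt$statistic),
       method = if (exact) "exact rank-sum" else "normal approximation (tie-corrected)")
}
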