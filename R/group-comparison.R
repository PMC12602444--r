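# One-way group comparisons: Shapiro-Wilk and Levene pre-checks,
# one-way ANOVA, Tukey HSD, compact letter display.

#' Compare a response across groups (ANOVA + Tukey HSD)
#'
#' The standard battery for replicate treatment means: Shapiro-Wilk on
#' the model residuals for normality, Levene's test (mean-centered) for
#' homogeneity of variance, one-way ANOVA, then Tukey's HSD at the
#' given alpha with a compact letter display -- groups sharing a letter
#' are not significantly different. Pre-check failures are surfaced as
#' warnings, not hard stops: with n = 4 per group the pre-tests have
#' little power either way, and the ANOVA is reported regardless so the
#' analyst can judge.
#'
#' @param values Numeric response vector.
#' @param group Grouping factor (coerced); >= 2 groups, each n >= 2.
#' @param alpha Significance level for the letter display (default
#'   0.05).
#' @return A list: `f_statistic`, `df`, `p_value`, `shapiro_p`,
#'   `levene_p`, `letters` (named by group level), `tukey` (a tibble of
#'   pairwise comparisons), `warnings` (character).
#' @examples
#' compare_groups(c(1, 2, 1.5, 9, 10, 11), rep(c("a", "b"), each = 3))
#' @export
compare_groups <- function(values, group, alpha = 0.05) {
  group <- factor(group)
  stopifnot(length(values) == length(group))
  sizes <- table(group)
  if (length(sizes) < 2L) {
    stop("need at least two groups to compare", call. = FALSE)
  }
  if (any(sizes < 2L)) {
    stop("every group needs n >= 2 (got n = ",
         min(sizes), " in group '", names(sizes)[which.min(sizes)], "')",
         call. = FALSE)
  }
  d <- data.frame(y = values, g = group)
  fit <- stats::aov(y ~ g, data = d)
  tab <- summary(fit)[[1L]]
  f_stat <- tab[["F value"]][1L]
  p_val <- tab[["Pr(>F)"]][1L]
  dfs <- tab[["Df"]]

  warnings_out <- character()
  shapiro_p <- tryCatch(stats::shapiro.test(stats::residuals(fit))$p.value,
                        error = function(e) NA_real_)
  levene_p <- tryCatch(
    car::leveneTest(y ~ g, data = d, center = mean)[1L, "Pr(>F)"],
    error = function(e) NA_real_
  )
  note <- function(msg) {
    warnings_out <<- c(warnings_out, msg)
    warning(msg, call. = FALSE)
  }
  if (is.finite(shapiro_p) && shapiro_p < alpha) {
    note(sprintf("Shapiro-Wilk rejects residual normality (p = %.3g)",
                 shapiro_p))
  }
  if (is.finite(levene_p) && levene_p < alpha) {
    note(sprintf("Levene's test rejects homogeneous variances (p = %.3g)",
                 levene_p))
  }

  letters <- tryCatch({
    glht <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Tukey"))
    cld <- multcomp::cld(glht, level = alpha)
    cld$mcletters$Letters
  }, error = function(e) {
    warnings_out <<- c(warnings_out,
                       paste("letter display unavailable:",
                             conditionMessage(e)))
    stats::setNames(rep(NA_character_, nlevels(group)), levels(group))
  })

  hsd <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  tukey <- tibble::tibble(
    comparison = rownames(hsd),
    diff = hsd[, "diff"],
    lwr = hsd[, "lwr"],
    upr = hsd[, "upr"],
    p_adj = hsd[, "p adj"]
  )

  list(
    f_statistic = f_stat,
    df = dfs,
    p_value = p_val,
    shapiro_p = shapiro_p,
    levene_p = unname(levene_p),
    letters = letters,
    tukey = tukey,
    warnings = warnings_out
  )
}
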