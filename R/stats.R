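significance_tier <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' Paired t test with significance tiers
#'
#' Standard paired t test on the within-pair differences, reporting the
#' significance tier convention (* P < 0.05, ** P < 0.01, *** P < 0.001).
#' Degenerate inputs (zero-variance differences) are resolved by
#' convention: all-zero differences give t = 0, p = 1; constant non-zero
#' differences give p = 0. Both are flagged with a warning.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return list of class `comparison_result`: `test`, `statistic`, `df`,
#'   `p_value`, `tier`.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal lengths")
  if (length(x) < 2) stop("need at least 2 pairs")
  d <- x - y
  n <- length(d)
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      warning("all differences are zero: reporting t = 0, p = 1 by convention")
      res <- list(statistic = 0, df = n - 1, p_value = 1)
    } else {
      warning("constant non-zero differences: reporting p = 0 by convention")
      res <- list(statistic = sign(mean(d)) * Inf, df = n - 1, p_value = 0)
    }
  } else {
    tt <- stats::t.test(x, y, paired = TRUE)
    res <- list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                p_value = tt$p.value)
  }
  structure(c(list(test = "paired_t"), res,
              list(tier = significance_tier(res$p_value))),
            class = "comparison_result")
}

#' One- or two-way ANOVA with Bonferroni post hoc tests
#'
#' F tests from the standard sum-of-squares decomposition (via
#' [stats::aov()]), followed by Bonferroni-corrected pairwise comparisons:
#' pooled-error t tests between factor levels with raw p values multiplied
#' by the number of comparisons and capped at 1. Two-way designs must be
#' balanced (equal cell sizes), which keeps the decomposition unambiguous.
#'
#' @param values numeric response vector.
#' @param group factor (or coercible) for the one-way layout.
#' @param factor2 optional second factor; supplying it fits the two-way
#'   layout with interaction.
#' @return list of class `comparison_result`: `test`, `anova` (data.frame
#'   of effects: term, df, F, p, tier), `posthoc` (data.frame of pairwise
#'   comparisons with raw and Bonferroni-adjusted p values and tiers).
#' @export
anova_bonferroni <- function(values, group, factor2 = NULL) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need at least 2 groups")
  if (any(table(group) < 2)) stop("each group needs n >= 2")
  if (is.null(factor2)) {
    fit <- stats::aov(values ~ group)
    test <- "one_way_anova"
  } else {
    factor2 <- factor(factor2)
    tab <- table(group, factor2)
    if (length(unique(as.vector(tab))) != 1) {
      stop("two-way layout must be balanced (equal cell sizes)")
    }
    fit <- stats::aov(values ~ group * factor2)
    test <- "two_way_anova"
  }
  sm <- summary(fit)[[1]]
  terms <- trimws(rownames(sm))
  eff <- which(terms != "Residuals")
  anova_df <- data.frame(
    term = terms[eff], df = sm$Df[eff], F = sm$`F value`[eff],
    p_value = sm$`Pr(>F)`[eff],
    tier = vapply(sm$`Pr(>F)`[eff], significance_tier, ""),
    row.names = NULL
  )
  # Bonferroni pairwise comparisons on `group`, pooled residual error
  mse <- sm$`Sum Sq`[terms == "Residuals"] / sm$Df[terms == "Residuals"]
  df_res <- sm$Df[terms == "Residuals"]
  lv <- levels(group)
  cmb <- utils::combn(lv, 2)
  m_comp <- ncol(cmb)
  posthoc <- do.call(rbind, lapply(seq_len(m_comp), function(i) {
    g1 <- cmb[1, i]; g2 <- cmb[2, i]
    v1 <- values[group == g1]; v2 <- values[group == g2]
    se <- sqrt(mse * (1 / length(v1) + 1 / length(v2)))
    tstat <- (mean(v1) - mean(v2)) / se
    p_raw <- 2 * stats::pt(-abs(tstat), df_res)
    data.frame(comparison = paste(g1, "vs", g2), t = tstat, df = df_res,
               p_raw = p_raw, p_adjusted = min(1, p_raw * m_comp))
  }))
  posthoc$tier <- vapply(posthoc$p_adjusted, significance_tier, "")
  structure(list(test = test, anova = anova_df, posthoc = posthoc),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("<comparison_result>", x$test, "\n")
  if (!is.null(x$anova)) {
    print(x$anova)
    cat("post hoc (Bonferroni):\n")
    print(x$posthoc)
  } else {
    cat(sprintf("  t = %.4g, df = %g, p = %.4g %s\n",
                x$statistic, x$df, x$p_value, x$tier))
  }
  invisible(x)
}
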