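# breed/pasture comparisons: Tukey range tests and the paddock-size x breed
# analysis of variance

#' Tukey range test over groups
#'
#' One-way layout followed by Tukey's honest significant difference:
#' all pairwise group contrasts with p-values from the studentized-range
#' distribution (evaluated by R's numerically integrated `ptukey`).
#' With two groups the adjusted p-value coincides with the pooled-variance
#' two-sample t-test.
#'
#' @param data A data frame.
#' @param value Unquoted column with the response (one value per animal).
#' @param group Unquoted grouping column (>= 2 groups, each n >= 2).
#' @param conf.level Confidence level of the interval (default 0.95).
#' @return A tibble with one row per pairwise contrast: `group1`, `group2`,
#'   `estimate` (mean difference group1 - group2), `conf.low`, `conf.high`,
#'   `adj.p.value`.
#' @export
tukey_pairwise <- function(data, value, group, conf.level = 0.95) {
  v <- dplyr::pull(data, {{ value }})
  g <- factor(dplyr::pull(data, {{ group }}))
  ok <- complete.cases(v, g)
  v <- v[ok]; g <- droplevels(g[ok])
  if (nlevels(g) < 2) abort_bad_arg("need at least 2 groups.")
  sizes <- table(g)
  if (any(sizes < 2)) {
    abort_bad_arg(sprintf("group(s) with fewer than 2 observations: %s.",
                          paste(names(sizes)[sizes < 2], collapse = ", ")),
                  class = "grazemetry_degenerate_error")
  }
  fit <- aov(v ~ g)
  tk <- TukeyHSD(fit, conf.level = conf.level)$g
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  tibble(
    group1 = vapply(pairs, `[`, character(1), 1),
    group2 = vapply(pairs, `[`, character(1), 2),
    estimate = tk[, "diff"],
    conf.low = tk[, "lwr"],
    conf.high = tk[, "upr"],
    adj.p.value = tk[, "p adj"]
  )
}

#' Breed and paddock-size effects on a response
#'
#' Sequential (type I) analysis of variance of the linear model
#' `response ~ breed + size + breed:size`, the layout used to separate the
#' effect of breed from the effect of the available paddock area on
#' movement variables.
#'
#' @param data A data frame.
#' @param response Unquoted response column.
#' @param breed Unquoted breed column (factor-like, >= 2 levels).
#' @param size Unquoted numeric paddock-size column (must vary).
#' @return A tibble: `term`, `df`, `sumsq`, `meansq`, `statistic`,
#'   `p.value` (the residual row carries `NA` statistics).
#' @export
anova_breed_size <- function(data, response, breed, size) {
  y <- dplyr::pull(data, {{ response }})
  b <- factor(dplyr::pull(data, {{ breed }}))
  s <- dplyr::pull(data, {{ size }})
  ok <- complete.cases(y, b, s)
  y <- y[ok]; b <- droplevels(b[ok]); s <- s[ok]
  if (nlevels(b) < 2) abort_bad_arg("need at least 2 breeds.")
  if (sd(s) == 0) abort_bad_arg("paddock size does not vary.",
                                class = "grazemetry_degenerate_error")
  fit <- lm(y ~ b * s)
  if (any(is.na(coef(fit)))) {
    abort_bad_arg("model is rank deficient (collinear breed/size design).",
                  class = "grazemetry_degenerate_error")
  }
  an <- anova(fit)
  terms <- c("breed", "size", "breed:size", "residuals")
  tibble(
    term = terms,
    df = an$Df,
    sumsq = an$`Sum Sq`,
    meansq = an$`Mean Sq`,
    statistic = an$`F value`,
    p.value = an$`Pr(>F)`
  )
}
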