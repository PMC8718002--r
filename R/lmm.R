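#' Likelihood-ratio comparison of nested mixed models
#'
#' Compares nested linear mixed models with a random intercept for plant
#' family, refit by maximum likelihood (not REML) as required for
#' likelihood-ratio tests of fixed effects. Two comparisons are supported:
#'
#' * `effect = "syndrome"`: response ~ syndrome + (1|family) against
#'   response ~ (1|family). 1 df.
#' * `effect = "surface_x_syndrome"`: response ~ ln(area) * syndrome +
#'   (1|family) against response ~ ln(area) + (1|family). 2 df (main effect
#'   plus interaction).
#'
#' Boundary effects for the family variance component (a variance estimated
#' at zero) make the chi-square reference conservative; this is inherent to
#' LR tests of mixed models and is not corrected here.
#'
#' @param data data frame with the response, `syndrome`, `family` and (for
#'   the interaction comparison) `surface_area` columns.
#' @param response name of the response column (e.g. `"ts_broad"`).
#' @param effect which fixed-effect comparison to run.
#' @return list with `chisq`, `df`, `p_value`, and the two fitted models
#'   (`null`, `full`). Non-convergence is raised as an error.
#' @export
lmm_compare <- function(data, response = "ts_broad",
                        effect = c("syndrome", "surface_x_syndrome")) {
  effect <- match.arg(effect)
  if (!response %in% names(data)) stopf("no column %s", response)
  d <- data
  d$.y <- d[[response]]
  if (effect == "syndrome") {
    f0 <- .y ~ (1 | family)
    f1 <- .y ~ syndrome + (1 | family)
  } else {
    if (!"surface_area" %in% names(d)) stopf("surface_area column required")
    d$.la <- log(d$surface_area)
    f0 <- .y ~ .la + (1 | family)
    f1 <- .y ~ .la * syndrome + (1 | family)
  }
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore")
  m0 <- lme4::lmer(f0, data = d, REML = FALSE, control = ctrl)
  m1 <- lme4::lmer(f1, data = d, REML = FALSE, control = ctrl)
  for (m in list(m0, m1)) {
    cc <- m@optinfo$conv$lme4
    if (!is.null(cc$code) && cc$code != 0)
      stopf("mixed model did not converge (code %d)", cc$code)
  }
  a <- stats::anova(m0, m1)
  list(chisq = a$Chisq[2], df = a$Df[2], p_value = a$`Pr(>Chisq)`[2],
       null = m0, full = m1)
}
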