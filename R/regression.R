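#' Fit the target-strength vs surface-area regression
#'
#' Ordinary least squares of a band target strength (dB) on the natural log
#' of flower surface area (mm^2): `TS = a ln(F_sur) + b`. Returns a classed
#' fit with the usual accessor methods.
#'
#' @param ts_table per-flower table from [flower_ts_table()] (or a CSV with
#'   the same columns).
#' @param band which TS column to model (default the broad 40-160 kHz band).
#' @return object of class `ts_regression`: the underlying `lm` fit plus
#'   `slope`, `intercept`, `r_squared`, `f_statistic`, `df`, and the data.
#' @examples
#' \donttest{
#' fl <- sample_flowers(make_catalog(1), 14, seed = 2)
#' tab <- flower_ts_table(fl, cfg = sim_config(seed = 3))
#' fit <- fit_ts_regression(tab)
#' coef(fit)
#' }
#' @export
fit_ts_regression <- function(ts_table, band = "ts_broad") {
  if (!band %in% names(ts_table)) stopf("no column %s in ts_table", band)
  if (nrow(ts_table) < 3) stopf("need at least 3 flowers")
  if (any(ts_table$surface_area <= 0)) stopf("surface areas must be > 0")
  x <- log(ts_table$surface_area)
  if (var(x) == 0) stopf("degenerate predictor: all areas equal")
  df <- data.frame(ts = ts_table[[band]], log_area = x,
                   syndrome = ts_table$syndrome)
  fit <- lm(ts ~ log_area, data = df)
  s <- summary(fit)
  structure(list(lm = fit, data = df, band = band,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = s$r.squared,
                 f_statistic = unname(s$fstatistic[1]),
                 df = unname(s$fstatistic[2:3]),
                 slope_se = s$coefficients[2, 2]),
            class = "ts_regression")
}

#' @export
print.ts_regression <- function(x, ...) {
  cat(sprintf("Target strength ~ ln(surface area) [%s]\n", x$band))
  cat(sprintf("  TS = %.3f ln(area) %+.3f dB\n", x$slope, x$intercept))
  cat(sprintf("  R^2 = %.3f, F(%d, %d) = %.1f, n = %d\n",
              x$r_squared, x$df[1], x$df[2], x$f_statistic,
              nrow(x$data)))
  invisible(x)
}

#' @export
summary.ts_regression <- function(object, ...) summary(object$lm, ...)

#' @export
coef.ts_regression <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
residuals.ts_regression <- function(object, ...) residuals(object$lm)

#' @export
predict.ts_regression <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(predict(object$lm))
  if (!is.null(newdata$surface_area))
    newdata <- data.frame(log_area = log(newdata$surface_area))
  predict(object$lm, newdata = newdata)
}

#' @export
plot.ts_regression <- function(x, ...) {
  cols <- ifelse(x$data$syndrome == "bat", "black", "grey60")
  plot(x$data$log_area, x$data$ts, pch = 21, bg = cols,
       xlab = "ln(surface area / mm^2)", ylab = "overall TS (dB)", ...)
  graphics::abline(x$lm, lwd = 2)
  graphics::legend("topleft", c("bat", "other"), pt.bg = c("black",
                   "grey60"), pch = 21, bty = "n")
  invisible(x)
}

#' Syndrome comparison of regression residuals
#'
#' Welch two-sample t-test of the regression residuals grouped by pollination
#' syndrome: does target strength differ between bat-pollinated and other
#' flowers after removing the effect of surface area? Welch (unequal
#' variance) degrees of freedom are fractional.
#'
#' @param fit a [fit_ts_regression()] object.
#' @param syndromes optional explicit syndrome vector (defaults to the one
#'   stored with the fit).
#' @return object of class `syndrome_test`: list with group means (of the
#'   residuals), `t_statistic`, `welch_df`, `p_value` and `difference`
#'   (bat minus other, dB).
#' @export
residual_syndrome_test <- function(fit, syndromes = fit$data$syndrome) {
  res <- residuals(fit)
  g <- factor(syndromes, levels = c("bat", "other"))
  if (any(table(g) < 2)) stopf("each syndrome group needs >= 2 flowers")
  tt <- t.test(res[g == "bat"], res[g == "other"], var.equal = FALSE)
  structure(list(group_means = c(bat = mean(res[g == "bat"]),
                                 other = mean(res[g == "other"])),
                 difference = unname(diff(rev(tt$estimate))),
                 t_statistic = unname(tt$statistic),
                 welch_df = unname(tt$parameter),
                 p_value = tt$p.value),
            class = "syndrome_test")
}

#' @export
print.syndrome_test <- function(x, ...) {
  cat("Welch t-test of TS residuals by pollination syndrome\n")
  cat(sprintf("  mean residual: bat %+.2f dB, other %+.2f dB (diff %+.2f)\n",
              x$group_means["bat"], x$group_means["other"], x$difference))
  cat(sprintf("  t = %.3f, df = %.2f, p = %.3g\n",
              x$t_statistic, x$welch_df, x$p_value))
  invisible(x)
}
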