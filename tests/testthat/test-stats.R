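test_that("regression: exact fit on noiseless data, closed-form check", {
  area <- c(300, 700, 1500, 3000, 5200, 8000)
  tab <- data.frame(surface_area = area, syndrome = rep(c("bat", "other"),
                                                        3),
                    ts_broad = 3 * log(area) - 30)
  fit <- fit_ts_regression(tab)
  expect_equal(fit$slope, 3, tolerance = 1e-10)
  expect_equal(fit$intercept, -30, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  # closed-form normal equations on a noisy instance
  set.seed(2)
  tab$ts_broad <- tab$ts_broad + rnorm(6)
  fit2 <- fit_ts_regression(tab)
  x <- log(area); y <- tab$ts_broad
  slope_nf <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(fit2$slope, slope_nf, tolerance = 1e-12)
  expect_equal(fit2$intercept, mean(y) - slope_nf * mean(x),
               tolerance = 1e-12)
  # R^2 definition against brute force
  ss_res <- sum(residuals(fit2)^2)
  ss_tot <- sum((y - mean(y))^2)
  expect_equal(fit2$r_squared, 1 - ss_res / ss_tot, tolerance = 1e-12)
  expect_equal(sum(residuals(fit2)), 0, tolerance = 1e-9)
  # degenerate predictor
  tab3 <- tab
  tab3$surface_area <- 100
  expect_error(fit_ts_regression(tab3), "degenerate")
})

test_that("Welch test matches the textbook formula on a toy table", {
  x <- c(4.1, 5.2, 6.3, 5.8)
  y <- c(3.0, 2.5, 3.9, 3.2)
  fit <- fit_ts_regression(data.frame(surface_area = rep(c(300, 900), 4),
                                      syndrome = rep(c("bat", "other"),
                                                     each = 4),
                                      ts_broad = c(x, y)))
  res <- residuals(fit)
  got <- residual_syndrome_test(fit)
  a <- res[1:4]; b <- res[5:8]
  se <- sqrt(var(a) / 4 + var(b) / 4)
  t_manual <- (mean(a) - mean(b)) / se
  df_manual <- (var(a) / 4 + var(b) / 4)^2 /
    ((var(a) / 4)^2 / 3 + (var(b) / 4)^2 / 3)
  expect_equal(got$t_statistic, t_manual, tolerance = 1e-12)
  expect_equal(got$welch_df, df_manual, tolerance = 1e-12)
  expect_false(got$welch_df == round(got$welch_df))  # fractional df
  # identical groups give t = 0
  same <- data.frame(surface_area = rep(c(300, 900), 6),
                     syndrome = rep(c("bat", "other"), 6),
                     ts_broad = rep(c(1, 2), 6))
  expect_equal(residual_syndrome_test(fit_ts_regression(same))$t_statistic,
               0, tolerance = 1e-9)
})

test_that("generator recovery: slope, syndrome offset, R^2 ballpark", {
  truth <- acoustic_truth()
  fl <- sample_flowers(make_catalog(seed = 3), 14, seed = 4)
  tab <- flower_ts_table(fl, truth, sim_config(seed = 5))
  fit <- fit_ts_regression(tab)
  expect_equal(fit$slope, truth$slope, tolerance = 3 * fit$slope_se / 3.488)
  st <- residual_syndrome_test(fit)
  expect_equal(st$difference, truth$syndrome_offset_db, tolerance = 1)
  expect_gt(fit$r_squared, 0.65)
  expect_lt(fit$r_squared, 0.92)
})

test_that("syndrome cV summary: zero-variance case and group ordering", {
  cat0 <- make_catalog(seed = 1)
  cat0$cv_target <- 0
  fl0 <- sample_flowers(cat0, 4, seed = 2)
  cv0 <- species_cv_table(fl0)
  s0 <- cv_syndrome_summary(cv0)
  expect_equal(s0$morphological_cv, c(0, 0))
  # with defaults the bat group is less variable in most seeds; check one
  fl <- sample_flowers(make_catalog(seed = 6), 14, seed = 7)
  s <- cv_syndrome_summary(species_cv_table(fl))
  expect_lt(s$morphological_cv[s$syndrome == "bat"],
            s$morphological_cv[s$syndrome == "other"])
})

test_that("acoustic cV follows morphological cV across species", {
  fl <- sample_flowers(make_catalog(seed = 8), 14, seed = 9)
  tab <- flower_ts_table(fl, cfg = sim_config(seed = 10))
  mcv <- attr(species_cv_table(fl), "species_mean")
  acv <- attr(acoustic_cv_table(tab), "species_mean")
  m <- merge(mcv, acv, by = "species")
  expect_gt(cor(m$mean_cv.x, m$mean_cv.y, method = "spearman"), 0)
  s <- cv_syndrome_summary(species_cv_table(fl), acoustic_cv_table(tab))
  expect_true("acoustic_cv" %in% names(s))
})

test_that("mixed-model comparison: df, power, null calibration", {
  truth <- acoustic_truth()
  fl <- sample_flowers(make_catalog(seed = 11), 14, seed = 12)
  tab <- flower_ts_table(fl, truth, sim_config(seed = 13))
  cmp <- lmm_compare(tab, "ts_broad", "surface_x_syndrome")
  expect_equal(cmp$df, 2)
  expect_lt(cmp$p_value, 0.001)  # strong planted syndrome effect
  cmp1 <- lmm_compare(tab, "ts_broad", "syndrome")
  expect_equal(cmp1$df, 1)
  # null calibration: no syndrome effect -> roughly uniform p (cheap check:
  # type-I error near 0.05 over simulated nulls, using a plain Gaussian
  # response so each replicate is fast)
  set.seed(14)
  fams <- rep(paste0("fam", 1:6), each = 28)
  syn <- rep(rep(c("bat", "other"), each = 14), 6)
  pvals <- replicate(60, {
    d <- data.frame(family = fams, syndrome = syn,
                    y = rnorm(168) + rep(rnorm(6, sd = 0.5), each = 28))
    lmm_compare(d, "y", "syndrome")$p_value
  })
  # type-I error at or below the nominal level (the LR test is slightly
  # conservative for variance components at the boundary), p not
  # systematically small under the null
  expect_lt(mean(pvals < 0.05), 0.15)
  expect_gt(mean(pvals), 0.3)
  expect_lt(mean(pvals), 0.7)
})
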