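#' Reflective surface area of a bell-shaped flower
#'
#' Estimates the acoustically reflective surface of a bell-shaped corolla as
#' the lateral surface of a paraboloid (the corolla chalice) plus the disc of
#' the corolla opening:
#' \deqn{F_{sur} = \frac{\pi r_p}{6 h^2}\left[(r_p^2+4h^2)^{3/2}-r_p^3\right]
#'   + \pi r_c^2}
#' where `r_p` is half the mean inner corolla diameter, `r_c` half the mean
#' outer corolla diameter and `h` the corolla length. Mean diameters are the
#' arithmetic mean of the horizontal and vertical measurements. As `h -> 0`
#' the paraboloid term tends to `pi * r_p^2` (flat disc), which is used
#' directly for very small `h` to avoid cancellation.
#'
#' @param corolla_length corolla length `h` in mm.
#' @param inner_diam_h,inner_diam_v inner corolla-opening diameters in mm
#'   (pass the same value twice for radially symmetric flowers).
#' @param outer_diam_h,outer_diam_v outer corolla-opening diameters in mm.
#' @return surface area in mm^2 (vectorised).
#' @examples
#' surface_area(20, 10, 10, 12, 12)
#' @export
surface_area <- function(corolla_length, inner_diam_h, inner_diam_v,
                         outer_diam_h, outer_diam_v) {
  r_p <- (inner_diam_h + inner_diam_v) / 4
  r_c <- (outer_diam_h + outer_diam_v) / 4
  h <- corolla_length
  if (any(!is.finite(c(r_p, r_c, h))) || any(c(r_p, r_c, h) <= 0))
    stopf("all morphological inputs must be positive and finite")
  para <- ifelse(h / r_p < 1e-6,
                 pi * r_p^2,
                 pi * r_p / (6 * h^2) * ((r_p^2 + 4 * h^2)^1.5 - r_p^3))
  para + pi * r_c^2
}

#' Surface area from a flower feature row
#'
#' Convenience wrapper applying [surface_area()] to the feature columns of a
#' flower table (as produced by [sample_flowers()]).
#'
#' @param flowers data frame with columns `corolla_length`, `inner_diam_h`,
#'   `inner_diam_v`, `outer_diam_h`, `outer_diam_v`.
#' @return numeric vector of areas in mm^2.
#' @export
flower_surface_area <- function(flowers) {
  surface_area(flowers$corolla_length,
               flowers$inner_diam_h, flowers$inner_diam_v,
               flowers$outer_diam_h, flowers$outer_diam_v)
}

#' Coefficient of variation
#'
#' Ratio of the sample standard deviation (n-1 denominator) to the sample
#' mean: a dimensionless measure of relative variability that allows
#' comparing features of flowers that differ greatly in absolute size.
#'
#' @param values numeric vector, length >= 2, non-zero mean.
#' @return scalar cV.
#' @examples
#' coefficient_of_variation(c(1, 2, 3))  # 0.5
#' @export
coefficient_of_variation <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) stopf("need at least 2 values for a cV")
  m <- mean(values)
  if (m == 0) stopf("cV undefined for zero mean")
  sd(values) / m
}

#' Per-species, per-feature coefficients of variation
#'
#' Computes the cV of every morphological feature within every species, the
#' standard within-species variability summary. Features that are entirely
#' missing for a species are skipped (not zero-filled); species with fewer
#' than two flowers are dropped with a warning.
#'
#' @param flowers flower table (see [sample_flowers()]); must carry
#'   `species`, `syndrome` and the feature columns.
#' @param features character vector of feature column names.
#' @return A long data frame (species, syndrome, feature, cv) with attribute
#'   `species_mean`: a data frame of per-species mean cV across features.
#' @export
species_cv_table <- function(flowers,
                             features = c("corolla_length", "calyx_length",
                                          "inner_depth",
                                          "inner_diam_h", "inner_diam_v",
                                          "outer_diam_h", "outer_diam_v")) {
  stopifnot(all(c("species", "syndrome") %in% names(flowers)))
  features <- intersect(features, names(flowers))
  rows <- list()
  for (sp in unique(flowers$species)) {
    sub <- flowers[flowers$species == sp, , drop = FALSE]
    if (nrow(sub) < 2) {
      warning(sprintf("species %s has < 2 flowers; dropped", sp))
      next
    }
    for (f in features) {
      v <- sub[[f]]
      v <- v[!is.na(v)]
      if (length(v) < 2) next
      rows[[length(rows) + 1]] <- data.frame(
        species = sp, syndrome = sub$syndrome[1], feature = f,
        cv = coefficient_of_variation(v), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  sm <- aggregate(cv ~ species + syndrome, data = out, FUN = mean)
  names(sm)[names(sm) == "cv"] <- "mean_cv"
  attr(out, "species_mean") <- sm
  out
}
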