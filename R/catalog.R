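# Default species pool: six neotropical families, each contributing one
# bat-pollinated and one insect- or bird-pollinated species. The species and
# family names follow the classic chiropterophily literature; the mean
# morphological features (mm) are synthetic calibration values chosen so that
# surface areas span more than an order of magnitude and both syndromes cover
# the size range.
.default_species <- data.frame(
  species  = c("Crescentia cujete",       "Paragonia pyramidata",
               "Burmeistera tenuiflora",  "Centropogon costaricae",
               "Macrocarpea macrophylla", "Symbolanthus calygonus",
               "Cobaea scandens",         "Cantua quercifolia",
               "Condaminea corymbosa",    "Palicourea guianensis",
               "Merinthopodium neuranthum", "Witheringia sp."),
  code     = c("Cj", "Pp", "Bt", "Cr", "Mm", "Sy", "Cs", "Cq",
               "Cc", "Pg", "Mn", "Ws"),
  family   = rep(c("Bignoniaceae", "Campanulaceae", "Gentianaceae",
                   "Polemoniaceae", "Rubiaceae", "Solanaceae"), each = 2),
  syndrome = rep(c("bat", "other"), 6),
  corolla_length = c(50, 48, 24, 32, 40, 55, 34, 34, 20, 16, 26, 10),
  calyx_length   = c(18, 12,  7,  9, 14, 15, 12, 10,  6,  4, 10,  3),
  inner_depth    = c(40, 38, 19, 26, 32, 45, 27, 28, 16, 13, 21,  6),
  inner_diam_h   = c(45, 30, 12, 14, 30, 32, 24, 18, 10,  7, 16,  8),
  inner_diam_v   = c(45, 30, 12, 14, 30, 32, 24, 18, 10,  7, 16,  8),
  outer_diam_h   = c(55, 50, 16, 22, 40, 50, 36, 30, 15, 11, 24, 16),
  outer_diam_v   = c(55, 50, 16, 22, 40, 50, 36, 30, 15, 11, 24, 16),
  stringsAsFactors = FALSE)

.feature_names <- c("corolla_length", "calyx_length", "inner_depth",
                    "inner_diam_h", "inner_diam_v",
                    "outer_diam_h", "outer_diam_v")

#' Build a species catalog
#'
#' Returns templates for `2 * n_families` species: per family one
#' bat-pollinated and one insect- or bird-pollinated species, with mean
#' morphological features (mm) and a per-species relative-variability target
#' `cv_target`. The default variability is syndrome specific - bat-pollinated
#' flowers are morphologically conserved (`cv_bat = 0.08`) while insect- and
#' bird-pollinated flowers vary more (`cv_other = 0.16`) - with a uniform
#' +/-`cv_jitter` relative jitter around the group value so species differ.
#' When more than six families are requested the default pool is recycled
#' with scaled features.
#'
#' @param seed integer seed (determines the cv jitter and any recycling).
#' @param n_families number of families (two species each).
#' @param cv_bat,cv_other per-syndrome mean cV targets.
#' @param cv_jitter relative jitter applied per species (0 disables).
#' @return data frame of species templates with columns `species`, `code`,
#'   `family`, `syndrome`, the seven mean features, `cv_target` and
#'   `mean_area` (mm^2).
#' @examples
#' cat6 <- make_catalog(seed = 1)
#' table(cat6$syndrome)
#' @export
make_catalog <- function(seed = 1L, n_families = 6L, cv_bat = 0.08,
                         cv_other = 0.16, cv_jitter = 0.2) {
  stopifnot(n_families >= 1, cv_bat >= 0, cv_other >= 0,
            cv_jitter >= 0, cv_jitter < 1)
  with_seed(seed, {
    reps <- ceiling(n_families / 6)
    cat <- do.call(rbind, lapply(seq_len(reps), function(r) {
      x <- .default_species
      if (r > 1) {  # recycled families get scaled copies and new labels
        sc <- 0.75 + 0.5 * runif(1)
        x[, .feature_names] <- x[, .feature_names] * sc
        x$species <- paste0(x$species, " (", r, ")")
        x$code <- paste0(x$code, r)
        x$family <- paste0(x$family, "-", r)
      }
      x
    }))
    cat <- cat[cat$family %in% unique(cat$family)[seq_len(n_families)], ]
    base_cv <- ifelse(cat$syndrome == "bat", cv_bat, cv_other)
    jit <- runif(nrow(cat), 1 - cv_jitter, 1 + cv_jitter)
    cat$cv_target <- base_cv * jit
    cat$mean_area <- surface_area(cat$corolla_length,
                                  cat$inner_diam_h, cat$inner_diam_v,
                                  cat$outer_diam_h, cat$outer_diam_v)
    rownames(cat) <- NULL
    cat
  })
}

#' Sample individual flowers from a catalog
#'
#' Draws `n_per_species` flowers per species. Each feature is drawn as
#' `mean * (1 + cv_target * z)` with `z` standard normal, redrawing any
#' non-positive value (truncation by rejection, at most 100 attempts per
#' value). Surface area is computed from the drawn features with
#' [surface_area()], so the stored area is exactly consistent with the
#' morphology.
#'
#' @param catalog a catalog from [make_catalog()].
#' @param n_per_species flowers per species.
#' @param seed integer seed.
#' @return data frame with one row per flower: `flower_id`, `species`,
#'   `code`, `family`, `syndrome`, the seven features (mm) and
#'   `surface_area` (mm^2).
#' @examples
#' fl <- sample_flowers(make_catalog(seed = 1), n_per_species = 14, seed = 2)
#' nrow(fl)  # 168
#' @export
sample_flowers <- function(catalog, n_per_species = 14L, seed = 1L) {
  stopifnot(n_per_species >= 1)
  with_seed(seed, {
    out <- lapply(seq_len(nrow(catalog)), function(i) {
      tpl <- catalog[i, ]
      feat <- sapply(.feature_names, function(f) {
        mu <- tpl[[f]]
        v <- mu * (1 + tpl$cv_target * rnorm(n_per_species))
        for (j in which(v <= 0)) {
          ok <- FALSE
          for (att in seq_len(100)) {
            cand <- mu * (1 + tpl$cv_target * rnorm(1))
            if (cand > 0) { v[j] <- cand; ok <- TRUE; break }
          }
          if (!ok) stopf("could not draw a positive %s for %s in 100 tries",
                         f, tpl$species)
        }
        v
      })
      feat <- matrix(feat, nrow = n_per_species,
                     dimnames = list(NULL, .feature_names))
      df <- data.frame(
        flower_id = sprintf("%s_%02d", tpl$code, seq_len(n_per_species)),
        species = tpl$species, code = tpl$code, family = tpl$family,
        syndrome = tpl$syndrome, stringsAsFactors = FALSE)
      cbind(df, as.data.frame(feat))
    })
    flowers <- do.call(rbind, out)
    flowers$surface_area <- flower_surface_area(flowers)
    rownames(flowers) <- NULL
    flowers
  })
}
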