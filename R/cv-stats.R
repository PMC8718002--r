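#' Per-species coefficients of variation of band target strength
#'
#' Acoustic analogue of the morphological cV comparison: within each species,
#' the cV of the per-flower band TS values for the four narrow frequency
#' bands. The cV is computed on the linear-power (delogged) scale, where
#' target strength is a positive intensity ratio: a cV of dB values would
#' depend on the arbitrary 0 dB reference (a species whose TS happens to sit
#' near the plate level would get an unbounded cV). For small spreads the
#' linear cV is proportional to the dB standard deviation
#' (`cv ~ ln(10)/10 * sd_dB`), so the species ordering is the same either
#' way wherever both are well defined.
#'
#' @param ts_table per-flower band TS table from [flower_ts_table()].
#' @param bands TS columns to use.
#' @return long data frame (species, syndrome, band, cv) with attribute
#'   `species_mean` as in [species_cv_table()].
#' @export
acoustic_cv_table <- function(ts_table,
                              bands = c("ts_f45", "ts_f68", "ts_f102",
                                        "ts_f153")) {
  bands <- intersect(bands, names(ts_table))
  if (length(bands) == 0) stopf("no band TS columns found")
  rows <- list()
  for (sp in unique(ts_table$species)) {
    sub <- ts_table[ts_table$species == sp, , drop = FALSE]
    if (nrow(sub) < 2) next
    for (b in bands) {
      rows[[length(rows) + 1]] <- data.frame(
        species = sp, syndrome = sub$syndrome[1], band = b,
        cv = coefficient_of_variation(db_to_power(sub[[b]])),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  sm <- aggregate(cv ~ species + syndrome, data = out, FUN = mean)
  names(sm)[names(sm) == "cv"] <- "mean_cv"
  attr(out, "species_mean") <- sm
  out
}

#' Per-syndrome summary of morphological and acoustic variability
#'
#' Group means (over species) of the per-species mean coefficients of
#' variation, for the morphological features and for the band target
#' strengths.
#'
#' @param cv_table output of [species_cv_table()].
#' @param acoustic_table optional output of [acoustic_cv_table()].
#' @return data frame with one row per syndrome and columns
#'   `morphological_cv` and (if supplied) `acoustic_cv`.
#' @export
cv_syndrome_summary <- function(cv_table, acoustic_table = NULL) {
  msm <- attr(cv_table, "species_mean")
  out <- aggregate(mean_cv ~ syndrome, data = msm, FUN = mean)
  names(out)[2] <- "morphological_cv"
  if (!is.null(acoustic_table)) {
    asm <- attr(acoustic_table, "species_mean")
    a <- aggregate(mean_cv ~ syndrome, data = asm, FUN = mean)
    out$acoustic_cv <- a$mean_cv[match(out$syndrome, a$syndrome)]
  }
  out
}
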