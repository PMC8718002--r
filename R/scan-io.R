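#' Write / read an impulse-response scan container
#'
#' Plain-text on-disk container for one flower's scan planes: one CSV matrix
#' of impulse responses per plane (rows = angles) plus a JSON sidecar holding
#' the angle grid, the sample rate and the flower metadata. `write_scan()`
#' creates `<dir>/<flower_id>/`; `read_scan()` reads one plane back as an
#' `ir_scan`.
#'
#' @param scan an `ir_scan` object.
#' @param dir container directory.
#' @return `write_scan()` returns the flower directory invisibly;
#'   `read_scan()` returns an `ir_scan`.
#' @export
write_scan <- function(scan, dir) {
  fdir <- file.path(dir, scan$flower_id)
  dir.create(fdir, recursive = TRUE, showWarnings = FALSE)
  write.csv(scan$irs, file.path(fdir, paste0(scan$plane, ".csv")),
            row.names = FALSE)
  meta_path <- file.path(fdir, "meta.json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  meta$flower_id <- scan$flower_id
  meta$species <- scan$species
  meta$syndrome <- scan$syndrome
  meta$family <- scan$family
  meta$sample_rate <- scan$sample_rate
  meta$angles <- scan$angles
  meta$planes <- union(meta$planes, scan$plane)
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(fdir)
}

#' @rdname write_scan
#' @param flower_id flower directory name inside `dir`.
#' @param plane which plane to read.
#' @export
read_scan <- function(dir, flower_id, plane = c("azimuth", "elevation")) {
  plane <- match.arg(plane)
  fdir <- file.path(dir, flower_id)
  meta <- jsonlite::read_json(file.path(fdir, "meta.json"),
                              simplifyVector = TRUE)
  irs <- as.matrix(read.csv(file.path(fdir, paste0(plane, ".csv"))))
  dimnames(irs) <- NULL
  structure(list(flower_id = meta$flower_id, species = meta$species,
                 syndrome = meta$syndrome, family = meta$family,
                 plane = plane, angles = as.numeric(meta$angles),
                 sample_rate = meta$sample_rate, irs = irs),
            class = "ir_scan")
}
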