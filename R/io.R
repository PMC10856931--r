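# Readers and writers for the scan, source-configuration and anisotropy
# formats. CSV dialect: comma separated, dot decimal, UTF-8, mandatory
# header; units are encoded in the column names (distances cm, rates kHz,
# windows s) to prevent unit drift.

.readCsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, check.names = FALSE, strip.white = TRUE)
}

.requireCols <- function(d, cols, path) {
  miss <- setdiff(cols, names(d))
  if (length(miss))
    stop(sprintf("%s: missing column%s %s", path,
                 if (length(miss) > 1) "s" else "",
                 paste(miss, collapse = ", ")))
}

#' Read / write a laboratory current scan
#'
#' CSV with header `current_mA,gross_counts,dark_counts,window_s`; row
#' order is preserved and validated (strictly increasing currents,
#' non-negative integer counts, positive windows). Violations raise errors
#' naming the offending row.
#'
#' @param path CSV file path.
#' @param threshold,detector metadata attached to the scan.
#' @return [readCurrentScan()]: a [CurrentScan-class].
#' @export
readCurrentScan <- function(path, threshold = 0.5, detector = "unknown") {
  d <- .readCsv(path)
  .requireCols(d, .CURRENT_SCAN_COLS, path)
  bad <- which(d$gross_counts < 0 | d$dark_counts < 0)
  if (length(bad))
    stop(sprintf("%s: negative counts at row %d", path, bad[1]))
  bad <- which(diff(d$current_mA) <= 0)
  if (length(bad))
    stop(sprintf("%s: currents not strictly increasing at row %d", path,
                 bad[1] + 1L))
  currentScan(d[.CURRENT_SCAN_COLS], threshold = threshold,
              detector = detector)
}

#' @param scan a [CurrentScan-class].
#' @rdname readCurrentScan
#' @export
writeCurrentScan <- function(scan, path) {
  utils::write.csv(scan@data[.CURRENT_SCAN_COLS], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read / write a pre-clinical scan series
#'
#' CSV in one of two geometry conventions, never mixed within a file:
#' bench columns `y_cm,z_cm` (sensor on the z axis at z = 0) or polar
#' columns `r_cm,theta_rad`, each followed by `pcr_khz,sigma_khz,window_s`.
#' Bench rows are converted through [yzToPolar()] on read.
#'
#' @param path CSV file path.
#' @param threshold,detector,sourceName metadata attached to the series.
#' @return [readScanSeries()]: a [ScanSeries-class].
#' @export
readScanSeries <- function(path, threshold = 1.5, detector = "unknown",
                           sourceName = "unknown") {
  d <- .readCsv(path)
  bench <- all(c("y_cm", "z_cm") %in% names(d))
  polar <- all(c("r_cm", "theta_rad") %in% names(d))
  if (bench && polar)
    stop(path, ": mixed geometry conventions ((y,z) and (r,theta)) in one file")
  if (!bench && !polar)
    stop(path, ": need either (y_cm, z_cm) or (r_cm, theta_rad) columns")
  .requireCols(d, c("pcr_khz", "sigma_khz", "window_s"), path)
  scanSeries(d, threshold = threshold, detector = detector,
             sourceName = sourceName)
}

#' @param series a [ScanSeries-class].
#' @rdname readScanSeries
#' @export
writeScanSeries <- function(series, path) {
  d <- series@data
  cols <- if (all(c("y_cm", "z_cm") %in% names(d)))
    c("y_cm", "z_cm", "pcr_khz", "sigma_khz", "window_s")
  else .SCAN_SERIES_COLS
  utils::write.csv(d[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an anisotropy look-up table
#'
#' CSV layout following the common published convention: blank first cell,
#' first row the theta grid in degrees, first column the r grid in cm, body
#' the \eqn{F(r,\theta)} values.
#'
#' @param path CSV file path.
#' @return An [AnisotropyTable-class].
#' @export
readAnisotropy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, header = FALSE, check.names = FALSE)
  if (nrow(raw) < 3L || ncol(raw) < 3L)
    stop(path, ": anisotropy grid must be at least 2 x 2")
  thetaGrid <- as.numeric(raw[1, -1])
  rGrid <- as.numeric(raw[-1, 1])
  values <- as.matrix(raw[-1, -1])
  suppressWarnings(mode(values) <- "numeric")
  if (any(is.na(thetaGrid)) || any(is.na(rGrid)) || any(is.na(values)))
    stop(path, ": malformed anisotropy grid (non-numeric entries)")
  anisotropyTable(rGrid, thetaGrid, values)
}

#' @param table an [AnisotropyTable-class].
#' @rdname readAnisotropy
#' @export
writeAnisotropy <- function(table, path) {
  header <- paste(c("", table@thetaGrid), collapse = ",")
  body <- apply(cbind(table@rGrid, table@values), 1, paste, collapse = ",")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a source configuration
#'
#' YAML key-value file with keys `air_kerma_strength`, `dose_rate_constant`,
#' `capsule_length_cm`, `radial_coeffs` (six numbers, the \eqn{a_n} for
#' \eqn{n = -2..3}), `radial_decay`, `anisotropy_file` (path relative to
#' the configuration file, or the string `"point"`), `r0_cm`, `theta0_deg`.
#' Loading re-checks the TG-43 normalisation conventions and warns on
#' \eqn{g(r_0) \ne 1} or a transverse anisotropy row away from 1.
#'
#' @param path YAML file path.
#' @return A [SourceSpec-class].
#' @export
readSourceConfig <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- yaml::read_yaml(path)
  need <- c("air_kerma_strength", "dose_rate_constant", "capsule_length_cm",
            "radial_coeffs", "radial_decay", "anisotropy_file")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop(path, ": missing keys ", paste(miss, collapse = ", "))
  if (length(cfg$radial_coeffs) != 6L)
    stop(path, ": radial_coeffs must hold 6 numbers (n = -2..3)")
  aniso <- if (identical(cfg$anisotropy_file, "point")) "point"
  else readAnisotropy(file.path(dirname(path), cfg$anisotropy_file))
  sourceSpec(airKermaStrength = as.numeric(cfg$air_kerma_strength),
             doseRateConstant = as.numeric(cfg$dose_rate_constant),
             capsuleLength = as.numeric(cfg$capsule_length_cm),
             radialCoeffs = as.numeric(cfg$radial_coeffs),
             radialDecay = as.numeric(cfg$radial_decay),
             anisotropy = aniso,
             r0 = as.numeric(cfg$r0_cm %||% 2),
             theta0 = as.numeric(cfg$theta0_deg %||% 90) * pi / 180)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an analysis report as JSON
#'
#' Serialises a [PerformanceReport-class] (plus arbitrary extra fields,
#' e.g. the calibration factor or the RNG seed of a simulated input) to a
#' JSON file for downstream tooling.
#'
#' @param report a [PerformanceReport-class].
#' @param path output path.
#' @param extra named list merged into the JSON object.
#' @return The path, invisibly.
#' @export
writeReport <- function(report, path, extra = list()) {
  obj <- c(list(mode = report@mode,
                mdr_crossing_cm = report@mdrCrossing,
                mdr_crossing_se_cm = report@mdrCrossingSE,
                checks = report@checks), extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}
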