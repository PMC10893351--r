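#' Write an FID to the JSON interchange format
#'
#' The canonical on-disk form of an FID: a JSON object with fields
#' \code{sw_hz}, \code{n_points}, \code{dwell_s}, \code{ref_offset_hz},
#' optional \code{spectrometer_mhz}, and \code{samples} as an array of
#' [re, im] pairs.  Values are written at full precision so the round trip
#' is lossless.
#'
#' @param fid an \linkS4class{FID}
#' @param path output file path
#' @return \code{path}, invisibly
#' @seealso \code{\link{readFid}}
#' @export
writeFid <- function(fid, path) {
  stopifnot(is(fid, "FID"))
  p <- fid@params
  obj <- list(sw_hz = p@sw, n_points = p@nPoints, dwell_s = p@dwell,
              ref_offset_hz = p@refOffset)
  if (!is.na(p@spectrometerFreq))
    obj$spectrometer_mhz <- p@spectrometerFreq
  obj$samples <- cbind(Re(fid@samples), Im(fid@samples))
  # I(17) = 17 significant digits: enough to round-trip any double exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read an FID from the JSON interchange format
#'
#' Validates the schema field by field and reports violations with the
#' offending field name.  If the stored dwell time disagrees with 1/sw by
#' more than 1e-6 relative, a warning is issued and the dwell is recomputed
#' from the spectral width (quadrature convention).
#'
#' @param path JSON file path
#' @return an \linkS4class{FID}
#' @export
readFid <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  num1 <- function(field, optional = FALSE) {
    v <- obj[[field]]
    if (is.null(v)) {
      if (optional) return(NULL)
      stop("FID interchange: missing field '", field, "'")
    }
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("FID interchange: field '", field,
           "' must be a single finite number")
    v
  }
  sw <- num1("sw_hz")
  n <- num1("n_points")
  dwell <- num1("dwell_s")
  refOffset <- num1("ref_offset_hz")
  mhz <- num1("spectrometer_mhz", optional = TRUE)
  s <- obj$samples
  if (is.null(s)) stop("FID interchange: missing field 'samples'")
  if (!is.matrix(s)) s <- matrix(unlist(s), ncol = 2, byrow = TRUE)
  if (!is.numeric(s) || ncol(s) != 2L)
    stop("FID interchange: field 'samples' must be an array of [re, im] pairs")
  if (nrow(s) != n)
    stop("FID interchange: field 'samples' has ", nrow(s),
         " points but 'n_points' is ", n)
  if (abs(dwell * sw - 1) > 1e-6) {
    warning("FID interchange: dwell_s * sw_hz differs from 1; ",
            "recomputing dwell as 1/sw (quadrature convention)")
  }
  params <- acquisitionParams(sw = sw, nPoints = n, refOffset = refOffset,
                              spectrometerFreq =
                                if (is.null(mhz)) NA_real_ else mhz)
  newFid(complex(real = s[, 1], imaginary = s[, 2]), params)
}

#' Read a peak list from CSV
#'
#' Expected header: \code{amplitude,phase_rad,frequency_hz,t2_s}.
#'
#' @param path CSV file path
#' @return a peak table (see \code{\link{peakTable}})
#' @export
readPeakCsv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("amplitude", "phase_rad", "frequency_hz", "t2_s")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("peak CSV is missing column(s): ", paste(miss, collapse = ", "))
  peakTable(amplitude = d$amplitude, phase = d$phase_rad,
            frequency = d$frequency_hz, t2 = d$t2_s)
}

#' Write a peak list to CSV
#' @param peaks a peak table
#' @param path output file path
#' @return \code{path}, invisibly
#' @export
writePeakCsv <- function(peaks, path) {
  validatePeakTable(peaks)
  utils::write.csv(
    data.frame(amplitude = peaks$amplitude, phase_rad = peaks$phase,
               frequency_hz = peaks$frequency, t2_s = peaks$t2),
    path, row.names = FALSE)
  invisible(path)
}

#' Read a region table from CSV
#'
#' Expected header: \code{label,f_low_hz,f_high_hz}, or
#' \code{label,f_low_ppm,f_high_ppm} with \code{spectrometerFreq} supplied
#' to convert ppm to display Hz (ppm bounds may be given in either order;
#' they are sorted so fLow < fHigh).
#'
#' @param path CSV file path
#' @param spectrometerFreq observe frequency in MHz, required for ppm input
#' @return a region table (see \code{\link{regionTable}})
#' @export
readRegionCsv <- function(path, spectrometerFreq = NA_real_) {
  d <- utils::read.csv(path)
  if (all(c("f_low_hz", "f_high_hz") %in% names(d))) {
    lo <- d$f_low_hz; hi <- d$f_high_hz
  } else if (all(c("f_low_ppm", "f_high_ppm") %in% names(d))) {
    if (is.na(spectrometerFreq))
      stop("region CSV uses ppm columns; spectrometerFreq (MHz) is required")
    lo <- ppmToHz(pmin(d$f_low_ppm, d$f_high_ppm), spectrometerFreq)
    hi <- ppmToHz(pmax(d$f_low_ppm, d$f_high_ppm), spectrometerFreq)
  } else {
    stop("region CSV must have columns label,f_low_hz,f_high_hz ",
         "or label,f_low_ppm,f_high_ppm")
  }
  if (!"label" %in% names(d)) stop("region CSV is missing column 'label'")
  regionTable(label = d$label, fLow = lo, fHigh = hi)
}
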