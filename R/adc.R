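# Voxelwise ADC estimation with background noise-floor correction,
# b-value subsetting and temperature correction of calibrated references.

#' Estimate the background noise floor from a signal-free cuboid
#'
#' Computes the second moment of the magnitude signal over a user-selected
#' background cuboid, pooled across all volumes of the series. For a pure
#' Rayleigh background this converges to `2 * sigma^2`, so subtracting it
#' from squared intensities (see [correctNoiseFloor()]) yields an unbiased
#' estimate of the squared true signal at high SNR.
#'
#' @param dwi a [DWISeries-class] or a 4D array.
#' @param cuboidStart integer(3), 0-based start indices of the cuboid.
#' @param cuboidSize integer(3), cuboid extent in voxels.
#' @return a [NoiseEstimate-class]. A warning is raised when the cuboid has
#'   fewer than 100 voxels (per volume).
#' @export
estimateBackgroundNoise <- function(dwi, cuboidStart, cuboidSize) {
  x <- if (is(dwi, "DWISeries")) seriesData(dwi) else dwi
  stopifnot(length(dim(x)) == 4L)
  cuboidStart <- as.integer(cuboidStart)
  cuboidSize <- as.integer(cuboidSize)
  stopifnot(length(cuboidStart) == 3L, length(cuboidSize) == 3L)
  if (any(cuboidStart < 0L) || any(cuboidSize < 1L) ||
      any(cuboidStart + cuboidSize > dim(x)[1:3]))
    stop("noise cuboid lies outside the volume")
  n <- prod(cuboidSize)
  if (n < 100L)
    warning("noise cuboid has fewer than 100 voxels; the estimate is noisy")
  idx <- lapply(1:3, function(a) (cuboidStart[a] + 1L):(cuboidStart[a] + cuboidSize[a]))
  sub <- x[idx[[1L]], idx[[2L]], idx[[3L]], , drop = FALSE]
  new("NoiseEstimate", etaSq = mean(sub^2), nVoxels = as.integer(n),
      cuboid = list(start = cuboidStart, size = cuboidSize))
}

#' Correct magnitude signal for a uniform background noise floor
#'
#' Applies the power-subtraction correction
#' `S' = sqrt(max(S^2 - etaSq, 0))`. Voxels whose squared signal does not
#' exceed the noise floor are set to 0 and flagged; the ADC fit drops
#' flagged points from the regression instead of clamping them.
#'
#' @param signal non-negative numeric array (any shape).
#' @param noise a [NoiseEstimate-class], or a single `etaSq` value.
#' @return list with `corrected` (same shape as `signal`) and `flagged`
#'   (logical, TRUE where `S^2 <= etaSq`). With `etaSq = 0` the signal is
#'   returned unchanged and nothing is flagged.
#' @examples
#' correctNoiseFloor(100, 400)$corrected  # sqrt(9600) = 97.98
#' @export
correctNoiseFloor <- function(signal, noise) {
  eta <- if (is(noise, "NoiseEstimate")) etaSq(noise) else as.numeric(noise)
  stopifnot(eta >= 0)
  if (eta == 0)
    return(list(corrected = signal,
                flagged = array(FALSE, dim(signal) %||% length(signal))))
  s2 <- signal^2 - eta
  flagged <- s2 <= 0
  corrected <- sqrt(pmax(s2, 0))
  list(corrected = corrected, flagged = flagged)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Voxelwise ADC fit over a b-value subset
#'
#' Estimates the apparent diffusion coefficient per voxel by unweighted
#' ordinary least squares of `log(S')` on b over the selected b-values:
#' slope `= -ADC * 1e-6` (ADC in um^2/s), intercept `= log(S0)`. When a
#' noise estimate is given, every volume is noise-floor corrected first
#' ([correctNoiseFloor()]); replicate acquisitions at the same b-value
#' (e.g. the two PE polarities) are then averaged over their unflagged
#' replicates before taking the logarithm. Voxels with fewer than two
#' usable b-value points (or with no spread in b among them) are marked
#' invalid.
#'
#' @param dwi a [DWISeries-class].
#' @param bSubset numeric, subset of the series b-values to fit; must
#'   contain 0 and at least one other b-value.
#' @param noise optional [NoiseEstimate-class]; `NULL` disables the
#'   noise-floor correction.
#' @return an [ADCMap-class].
#' @examples
#' # two-point closed form: ADC = ln(S0/Sb) / (b * 1e-6)
#' @export
fitADC <- function(dwi, bSubset = NULL, noise = NULL) {
  stopifnot(is(dwi, "DWISeries"))
  bAll <- bValues(dwi)
  if (is.null(bSubset)) bSubset <- sort(unique(bAll))
  if (!all(bSubset %in% bAll))
    stop("bSubset must be a subset of the series b-values")
  if (!any(bSubset == 0)) stop("bSubset must contain b = 0")
  if (length(unique(bSubset)) < 2L)
    stop("bSubset must contain at least two distinct b-values")
  sel <- which(bAll %in% bSubset)
  x <- seriesData(dwi)
  d3 <- dim(x)[1:3]
  nvox <- prod(d3)
  S <- matrix(x[, , , sel, drop = FALSE], nrow = nvox)
  bSel <- bAll[sel]

  eta <- if (is.null(noise)) 0 else etaSq(noise)
  cf <- correctNoiseFloor(S, eta)
  Sc <- cf$corrected
  ok <- !cf$flagged
  nFlagged <- sum(!ok)

  # average unflagged replicates per unique b
  ub <- sort(unique(bSel))
  nb <- length(ub)
  Y <- matrix(NA_real_, nvox, nb)
  usable <- matrix(FALSE, nvox, nb)
  for (j in seq_len(nb)) {
    cols <- which(bSel == ub[j])
    num <- rowSums(Sc[, cols, drop = FALSE] * ok[, cols, drop = FALSE])
    den <- rowSums(ok[, cols, drop = FALSE])
    avg <- ifelse(den > 0, num / pmax(den, 1L), NA_real_)
    usable[, j] <- den > 0 & avg > 0
    Y[, j] <- ifelse(usable[, j], log(avg), NA_real_)
  }

  W <- usable * 1
  n <- rowSums(W)
  bRow <- matrix(ub, nvox, nb, byrow = TRUE)
  Sx <- rowSums(W * bRow)
  Sy <- rowSums(W * Y, na.rm = TRUE)
  Sxx <- rowSums(W * bRow^2)
  Sxy <- rowSums(W * bRow * Y, na.rm = TRUE)
  den <- n * Sxx - Sx^2
  valid <- n >= 2 & den > .Machine$double.eps * pmax(Sxx, 1)
  slope <- ifelse(valid, (n * Sxy - Sx * Sy) / den, NA_real_)
  icept <- ifelse(valid, (Sy - slope * Sx) / pmax(n, 1), NA_real_)

  adc <- array(-slope * 1e6, d3)
  s0 <- array(exp(icept), d3)
  nUsedA <- array(as.integer(n), d3)
  validA <- array(valid & is.finite(-slope), d3)
  new("ADCMap", adc = adc, s0 = s0, nUsed = nUsedA, validMask = validA,
      affine = dwi@affine,
      meta = list(bSubset = ub, etaSq = eta, nFlagged = nFlagged))
}

#' Temperature-correct a calibrated reference ADC
#'
#' Calibrated vial ADC values are specified at fixed temperatures; the
#' reference for an acquisition at another temperature is obtained by
#' linear interpolation between the bracketing calibration temperatures of
#' that vial, as prescribed by phantom calibration sheets.
#'
#' @param vialId vial identifier matching `calibrationTable$vial`.
#' @param tempC acquisition temperature, degrees C; must lie within the
#'   table's temperature range for that vial.
#' @param calibrationTable data.frame with columns `vial`, `temp_c`, `adc`.
#' @return reference ADC in um^2/s.
#' @examples
#' tab <- data.frame(vial = "v1", temp_c = c(15, 25), adc = c(800, 1200))
#' temperatureCorrectReference("v1", 19.5, tab)  # 980
#' @export
temperatureCorrectReference <- function(vialId, tempC, calibrationTable) {
  stopifnot(all(c("vial", "temp_c", "adc") %in% names(calibrationTable)))
  rows <- calibrationTable[calibrationTable$vial == vialId, , drop = FALSE]
  if (nrow(rows) == 0L) stop("vial not found in the calibration table")
  rows <- rows[order(rows$temp_c), , drop = FALSE]
  if (tempC < min(rows$temp_c) || tempC > max(rows$temp_c))
    stop(sprintf("temperature %.1f C outside the calibration range [%.1f, %.1f]",
                 tempC, min(rows$temp_c), max(rows$temp_c)))
  if (nrow(rows) == 1L) return(rows$adc[1L])
  stats::approx(rows$temp_c, rows$adc, xout = tempC, ties = "ordered")$y
}
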