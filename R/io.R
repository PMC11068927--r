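# File formats: NIfTI-1 volumes (via RNifti), FSL-style .bval files,
# marker TSVs and protocol JSON. External representations use 0-based
# voxel indices and 0-based PE axes; the readers/writers convert to the
# package's internal 1-based R conventions.

#' Read and write 3D/4D volumes as NIfTI-1
#'
#' Volumes are written with `datatype = "double"` so numeric data
#' round-trips bit-identically; the voxel size is stored in the NIfTI
#' pixdim fields.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param data numeric array (3D or 4D).
#' @param voxelSize numeric(3), mm.
#' @param datatype NIfTI storage type (e.g. `"double"`, `"float"`).
#' @return `readVolumeNifti`: list with `data` (plain array), `voxelSize`
#'   and `affine` (diagonal, from pixdim).
#' @export
writeVolumeNifti <- function(data, path, voxelSize, datatype = "double") {
  stopifnot(length(dim(data)) %in% c(3L, 4L), length(voxelSize) == 3L)
  im <- RNifti::asNifti(unclass(as.array(data)))
  pd <- if (length(dim(data)) == 4L) c(voxelSize, 1) else voxelSize
  im <- RNifti::`pixdim<-`(im, pd)
  RNifti::writeNifti(im, path, datatype = datatype)
  invisible(path)
}

#' @rdname writeVolumeNifti
#' @export
readVolumeNifti <- function(path) {
  im <- RNifti::readNifti(path)
  arr <- as.array(im)
  attributes(arr) <- list(dim = dim(arr))
  vox <- RNifti::pixdim(im)[1:3]
  list(data = arr, voxelSize = vox, affine = diagAffine(vox))
}

#' Read and write FSL-style b-value files
#'
#' A `.bval` file is a single line of whitespace-separated b-values, one
#' per volume of the accompanying 4D series.
#'
#' @param path file path.
#' @param bValues numeric vector.
#' @return `readBval`: numeric vector.
#' @export
writeBval <- function(bValues, path) {
  writeLines(paste(format(bValues, trim = TRUE, scientific = FALSE),
                   collapse = " "), path)
  invisible(path)
}

#' @rdname writeBval
#' @export
readBval <- function(path) {
  scan(path, what = numeric(), quiet = TRUE)
}

#' Read and write marker sets as TSV
#'
#' Tab-separated with a header: columns `id`, `i`, `j`, `k` (0-based grid
#' indices), `x_mm`, `y_mm`, `z_mm`, and for detected sets `score` and
#' `missing`.
#'
#' @param markers a [MarkerSet-class].
#' @param path file path.
#' @return `readMarkersTSV`: a [MarkerSet-class].
#' @export
writeMarkersTSV <- function(markers, path) {
  utils::write.table(as.data.frame(markers), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMarkersTSV
#' @export
readMarkersTSV <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "i", "j", "k", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df)))
    stop("marker TSV must have columns id, i, j, k, x_mm, y_mm, z_mm")
  n <- nrow(df)
  new("MarkerSet",
      ids = as.character(df$id),
      gridIndex = cbind(as.integer(df$i), as.integer(df$j), as.integer(df$k)),
      posMm = cbind(df$x_mm, df$y_mm, df$z_mm),
      score = if ("score" %in% names(df)) as.numeric(df$score)
              else rep(NA_real_, n),
      missing = if ("missing" %in% names(df)) as.logical(df$missing)
                else rep(FALSE, n))
}

#' Read and write acquisition protocols as JSON
#'
#' The JSON representation uses the external conventions: `pe_axis` is
#' 0-based (0, 1 or 2); all other fields carry their physical units
#' (`b_values` s/mm^2, `bw_pe_px` Hz/px, `voxel_size` mm,
#' `resonance_hz` Hz).
#'
#' @param protocol an [AcquisitionProtocol-class].
#' @param path file path.
#' @return `readProtocolJson`: an [AcquisitionProtocol-class].
#' @export
writeProtocolJson <- function(protocol, path) {
  obj <- list(
    b_values = bValues(protocol),
    pe_axis = peAxis(protocol) - 1L,
    pe_sign = protocol@peSign,
    bw_pe_px = bwPePx(protocol),
    voxel_size = voxelSize(protocol),
    resonance_hz = resonanceHz(protocol)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeProtocolJson
#' @export
readProtocolJson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("b_values", "pe_axis", "pe_sign", "bw_pe_px", "voxel_size",
            "resonance_hz")
  miss <- setdiff(need, names(obj))
  if (length(miss))
    stop("protocol JSON is missing keys: ", paste(miss, collapse = ", "))
  acquisitionProtocol(obj$b_values, peAxis = obj$pe_axis + 1L,
                      peSign = obj$pe_sign, bwPePx = obj$bw_pe_px,
                      voxelSize = obj$voxel_size,
                      resonanceHz = obj$resonance_hz)
}

#' Read a DWI series from NIfTI + .bval + protocol JSON
#'
#' Validates that the number of b-values matches the 4th data dimension
#' and that the protocol invariants hold (b = 0 present, positive
#' bandwidth, ...).
#'
#' @param niftiPath 4D NIfTI file.
#' @param bvalPath FSL-style b-value file.
#' @param protocol an [AcquisitionProtocol-class] or the path to a
#'   protocol JSON.
#' @param peSigns optional integer vector of per-volume PE polarities
#'   (defaults to the protocol's polarity for all volumes).
#' @return a [DWISeries-class].
#' @export
readDWISeries <- function(niftiPath, bvalPath, protocol, peSigns = NULL) {
  if (is.character(protocol)) protocol <- readProtocolJson(protocol)
  vol <- readVolumeNifti(niftiPath)
  if (length(dim(vol$data)) != 4L) stop("expected a 4D NIfTI series")
  bv <- readBval(bvalPath)
  if (length(bv) != dim(vol$data)[4L])
    stop("number of b-values does not match the number of volumes")
  if (!any(bv == 0)) stop("series must include a b = 0 volume")
  if (is.null(peSigns)) peSigns <- rep(protocol@peSign, length(bv))
  new("DWISeries", data = vol$data, bValues = bv,
      peSigns = as.integer(peSigns), protocol = protocol,
      affine = diagAffine(voxelSize(protocol)))
}

#' Write a DWI series as NIfTI + .bval (+ protocol JSON)
#'
#' @param dwi a [DWISeries-class].
#' @param prefix output path prefix; writes `<prefix>.nii.gz`,
#'   `<prefix>.bval` and `<prefix>_protocol.json`.
#' @return invisibly, the written file paths.
#' @export
writeDWISeries <- function(dwi, prefix) {
  paths <- c(nifti = paste0(prefix, ".nii.gz"),
             bval = paste0(prefix, ".bval"),
             protocol = paste0(prefix, "_protocol.json"))
  writeVolumeNifti(seriesData(dwi), paths["nifti"], voxelSize(dwi))
  writeBval(bValues(dwi), paths["bval"])
  writeProtocolJson(protocol(dwi), paths["protocol"])
  invisible(paths)
}

#' Write an ADC map to NIfTI with a JSON sidecar
#'
#' The ADC volume is written in um^2/s as float32 (NIfTI has no ADC unit
#' slot; the unit is recorded in the sidecar together with the fit
#' metadata), plus the fitted S0 and the valid-fit mask.
#'
#' @param adcMap an [ADCMap-class].
#' @param dir output directory (created if needed).
#' @param voxelSize numeric(3), mm.
#' @return invisibly, the written file paths.
#' @export
writeADCMap <- function(adcMap, dir, voxelSize) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  a <- adcValues(adcMap)
  a[!validMask(adcMap)] <- 0
  s0 <- s0Values(adcMap)
  s0[!validMask(adcMap)] <- 0
  paths <- c(adc = file.path(dir, "adc.nii.gz"),
             s0 = file.path(dir, "s0.nii.gz"),
             mask = file.path(dir, "valid_mask.nii.gz"),
             meta = file.path(dir, "adc_fit.json"))
  writeVolumeNifti(a, paths["adc"], voxelSize, datatype = "float")
  writeVolumeNifti(s0, paths["s0"], voxelSize, datatype = "float")
  writeVolumeNifti(validMask(adcMap) * 1, paths["mask"], voxelSize,
                   datatype = "uint8")
  meta <- fitMeta(adcMap)
  meta$units <- "um^2/s"
  jsonlite::write_json(meta, paths["meta"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
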