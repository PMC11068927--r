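# Generics and accessor methods. Slot access goes through these everywhere.

#' @rdname DWISeries-class
#' @param x,object an object of the documented class
#' @export
setGeneric("bValues", function(x) standardGeneric("bValues"))

#' @rdname DWISeries-class
#' @export
setMethod("bValues", "AcquisitionProtocol", function(x) x@bValues)

#' @rdname DWISeries-class
#' @export
setMethod("bValues", "DWISeries", function(x) x@bValues)

#' @rdname DWISeries-class
#' @export
setGeneric("seriesData", function(x) standardGeneric("seriesData"))

#' @rdname DWISeries-class
#' @export
setMethod("seriesData", "DWISeries", function(x) x@data)

#' @rdname DWISeries-class
#' @export
setGeneric("protocol", function(x) standardGeneric("protocol"))

#' @rdname DWISeries-class
#' @export
setMethod("protocol", "DWISeries", function(x) x@protocol)

#' @rdname DWISeries-class
#' @export
setGeneric("peSigns", function(x) standardGeneric("peSigns"))

#' @rdname DWISeries-class
#' @export
setMethod("peSigns", "DWISeries", function(x) x@peSigns)

#' @rdname DWISeries-class
#' @export
setGeneric("affine", function(x) standardGeneric("affine"))

#' @rdname DWISeries-class
#' @export
setMethod("affine", "DWISeries", function(x) x@affine)

#' @rdname Scene-class
#' @param x,object an object of the documented class
#' @export
setMethod("affine", "Scene", function(x) x@affine)

#' @rdname FieldMap-class
#' @param x,object an object of the documented class
#' @export
setMethod("affine", "FieldMap", function(x) x@affine)

#' @rdname ADCMap-class
#' @param x,object an object of the documented class
#' @export
setMethod("affine", "ADCMap", function(x) x@affine)

#' @rdname AcquisitionProtocol-class
#' @param x,object an object of the documented class
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname AcquisitionProtocol-class
#' @export
setMethod("voxelSize", "AcquisitionProtocol", function(x) x@voxelSize)

#' @rdname AcquisitionProtocol-class
#' @export
setMethod("voxelSize", "DWISeries", function(x) x@protocol@voxelSize)

#' @rdname AcquisitionProtocol-class
#' @export
setGeneric("peAxis", function(x) standardGeneric("peAxis"))

#' @rdname AcquisitionProtocol-class
#' @export
setMethod("peAxis", "AcquisitionProtocol", function(x) x@peAxis)

#' @rdname DisplacementField1D-class
#' @param x,object an object of the documented class
#' @export
setMethod("peAxis", "DisplacementField1D", function(x) x@peAxis)

#' @rdname AcquisitionProtocol-class
#' @export
setGeneric("bwPePx", function(x) standardGeneric("bwPePx"))

#' @rdname AcquisitionProtocol-class
#' @export
setMethod("bwPePx", "AcquisitionProtocol", function(x) x@bwPePx)

#' @rdname AcquisitionProtocol-class
#' @export
setGeneric("resonanceHz", function(x) standardGeneric("resonanceHz"))

#' @rdname AcquisitionProtocol-class
#' @export
setMethod("resonanceHz", "AcquisitionProtocol", function(x) x@resonanceHz)

#' @rdname Scene-class
#' @export
setGeneric("labelMap", function(x) standardGeneric("labelMap"))

#' @rdname Scene-class
#' @export
setMethod("labelMap", "Scene", function(x) x@labelMap)

#' @rdname Scene-class
#' @export
setGeneric("tissueParams", function(x) standardGeneric("tissueParams"))

#' @rdname Scene-class
#' @export
setMethod("tissueParams", "Scene", function(x) x@tissueParams)

#' @rdname Scene-class
#' @export
setGeneric("sceneMeta", function(x) standardGeneric("sceneMeta"))

#' @rdname Scene-class
#' @export
setMethod("sceneMeta", "Scene", function(x) x@meta)

#' @rdname FieldMap-class
#' @export
setGeneric("fieldValues", function(x) standardGeneric("fieldValues"))

#' @rdname FieldMap-class
#' @export
setMethod("fieldValues", "FieldMap", function(x) x@values)

#' @rdname DisplacementField1D-class
#' @export
setMethod("fieldValues", "DisplacementField1D", function(x) x@values)

#' @rdname ADCMap-class
#' @export
setGeneric("adcValues", function(x) standardGeneric("adcValues"))

#' @rdname ADCMap-class
#' @export
setMethod("adcValues", "ADCMap", function(x) x@adc)

#' @rdname ADCMap-class
#' @export
setGeneric("s0Values", function(x) standardGeneric("s0Values"))

#' @rdname ADCMap-class
#' @export
setMethod("s0Values", "ADCMap", function(x) x@s0)

#' @rdname ADCMap-class
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' @rdname ADCMap-class
#' @export
setMethod("validMask", "ADCMap", function(x) x@validMask)

#' @rdname ADCMap-class
#' @export
setGeneric("nUsed", function(x) standardGeneric("nUsed"))

#' @rdname ADCMap-class
#' @export
setMethod("nUsed", "ADCMap", function(x) x@nUsed)

#' @rdname ADCMap-class
#' @export
setGeneric("fitMeta", function(x) standardGeneric("fitMeta"))

#' @rdname ADCMap-class
#' @export
setMethod("fitMeta", "ADCMap", function(x) x@meta)

#' @rdname NoiseEstimate-class
#' @param x,object an object of the documented class
#' @export
setGeneric("etaSq", function(x) standardGeneric("etaSq"))

#' @rdname NoiseEstimate-class
#' @export
setMethod("etaSq", "NoiseEstimate", function(x) x@etaSq)

#' @rdname MarkerSet-class
#' @param x,object an object of the documented class
#' @export
setGeneric("markerIds", function(x) standardGeneric("markerIds"))

#' @rdname MarkerSet-class
#' @export
setMethod("markerIds", "MarkerSet", function(x) x@ids)

#' @rdname MarkerSet-class
#' @export
setGeneric("gridIndex", function(x) standardGeneric("gridIndex"))

#' @rdname MarkerSet-class
#' @export
setMethod("gridIndex", "MarkerSet", function(x) x@gridIndex)

#' @rdname MarkerSet-class
#' @export
setGeneric("markerPositions", function(x) standardGeneric("markerPositions"))

#' @rdname MarkerSet-class
#' @export
setMethod("markerPositions", "MarkerSet", function(x) x@posMm)

#' @rdname MarkerSet-class
#' @export
setGeneric("detectionScores", function(x) standardGeneric("detectionScores"))

#' @rdname MarkerSet-class
#' @export
setMethod("detectionScores", "MarkerSet", function(x) x@score)

#' @rdname MarkerSet-class
#' @export
setGeneric("isMissing", function(x) standardGeneric("isMissing"))

#' @rdname MarkerSet-class
#' @export
setMethod("isMissing", "MarkerSet", function(x) x@missing)

#' @rdname RigidTransform-class
#' @param x,object an object of the documented class
#' @export
setGeneric("rotation", function(x) standardGeneric("rotation"))

#' @rdname RigidTransform-class
#' @export
setMethod("rotation", "RigidTransform", function(x) x@rotation)

#' @rdname RigidTransform-class
#' @export
setGeneric("translation", function(x) standardGeneric("translation"))

#' @rdname RigidTransform-class
#' @export
setMethod("translation", "RigidTransform", function(x) x@translation)

#' @rdname DistortionReport-class
#' @param x,object an object of the documented class
#' @export
setGeneric("meanDistortion", function(x) standardGeneric("meanDistortion"))

#' @rdname DistortionReport-class
#' @export
setMethod("meanDistortion", "DistortionReport", function(x) x@meanMm)

#' @rdname DistortionReport-class
#' @export
setGeneric("maxDistortion", function(x) standardGeneric("maxDistortion"))

#' @rdname DistortionReport-class
#' @export
setMethod("maxDistortion", "DistortionReport", function(x) x@maxMm)

#' @rdname DistortionReport-class
#' @export
setGeneric("perMarkerTable", function(x) standardGeneric("perMarkerTable"))

#' @rdname DistortionReport-class
#' @export
setMethod("perMarkerTable", "DistortionReport", function(x) x@perMarker)

# ---- coercions ----

#' @rdname MarkerSet-class
#' @param row.names,optional,... passed on as in [base::as.data.frame]
#' @export
as.data.frame.MarkerSet <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(
    id = x@ids,
    i = x@gridIndex[, 1L], j = x@gridIndex[, 2L], k = x@gridIndex[, 3L],
    x_mm = x@posMm[, 1L], y_mm = x@posMm[, 2L], z_mm = x@posMm[, 3L],
    score = x@score, missing = x@missing,
    stringsAsFactors = FALSE, row.names = row.names
  )
}

#' @rdname VOISummary-class
#' @param x,object an object of the documented class
#' @param row.names,optional,... passed on as in [base::as.data.frame]
#' @export
as.data.frame.VOISummary <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(mean = x@mean, median = x@median, sd = x@sd,
             np_skew = x@npSkew, n = x@n, row.names = row.names)
}

# ---- show methods ----

setMethod("show", "AcquisitionProtocol", function(object) {
  cat("AcquisitionProtocol\n")
  cat("  b-values (s/mm^2):", paste(object@bValues, collapse = ", "), "\n")
  cat(sprintf("  PE axis %d, sign %+d, bandwidth %.1f Hz/px\n",
              object@peAxis, object@peSign, object@bwPePx))
  cat(sprintf("  voxel %.2f x %.2f x %.2f mm, resonance %.3f MHz\n",
              object@voxelSize[1], object@voxelSize[2], object@voxelSize[3],
              object@resonanceHz / 1e6))
})

setMethod("show", "DWISeries", function(object) {
  d <- dim(object@data)
  cat(sprintf("DWISeries: %d x %d x %d voxels, %d volumes\n",
              d[1], d[2], d[3], d[4]))
  cat("  b-values:", paste(object@bValues, collapse = ", "), "\n")
  cat("  PE signs:", paste(sprintf("%+d", object@peSigns), collapse = ", "), "\n")
})

setMethod("show", "Scene", function(object) {
  d <- dim(object@labelMap)
  cat(sprintf("Scene: %d x %d x %d voxels, %d tissue label(s)\n",
              d[1], d[2], d[3], nrow(object@tissueParams)))
  print(object@tissueParams, row.names = FALSE)
})

setMethod("show", "FieldMap", function(object) {
  r <- range(object@values)
  cat(sprintf("FieldMap: %s voxels, range [%.2f, %.2f] Hz\n",
              paste(dim(object@values), collapse = " x "), r[1], r[2]))
})

setMethod("show", "DisplacementField1D", function(object) {
  r <- range(object@values)
  cat(sprintf("DisplacementField1D (PE axis %d): range [%.3f, %.3f] px\n",
              object@peAxis, r[1], r[2]))
})

setMethod("show", "ADCMap", function(object) {
  v <- object@validMask
  cat(sprintf("ADCMap: %s voxels, %d valid\n",
              paste(dim(object@adc), collapse = " x "), sum(v)))
  if (any(v))
    cat(sprintf("  ADC range (valid): [%.1f, %.1f] um^2/s\n",
                min(object@adc[v]), max(object@adc[v])))
})

setMethod("show", "NoiseEstimate", function(object) {
  cat(sprintf("NoiseEstimate: etaSq = %.3f (%d voxels)\n",
              object@etaSq, object@nVoxels))
})

setMethod("show", "MarkerSet", function(object) {
  cat(sprintf("MarkerSet: %d markers (%d missing)\n",
              length(object@ids), sum(object@missing)))
})

setMethod("show", "RigidTransform", function(object) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(object@rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("RigidTransform: rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm\n",
              ang, object@translation[1], object@translation[2],
              object@translation[3]))
})

setMethod("show", "DistortionReport", function(object) {
  cat(sprintf("DistortionReport: mean %.3f mm, max %.3f mm (%d/%d markers)\n",
              object@meanMm, object@maxMm, object@nDetected,
              object@nReference))
})

setMethod("show", "VOISummary", function(object) {
  cat(sprintf(
    "VOISummary: mean %.1f, median %.1f, sd %.1f um^2/s, np skew %.3f (n = %d)\n",
    object@mean, object@median, object@sd, object@npSkew, object@n))
})
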