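# Shared fixture builders (all generated in code; no stored data).

# small isotropic protocol for warp/field tests
testProtocol <- function(voxel = 2, bw = 1352, bValues = c(0, 800)) {
  acquisitionProtocol(bValues, peAxis = 2L, peSign = 1L, bwPePx = bw,
                      voxelSize = rep(voxel, 3), resonanceHz = 14.707e6)
}

# smooth box object with soft edges, suitable for CDF-matching tests
smoothBoxObject <- function(dims = c(24, 24, 8)) {
  img <- array(0, dims)
  img[6:(dims[1] - 6), 6:(dims[2] - 6), 3:(dims[3] - 2)] <- 1
  gaussSmooth3D(img, c(0.8, 0.8, 0.8))
}

# mono-exponential single-voxel series wrapped as a DWISeries
seriesFromSignal <- function(signal, bValues, voxel = c(3, 3, 6),
                             peSigns = NULL) {
  nb <- length(bValues)
  stopifnot(is.matrix(signal) || length(signal) == nb)
  data <- array(rep(signal, each = 1), c(1, 1, 1, nb))
  p <- acquisitionProtocol(sort(unique(bValues)), peAxis = 2L, peSign = 1L,
                           bwPePx = 1352, voxelSize = voxel,
                           resonanceHz = 14.707e6)
  if (is.null(peSigns)) peSigns <- rep(1L, nb)
  new("DWISeries", data = data, bValues = bValues, peSigns = peSigns,
      protocol = p, affine = diagAffine(voxel))
}

# minimal scene: one 2x2x1 patch per label row
newSceneForTest <- function(tissueParams, voxel = c(3, 3, 6)) {
  n <- nrow(tissueParams)
  lab <- array(0L, c(2L * n, 2L, 1L))
  for (i in seq_len(n)) lab[(2L * i - 1L):(2L * i), , 1L] <- tissueParams$label[i]
  new("Scene", labelMap = lab, tissueParams = tissueParams,
      affine = diagAffine(voxel), meta = list())
}

writeLinesToFile <- function(dir, text) {
  f <- file.path(dir, "tmp.tsv")
  writeLines(text, f)
  f
}

# rotation matrix about z
rotZ <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}
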