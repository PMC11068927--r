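# Low-level numerical helpers: affines, separable Gaussian smoothing,
# windowed box sums, and mass-conserving 1D line resampling.

#' Diagonal voxel-to-world affine
#'
#' Builds the 4x4 affine mapping 0-based voxel indices to world mm for an
#' axis-aligned image: `world = index * voxelSize + origin` (voxel centres).
#'
#' @param voxelSize numeric(3), voxel edge lengths in mm.
#' @param origin numeric(3), world position (mm) of voxel (0, 0, 0).
#' @return 4x4 numeric matrix.
#' @export
diagAffine <- function(voxelSize, origin = c(0, 0, 0)) {
  stopifnot(length(voxelSize) == 3L, all(voxelSize > 0), length(origin) == 3L)
  A <- diag(c(voxelSize, 1))
  A[1:3, 4L] <- origin
  A
}

#' Convert between voxel indices and world coordinates
#'
#' Voxel indices are 0-based and continuous (voxel centres at integers).
#'
#' @param affine 4x4 voxel-to-world matrix.
#' @param ijk,xyz numeric vector of length 3 or an n x 3 matrix.
#' @return n x 3 matrix of converted coordinates.
#' @export
voxelToWorld <- function(affine, ijk) {
  ijk <- rbind2mat(ijk)
  t(affine %*% rbind(t(ijk), 1))[, 1:3, drop = FALSE]
}

#' @rdname voxelToWorld
#' @export
worldToVoxel <- function(affine, xyz) {
  xyz <- rbind2mat(xyz)
  t(solve(affine) %*% rbind(t(xyz), 1))[, 1:3, drop = FALSE]
}

rbind2mat <- function(x) {
  if (is.null(dim(x))) matrix(x, ncol = 3L) else as.matrix(x)
}

# World-mm coordinates of every voxel centre along one axis (0-based index
# scale), for a diagonal affine.
axisCoordsMm <- function(affine, dim3, axis) {
  idx <- seq_len(dim3[axis]) - 1
  affine[axis, axis] * idx + affine[axis, 4L]
}

#' Separable Gaussian smoothing of a 3D array
#'
#' Convolves each axis with a normalized Gaussian kernel (radius 3 sigma),
#' using replicate padding at the edges. Axes with `sigmaVox = 0` are left
#' untouched.
#'
#' @param arr 3D numeric array.
#' @param sigmaVox numeric(3), kernel standard deviation per axis in voxels.
#' @return smoothed array of the same dimensions.
#' @export
gaussSmooth3D <- function(arr, sigmaVox) {
  stopifnot(length(dim(arr)) == 3L)
  sigmaVox <- rep_len(sigmaVox, 3L)
  for (ax in 1:3) {
    if (sigmaVox[ax] <= 0) next
    arr <- axisConvolve(arr, ax, gaussianKernel1D(sigmaVox[ax]))
  }
  arr
}

gaussianKernel1D <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-r):r / sigma)^2)
  k / sum(k)
}

# Convolve along one axis with replicate padding; kernel must be odd-length.
axisConvolve <- function(arr, axis, kernel) {
  d <- dim(arr)
  r <- (length(kernel) - 1L) %/% 2L
  perm <- c(axis, setdiff(1:3, axis))
  M <- matrix(aperm(arr, perm), nrow = d[axis])
  n <- nrow(M)
  pad <- rbind(M[rep(1L, r), , drop = FALSE], M, M[rep(n, r), , drop = FALSE])
  out <- matrix(0, n, ncol(M))
  for (t in seq_along(kernel))  # small kernel: loop over taps, vectorized rows
    out <- out + kernel[t] * pad[t:(t + n - 1L), , drop = FALSE]
  aperm(array(out, d[perm]), order(perm))
}

# Windowed sum along each axis (moving box filter of size w, "valid" output):
# result dim = dim(arr) - w + 1. Exact via cumulative sums.
boxSumValid <- function(arr, w) {
  d <- dim(arr)
  stopifnot(length(w) == length(d), all(w >= 1L), all(w <= d))
  for (ax in seq_along(d)) {
    dc <- dim(arr)
    perm <- c(ax, setdiff(seq_along(d), ax))
    M <- matrix(aperm(arr, perm), nrow = dc[ax])
    C <- rbind(0, apply(M, 2L, cumsum))
    n <- dc[ax]; wa <- w[ax]
    S <- C[(wa + 1L):(n + 1L), , drop = FALSE] - C[1:(n - wa + 1L), , drop = FALSE]
    newd <- dc[perm]; newd[1L] <- n - wa + 1L
    arr <- aperm(array(S, newd), order(perm))
  }
  arr
}

# Mass-conserving resampling of one line under a displacement of its
# content. `line` has n samples at 0-based centres 0..n-1; `dCenters` gives
# the displacement (in pixels, positive = towards higher index) of the
# material at each centre. Pixel edges are transported and the cumulative
# intensity re-read at the original edges, so the integral over any PE
# segment is conserved up to mass leaving the field of view.
warpLineConserve <- function(line, dCenters) {
  n <- length(line)
  edges <- (0:n) - 0.5
  dEdges <- c(dCenters[1L],
              (dCenters[-n] + dCenters[-1L]) / 2,
              dCenters[n])
  y <- edges + dEdges
  if (any(diff(y) <= 0))
    stop("EPI warp folds over: displacement gradient along PE <= -1 px/px")
  if (max(abs(dCenters)) > n)
    stop("EPI warp displacement exceeds the image extent")
  Cin <- c(0, cumsum(line))
  Cout <- stats::approx(y, Cin, xout = edges,
                        yleft = 0, yright = Cin[n + 1L])$y
  diff(Cout)
}

# Apply warpLineConserve along `axis` of a 3D volume with a voxelwise
# displacement array (pixels).
applyDisplacementVolume <- function(vol, dpx, axis) {
  stopifnot(identical(dim(vol), dim(dpx)))
  d <- dim(vol)
  perm <- c(axis, setdiff(1:3, axis))
  V <- matrix(aperm(vol, perm), nrow = d[axis])
  D <- matrix(aperm(dpx, perm), nrow = d[axis])
  out <- V
  for (j in seq_len(ncol(V))) {
    dj <- D[, j]
    if (all(dj == 0)) next
    out[, j] <- warpLineConserve(V[, j], dj)
  }
  aperm(array(out, d[perm]), order(perm))
}

# Fraction of each voxel (centres `x`, width `w`) covered by the nearest
# of a set of slabs of thickness `t` centred at `pos`. Slabs are assumed
# not to overlap within one voxel.
slabCoverage1D <- function(x, w, pos, t) {
  vapply(x, function(xc) {
    p <- pos[which.min(abs(xc - pos))]
    lo <- max(xc - w / 2, p - t / 2)
    hi <- min(xc + w / 2, p + t / 2)
    max(0, hi - lo) / w
  }, numeric(1))
}

# Deterministic sub-seed derivation: keeps every derived seed a valid
# 32-bit integer so a single top-level seed drives all randomness.
deriveSeed <- function(seed, k) {
  s <- (as.numeric(seed) %% 1000003) * 1009 + as.numeric(k) * 9176 + 17
  as.integer(s %% 2147483647)
}
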