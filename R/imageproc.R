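# Preprocessing of microCT-like stacks: bit-depth conversion, Gaussian
# filtering, global-threshold segmentation with despeckle, half resampling,
# external-contour masking and best-fit sphere extraction.

#' Convert a floating-point volume to 8-bit
#'
#' Linearly maps the window `[lo, hi]` to `[0, 255]`, clips outside the
#' window, and rounds half-up.
#'
#' @param vol An [image_volume()] (any value range).
#' @param window Numeric length-2, `c(lo, hi)` with `hi > lo`.
#' @return An 8-bit [image_volume()].
#' @export
to_8bit <- function(vol, window) {
  stopifnot(inherits(vol, "image_volume"))
  lo <- window[1]; hi <- window[2]
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo)
    stop("degenerate window: need hi > lo")
  x <- (vol$data - lo) / (hi - lo) * 255
  x[x < 0] <- 0
  x[x > 255] <- 255
  # round half-up (base round() is half-to-even)
  x <- floor(x + 0.5)
  image_volume(x, vol$voxel_size)
}

#' Segment bone by Gaussian filtering, global threshold and despeckle
#'
#' Applies a Gaussian filter with the kernel truncated at `support` voxels,
#' keeps voxels at or above the global grey threshold, then despeckles by
#' retaining only the largest 26-connected foreground component. Defaults
#' follow common practice for 39 um femoral-head scans: support 1 voxel,
#' sigma 0.5 voxel, threshold 110 GSV.
#'
#' @param vol 8-bit [image_volume()].
#' @param sigma Gaussian sigma in voxels.
#' @param support Kernel truncation radius in voxels.
#' @param threshold Global grey threshold (GSV); voxels `>= threshold` are bone.
#' @return A [binary_mask()] of the bone phase.
#' @export
segment_bone <- function(vol, sigma = 0.5, support = 1, threshold = 110) {
  stopifnot(inherits(vol, "image_volume"))
  d <- dim(vol$data)
  sm <- cpp_gaussian_blur(vol$data, d, sigma, as.integer(support))
  fg <- sm >= threshold
  if (!any(fg))
    stop("empty segmentation: no voxel reaches threshold ", threshold, " GSV")
  keep <- cpp_largest_component(fg, d)
  binary_mask(keep, vol$voxel_size)
}

#' Downsample a volume by a factor of 0.5
#'
#' Halves each axis (floor) by 2x2x2 block averaging, which equals linear
#' interpolation at half-sample offsets and keeps the operation isotropic;
#' `xy_only = TRUE` restricts the averaging to within-slice 2x2 blocks
#' (strict slice-wise bilinear) while still dropping every other slice pair
#' by in-plane means of both slices. The voxel size doubles.
#'
#' @param vol An [image_volume()].
#' @param xy_only Average only within slices (see above).
#' @return An [image_volume()] at twice the voxel size.
#' @export
resample_half <- function(vol, xy_only = FALSE) {
  stopifnot(inherits(vol, "image_volume"))
  d <- dim(vol$data)
  if (any(d < 2)) stop("need at least 2 voxels per axis")
  if (!xy_only) {
    out <- cpp_block_halve(vol$data, d)
  } else {
    m <- d %/% 2
    out <- array(0, m)
    a <- vol$data
    for (k in seq_len(m[3])) {
      sl <- a[, , 2 * k - 1]
      out[, , k] <- (sl[seq(1, 2 * m[1], 2), seq(1, 2 * m[2], 2)] +
                     sl[seq(2, 2 * m[1], 2), seq(1, 2 * m[2], 2)] +
                     sl[seq(1, 2 * m[1], 2), seq(2, 2 * m[2], 2)] +
                     sl[seq(2, 2 * m[1], 2), seq(2, 2 * m[2], 2)]) / 4
    }
  }
  image_volume(out, 2 * vol$voxel_size)
}

#' Build a solid external-contour mask of the bone
#'
#' Morphological closing with a ball structuring element (dilation then
#' erosion, both by Euclidean distance), followed by filling of fully
#' enclosed cavities. The result is a solid mask containing the trabecular
#' network, suitable for restricting DVC registration to the specimen.
#'
#' @param bone A [binary_mask()] of the segmented bone.
#' @param closing_radius Ball radius in voxels; should be at least half the
#'   largest marrow-space width to bridge across pores.
#' @return A solid [binary_mask()] (always a superset of `bone`).
#' @export
bone_contour_mask <- function(bone, closing_radius = 5) {
  stopifnot(inherits(bone, "binary_mask"))
  d <- dim(bone$data)
  faces_touched <- c(any(bone$data[1, , ]), any(bone$data[d[1], , ]),
                     any(bone$data[, 1, ]), any(bone$data[, d[2], ]),
                     any(bone$data[, , 1]), any(bone$data[, , d[3]]))
  if (all(faces_touched))
    warning("mask touches all six volume faces; closing may clip at borders")
  # dilation: distance-to-foreground <= r; erosion: keep where
  # distance-to-background > r
  dil <- cpp_edt(!bone$data, d) <= closing_radius
  ero <- cpp_edt(dil, d) > closing_radius
  filled <- cpp_fill_holes(ero | bone$data, d)
  binary_mask(filled, bone$voxel_size)
}

#' Fit a sphere to the boundary of a mask
#'
#' Least-squares sphere through the mask's boundary voxels (foreground voxels
#' with at least one 6-neighbour in the background): an algebraic (Pratt-style
#' linear) fit followed by geometric Gauss-Newton refinement of
#' `sum((|x - c| - r)^2)`. Used to delimit the trabecular analysis region of
#' a femoral head: the slice containing the fitted center is taken as the
#' lowest slice of the region (see [region_from_sphere()]).
#'
#' @param mask A nonempty [binary_mask()] (typically the solid contour mask).
#' @return A list of class `sphere_fit` with `center` (0-based voxel
#'   coordinates), `radius_vox`, `radius_um` and `rms_residual_um`.
#' @export
best_fit_sphere <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  a <- mask$data
  d <- dim(a)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- a
  interior <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] & pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] & pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] & pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  boundary <- a & !interior
  idx <- which(boundary, arr.ind = TRUE) - 1  # 0-based voxel coordinates
  if (nrow(idx) < 10)
    stop("need at least 10 boundary voxels for a sphere fit (got ",
         nrow(idx), ")")
  X <- idx[, 1]; Y <- idx[, 2]; Z <- idx[, 3]
  A <- cbind(2 * X, 2 * Y, 2 * Z, 1)
  b <- X^2 + Y^2 + Z^2
  beta <- qr.solve(A, b)
  ctr <- beta[1:3]
  r <- sqrt(beta[4] + sum(ctr^2))
  # geometric refinement
  obj <- function(p) {
    rr <- sqrt((X - p[1])^2 + (Y - p[2])^2 + (Z - p[3])^2)
    sum((rr - p[4])^2)
  }
  fit <- optim(c(ctr, r), obj, method = "BFGS",
               control = list(maxit = 200, reltol = 1e-10))
  ctr <- fit$par[1:3]; r <- fit$par[4]
  res <- sqrt(fit$value / nrow(idx))
  structure(list(center = ctr, radius_vox = r,
                 radius_um = r * mask$voxel_size,
                 rms_residual_um = res * mask$voxel_size,
                 n_boundary = nrow(idx)),
            class = "sphere_fit")
}

#' @export
print.sphere_fit <- function(x, ...) {
  cat(sprintf("<sphere_fit> center (%.2f, %.2f, %.2f) vox, radius %.2f vox (%.1f um), rms %.2f um\n",
              x$center[1], x$center[2], x$center[3], x$radius_vox,
              x$radius_um, x$rms_residual_um))
  invisible(x)
}

#' Analysis region above the fitted sphere center
#'
#' Builds a region-of-interest mask whose lowest slice is the slice containing
#' the center of a fitted sphere: all voxels of `mask` with z at or above the
#' center slice are kept.
#'
#' @param mask A [binary_mask()] delimiting the specimen.
#' @param fit A `sphere_fit` from [best_fit_sphere()].
#' @return A [binary_mask()].
#' @export
region_from_sphere <- function(mask, fit) {
  stopifnot(inherits(mask, "binary_mask"), inherits(fit, "sphere_fit"))
  z0 <- round(fit$center[3]) + 1L  # 1-based slice index
  out <- mask$data
  if (z0 > 1) out[, , seq_len(min(z0 - 1L, dim(out)[3]))] <- FALSE
  binary_mask(out, mask$voxel_size)
}

#' Full-volume region minus a border
#'
#' Default analysis region for synthetic volumes: everything except a border
#' of `border` voxels on each face.
#'
#' @param dims Integer length-3 volume dimensions.
#' @param voxel_size Voxel size in micrometres.
#' @param border Border width in voxels.
#' @return A [binary_mask()].
#' @export
region_box <- function(dims, voxel_size, border = 0) {
  a <- array(FALSE, dims)
  b <- border
  a[(1 + b):(dims[1] - b), (1 + b):(dims[2] - b), (1 + b):(dims[3] - b)] <- TRUE
  binary_mask(a, voxel_size)
}
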