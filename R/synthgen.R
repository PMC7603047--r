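# Synthetic OA-like trabecular volumes with known ground truth, and virtual
# deformation of volumes by exactly known displacement fields. These stand in
# for stepwise-loading microCT acquisitions in validation studies: the
# microstructure is a thresholded Gaussian random field, which reproduces the
# strut/plate texture, controllable bone fraction, cyst-like voids and
# sclerotic (locally denser) patches of osteoarthritic subchondral bone.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Specification of a synthetic trabecular volume
#'
#' @param dims Integer length-3: voxels per axis.
#' @param voxel_size Voxel size in micrometres.
#' @param target_bvtv Target bone volume fraction, in (0, 1).
#' @param correlation_length Gaussian correlation scale of the random field in
#'   micrometres; controls the strut/spacing scale of the microstructure.
#' @param cysts List of cyst-like voids, each `list(center = c(x, y, z),
#'   radius = r)` in 0-based voxel coordinates / voxels.
#' @param sclerotic_region Optional `list(center, radius, bvtv_boost)`: inside
#'   the ball the local bone fraction is raised by `bvtv_boost`.
#' @param foreground_gsv,background_gsv 8-bit grey levels of bone and marrow;
#'   must bracket the segmentation threshold (110 by default elsewhere).
#' @param noise_sigma Additive Gaussian imaging-noise sigma in grey levels,
#'   applied after grey-level assignment (0 disables).
#' @param edge_sigma Sigma (voxels) of the grey-level blur applied after
#'   binarisation to emulate partial-volume blur at bone/marrow interfaces.
#' @param seed Integer; fixes the output bit-for-bit.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(dims = c(128, 128, 128), voxel_size = 39,
                       target_bvtv = 0.20, correlation_length = 160,
                       cysts = list(), sclerotic_region = NULL,
                       foreground_gsv = 180, background_gsv = 60,
                       noise_sigma = 0, edge_sigma = 0.8, seed = 1) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3, all(dims >= 1), voxel_size > 0)
  if (target_bvtv <= 0 || target_bvtv >= 1)
    stop("target_bvtv must lie strictly in (0, 1)")
  if (foreground_gsv <= background_gsv)
    stop("foreground_gsv must exceed background_gsv")
  if (any(dims * voxel_size < 4 * correlation_length))
    stop("dims too small to resolve correlation_length: ",
         "need at least 4 struts per axis")
  for (cy in cysts) {
    if (any(cy$center - cy$radius < 0) || any(cy$center + cy$radius > dims - 1))
      stop("cyst at (", paste(cy$center, collapse = ","),
           ") radius ", cy$radius, " does not fit inside the volume")
  }
  structure(list(dims = dims, voxel_size = voxel_size,
                 target_bvtv = target_bvtv,
                 correlation_length = correlation_length, cysts = cysts,
                 sclerotic_region = sclerotic_region,
                 foreground_gsv = foreground_gsv,
                 background_gsv = background_gsv, noise_sigma = noise_sigma,
                 edge_sigma = edge_sigma, seed = as.integer(seed)),
            class = "synth_spec")
}

#' Bone volume fraction presets spanning the OA femoral-head range
#'
#' Five target BV/TV values (0.177-0.257) spanning the range reported for
#' osteoarthritic femoral-head trabecular bone, used to build synthetic
#' specimen cohorts.
#'
#' @return Named numeric vector of length 5.
#' @export
bvtv_presets <- function() {
  c(specimen1 = 0.177, specimen2 = 0.246, specimen3 = 0.257,
    specimen4 = 0.213, specimen5 = 0.225)
}

ball_mask <- function(dims, center, radius) {
  x <- (seq_len(dims[1]) - 1) - center[1]
  y <- (seq_len(dims[2]) - 1) - center[2]
  z <- (seq_len(dims[3]) - 1) - center[3]
  outer(outer(x^2, y^2, "+"), z^2, "+") <= radius^2
}

#' Generate a synthetic trabecular volume
#'
#' White Gaussian noise is smoothed to `correlation_length` and thresholded at
#' the quantile that yields `target_bvtv`; cyst spheres are forced to
#' background; within a sclerotic region the local threshold is lowered so the
#' local bone fraction rises by `bvtv_boost`. Grey levels are then set to
#' `foreground_gsv` / `background_gsv`, partial-volume blur (`edge_sigma`) and
#' imaging noise (`noise_sigma`) applied, and the result returned as an 8-bit
#' volume. Deterministic for a given `seed`.
#'
#' @param spec A [synth_spec()].
#' @return An 8-bit [image_volume()].
#' @export
generate_trabecular_volume <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  d <- spec$dims
  sig_vox <- spec$correlation_length / spec$voxel_size
  render <- function(bone) {
    vol <- array(spec$background_gsv, dim = d)
    vol[bone] <- spec$foreground_gsv
    if (spec$edge_sigma > 0)
      vol <- cpp_gaussian_blur(vol, d, spec$edge_sigma,
                               as.integer(ceiling(3 * spec$edge_sigma)))
    vol <- floor(vol + 0.5)
    vol[vol < 0] <- 0; vol[vol > 255] <- 255
    vol
  }
  with_seed(spec$seed, {
    field <- array(rnorm(prod(d)), dim = d)
    field <- cpp_gaussian_blur(field, d, sig_vox, as.integer(ceiling(3 * sig_vox)))
    # one-step calibration of the threshold against the imaging chain:
    # partial-volume blur and despeckling at segmentation slightly shrink the
    # recovered bone fraction, so the binary target is offset accordingly
    thr0 <- quantile(field, 1 - spec$target_bvtv, names = FALSE)
    seg <- segment_bone(image_volume(render(field >= thr0), spec$voxel_size))
    target_adj <- min(max(spec$target_bvtv +
                            (spec$target_bvtv - mean(seg$data)), 0.01), 0.95)
    thr <- quantile(field, 1 - target_adj, names = FALSE)
    bone <- field >= thr
    if (!is.null(spec$sclerotic_region)) {
      sr <- spec$sclerotic_region
      inb <- ball_mask(d, sr$center, sr$radius)
      local_target <- min(target_adj + sr$bvtv_boost, 0.95)
      thr_loc <- quantile(field[inb], 1 - local_target, names = FALSE)
      bone[inb] <- field[inb] >= thr_loc
    }
    for (cy in spec$cysts)
      bone[ball_mask(d, cy$center, cy$radius)] <- FALSE
    out <- image_volume(render(bone), spec$voxel_size)
    if (spec$noise_sigma > 0)
      out <- add_imaging_noise(out, spec$noise_sigma, seed = spec$seed + 1L)
    out
  })
}

#' Add imaging noise to a volume
#'
#' Independent zero-mean Gaussian noise of standard deviation `sigma` grey
#' levels, rounded and clipped to `[0, 255]`. Deterministic per seed;
#' `sigma = 0` returns the input unchanged.
#'
#' @param vol 8-bit [image_volume()].
#' @param sigma Noise standard deviation in grey levels (>= 0).
#' @param seed Integer seed.
#' @return An 8-bit [image_volume()].
#' @export
add_imaging_noise <- function(vol, sigma, seed) {
  stopifnot(inherits(vol, "image_volume"), sigma >= 0)
  if (sigma == 0) return(vol)
  with_seed(seed, {
    x <- vol$data + array(rnorm(length(vol$data), sd = sigma), dim(vol$data))
    x <- floor(x + 0.5)
    x[x < 0] <- 0; x[x > 255] <- 255
    image_volume(x, vol$voxel_size)
  })
}

#' Describe a uniform axial virtual compression
#'
#' Apparent compression along one axis toward a stationary plane (the potted
#' base of a loaded specimen): displacement `u_a(X) = strain * (X_a - fixed)`.
#'
#' @param apparent_strain Dimensionless strain; negative = compression;
#'   `|apparent_strain| < 0.2` (small-strain regime).
#' @param axis `"x"`, `"y"` or `"z"` (default `"z"`, the loading axis).
#' @param fixed_plane Voxel index of the stationary plane (default 0, the
#'   inferior face).
#' @return A list of class `applied_deformation`.
#' @export
deformation_uniform <- function(apparent_strain, axis = "z", fixed_plane = 0) {
  if (abs(apparent_strain) >= 0.2)
    stop("|apparent_strain| must be < 0.2 (small-strain regime)")
  ax <- match(axis, c("x", "y", "z"))
  if (is.na(ax)) stop("axis must be one of 'x', 'y', 'z'")
  A <- matrix(0, 3, 3)
  A[ax, ax] <- apparent_strain
  structure(list(kind = "uniform_axial_compression",
                 apparent_strain = apparent_strain, axis = ax,
                 gradient_matrix = A,
                 fixed_point = replace(c(0, 0, 0), ax, fixed_plane)),
            class = "applied_deformation")
}

#' Describe a general linear (affine) virtual deformation
#'
#' Displacement `u(X) = A (X - fixed_point)` for a constant 3x3 displacement
#' gradient `A`; the resulting ground-truth strain tensor is `sym(A)`.
#'
#' @param gradient_matrix 3x3 dimensionless displacement gradient with
#'   spectral norm below 0.2.
#' @param fixed_point Point (0-based voxel coordinates) with zero displacement.
#' @return A list of class `applied_deformation`.
#' @export
deformation_linear <- function(gradient_matrix, fixed_point = c(0, 0, 0)) {
  A <- as.matrix(gradient_matrix)
  stopifnot(all(dim(A) == c(3, 3)))
  if (max(abs(eigen(t(A) %*% A, only.values = TRUE)$values)) >= 0.2^2)
    stop("gradient too large: small-strain regime only (norm < 0.2)")
  structure(list(kind = "linear_field", gradient_matrix = A,
                 fixed_point = fixed_point),
            class = "applied_deformation")
}

#' Apply a virtual deformation with exactly known displacement field
#'
#' Resamples grey levels by trilinear interpolation under the inverse of the
#' affine map `x = X + u(X)`. Voxels whose source point falls outside the
#' volume are filled with `fill` (by default the given background grey level,
#' which avoids sharp grey-level gradients at replaced boundary slices;
#' `fill = 0` reproduces the artifact-inducing black fill used to study
#' boundary errors).
#'
#' @param vol An [image_volume()].
#' @param d An `applied_deformation` from [deformation_uniform()] or
#'   [deformation_linear()].
#' @param fill Grey value for voxels revealed by the deformation.
#' @return A list with `volume` (the deformed [image_volume()]),
#'   `displacement` (function: n x 3 matrix of 0-based voxel coordinates ->
#'   n x 3 displacements in voxels), `strain_tensor` (the exact constant
#'   small-strain tensor, dimensionless), and `deformation`.
#' @export
apply_virtual_deformation <- function(vol, d, fill = 60) {
  stopifnot(inherits(vol, "image_volume"), inherits(d, "applied_deformation"))
  A <- d$gradient_matrix
  x0 <- d$fixed_point
  Fwd <- diag(3) + A
  Minv <- solve(Fwd)
  # x = x0 + F (X - x0)  =>  X = Minv (x - x0) + x0 = Minv x + (I - Minv) x0
  t_off <- as.numeric((diag(3) - Minv) %*% x0)
  dims <- dim(vol$data)
  out <- cpp_affine_resample(vol$data, dims, Minv, t_off, fill)
  out <- floor(out + 0.5)
  out[out < 0] <- 0; out[out > 255] <- 255
  disp <- function(X) {
    X <- matrix(X, ncol = 3)
    t(A %*% (t(X) - x0))
  }
  list(volume = image_volume(out, vol$voxel_size),
       displacement = disp,
       strain_tensor = (A + t(A)) / 2,
       deformation = d)
}
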