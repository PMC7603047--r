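# Differentiation of nodal displacements into small-strain tensors on the
# hexahedral DVC grid, principal/von Mises invariants, and node masking.

avg_adjacent <- function(cellarr, counts) {
  # average cell-centered values onto nodes (equal cell volumes)
  acc <- array(0, counts)
  cnt <- array(0, counts)
  nc <- counts - 1L
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    ii <- (1 + di):(nc[1] + di)
    jj <- (1 + dj):(nc[2] + dj)
    kk <- (1 + dk):(nc[3] + dk)
    acc[ii, jj, kk] <- acc[ii, jj, kk] + cellarr
    cnt[ii, jj, kk] <- cnt[ii, jj, kk] + 1
  }
  acc / cnt
}

#' Differentiate a displacement field into strains
#'
#' On each hexahedral grid cell the displacement gradient is evaluated at the
#' cell center from the trilinear shape-function derivatives (the mean of the
#' four edge differences along each axis); the small-strain tensor
#' `e = (grad u + grad u^T) / 2` is then averaged from cells onto nodes
#' (volume weights are equal since all cells are congruent). Boundary nodes
#' average fewer cells and are flagged. Shear components are tensor shears
#' (`e_ij = gamma_ij / 2`).
#'
#' @param field A `displacement_field` from [dvc_register()] (or an
#'   analytically constructed one).
#' @return A list of class `strain_field`: `grid`; `E` (array
#'   `counts x 6`, components `ex, ey, ez, exy, eyz, exz` in microstrain);
#'   `principal` (`counts x 3`, descending); `eqv` (von Mises equivalent
#'   strain, microstrain); `keep` (logical array, all `TRUE` until
#'   [mask_nodes()] / [exclude_boundary_layers()]); `boundary` (logical);
#'   and the source displacement `u` (micrometres).
#' @export
differentiate_strain <- function(field) {
  stopifnot(inherits(field, "displacement_field"))
  counts <- field$grid$counts
  if (any(counts < 2)) stop("degenerate grid: need >= 2 nodes per axis")
  h <- field$grid$spacing_um
  u <- field$u  # um
  diffax <- function(a, ax) {
    n <- dim(a)[ax]
    hi <- lapply(dim(a), seq_len); hi[[ax]] <- 2:n
    lo <- lapply(dim(a), seq_len); lo[[ax]] <- 1:(n - 1)
    do.call(`[`, c(list(a), hi, list(drop = FALSE))) -
      do.call(`[`, c(list(a), lo, list(drop = FALSE)))
  }
  meanax <- function(a, ax) {
    n <- dim(a)[ax]
    hi <- lapply(dim(a), seq_len); hi[[ax]] <- 2:n
    lo <- lapply(dim(a), seq_len); lo[[ax]] <- 1:(n - 1)
    (do.call(`[`, c(list(a), hi, list(drop = FALSE))) +
       do.call(`[`, c(list(a), lo, list(drop = FALSE)))) / 2
  }
  grad_cell <- function(ua, ax) {
    g <- diffax(ua, ax) / h
    for (other in setdiff(1:3, ax)) g <- meanax(g, other)
    g
  }
  G <- vector("list", 9)  # G[[3*(b-1)+a]] = du_a/dx_b at cell centers
  for (a in 1:3) {
    ua <- array(u[, , , a], counts)
    for (b in 1:3) G[[3 * (b - 1) + a]] <- grad_cell(ua, b)
  }
  sym <- function(a, b) (G[[3 * (b - 1) + a]] + G[[3 * (a - 1) + b]]) / 2
  cellE <- list(ex = G[[1]], ey = G[[5]], ez = G[[9]],
                exy = sym(1, 2), eyz = sym(2, 3), exz = sym(1, 3))
  E <- array(0, c(counts, 6),
             dimnames = list(NULL, NULL, NULL,
                             c("ex", "ey", "ez", "exy", "eyz", "exz")))
  for (m in 1:6) E[, , , m] <- avg_adjacent(cellE[[m]], counts) * 1e6
  principal <- array(0, c(counts, 3))
  eqv <- array(0, counts)
  for (k in seq_len(counts[3]))
    for (j in seq_len(counts[2]))
      for (i in seq_len(counts[1])) {
        p <- principal_strains(E[i, j, k, ])
        principal[i, j, k, ] <- p
        eqv[i, j, k] <- von_mises_strain(p)
      }
  boundary <- array(FALSE, counts)
  boundary[c(1, counts[1]), , ] <- TRUE
  boundary[, c(1, counts[2]), ] <- TRUE
  boundary[, , c(1, counts[3])] <- TRUE
  structure(list(grid = field$grid, E = E, principal = principal, eqv = eqv,
                 keep = array(TRUE, counts), boundary = boundary,
                 u = u, converged = field$converged),
            class = "strain_field")
}

tensor3 <- function(x) {
  # accept a 6-vector (ex, ey, ez, exy, eyz, exz; tensor shear) or 3x3 matrix
  if (is.matrix(x)) {
    stopifnot(all(dim(x) == c(3, 3)))
    return((x + t(x)) / 2)
  }
  stopifnot(length(x) == 6)
  matrix(c(x[1], x[4], x[6],
           x[4], x[2], x[5],
           x[6], x[5], x[3]), 3, 3)
}

#' Principal strains of a symmetric tensor
#'
#' Eigenvalues sorted in descending order; the third (most compressive) is
#' the principal compressive strain `ep3`.
#'
#' @param tensor A symmetric 3x3 matrix, or a 6-vector
#'   `(ex, ey, ez, exy, eyz, exz)` with tensor shears.
#' @return Numeric length 3, `ep1 >= ep2 >= ep3`.
#' @export
principal_strains <- function(tensor) {
  Tm <- tensor3(tensor)
  if (any(!is.finite(Tm))) stop("non-finite strain tensor")
  sort(eigen(Tm, symmetric = TRUE, only.values = TRUE)$values,
       decreasing = TRUE)
}

#' Von Mises equivalent strain
#'
#' Deviatoric definition
#' `eqv = 1/(1+nu) * sqrt(((p1-p2)^2 + (p2-p3)^2 + (p3-p1)^2) / 2)` with the
#' default `nu = 0.5` (incompressible convention), which reduces to
#' `(2/3) * sqrt(...)`. Any hydrostatic tensor gives zero.
#'
#' @param tensor Symmetric 3x3 matrix, 6-vector, or length-3 vector of
#'   principal strains.
#' @param nu Effective Poisson ratio of the scaling convention.
#' @return Nonnegative equivalent strain (same units as input).
#' @export
von_mises_strain <- function(tensor, nu = 0.5) {
  p <- if (length(tensor) == 3 && !is.matrix(tensor)) tensor
       else principal_strains(tensor)
  s <- (p[1] - p[2])^2 + (p[2] - p[3])^2 + (p[3] - p[1])^2
  sqrt(s / 2) / (1 + nu)
}

compute_node_coverage <- function(grid, mask_arr) {
  counts <- grid$counts
  ns <- grid$ns
  half <- floor(ns / 2)
  dims <- dim(mask_arr)
  cov <- array(0, counts)
  for (k in seq_len(counts[3]))
    for (j in seq_len(counts[2]))
      for (i in seq_len(counts[1])) {
        px <- grid$coords[[1]][i]; py <- grid$coords[[2]][j]
        pz <- grid$coords[[3]][k]
        xr <- max(px - half, 0):min(px + half, dims[1] - 1) + 1
        yr <- max(py - half, 0):min(py + half, dims[2] - 1) + 1
        zr <- max(pz - half, 0):min(pz + half, dims[3] - 1) + 1
        cov[i, j, k] <- mean(mask_arr[xr, yr, zr])
      }
  cov
}

#' Remove strain nodes outside a mask
#'
#' Nodes whose NS-sized neighbourhood contains less than `coverage_cutoff`
#' masked-voxel fraction are excluded from all downstream statistics (e.g.
#' nodes centred in cysts or outside the specimen).
#'
#' @param strain A `strain_field`.
#' @param mask A [binary_mask()] on the image grid (typically the bone or
#'   contour mask).
#' @param coverage_cutoff Minimum masked-voxel fraction in the node
#'   neighbourhood.
#' @return The `strain_field` with its `keep` flags updated; also records
#'   `coverage`.
#' @export
mask_nodes <- function(strain, mask, coverage_cutoff = 0.05) {
  stopifnot(inherits(strain, "strain_field"), inherits(mask, "binary_mask"))
  cov <- compute_node_coverage(strain$grid, mask$data)
  keep <- strain$keep & (cov >= coverage_cutoff)
  if (!any(keep)) stop("all nodes removed by mask (coverage cutoff ",
                       coverage_cutoff, ")")
  strain$keep <- keep
  strain$coverage <- cov
  strain
}

#' Exclude boundary node layers along the loading axis
#'
#' Flags out the `layers` node layers nearest the top and bottom z faces,
#' where global DVC concentrates its errors (sharp grey-level gradients at
#' replaced boundary slices of virtually deformed images).
#'
#' @param strain A `strain_field`.
#' @param layers Number of node layers to drop at each z face.
#' @return The `strain_field` with updated `keep` flags.
#' @export
exclude_boundary_layers <- function(strain, layers = 2) {
  counts <- strain$grid$counts
  if (layers <= 0) return(strain)
  if (2 * layers >= counts[3])
    stop("exclusion would remove every node layer along z")
  keep <- strain$keep
  keep[, , seq_len(layers)] <- FALSE
  keep[, , (counts[3] - layers + 1):counts[3]] <- FALSE
  if (!any(keep)) stop("all nodes removed by boundary exclusion")
  strain$keep <- keep
  strain
}

#' Export a strain field as a per-node CSV table
#'
#' One row per node: grid indices, position (um), displacement (um), the six
#' strain components, principal strains, equivalent strain (microstrain) and
#' the keep flag. `shear = "engineering"` doubles the shear columns
#' (`gamma_ij = 2 e_ij`).
#'
#' @param strain A `strain_field`.
#' @param path Output CSV path.
#' @param shear `"tensor"` (default) or `"engineering"`.
#' @return The data frame, invisibly.
#' @export
export_strain_csv <- function(strain, path, shear = c("tensor", "engineering")) {
  shear <- match.arg(shear)
  counts <- strain$grid$counts
  idx <- as.matrix(expand.grid(i = seq_len(counts[1]), j = seq_len(counts[2]),
                               k = seq_len(counts[3])))
  pos <- cbind(strain$grid$coords[[1]][idx[, 1]],
               strain$grid$coords[[2]][idx[, 2]],
               strain$grid$coords[[3]][idx[, 3]]) * strain$grid$voxel_size
  Em <- matrix(strain$E, ncol = 6)
  if (shear == "engineering") Em[, 4:6] <- 2 * Em[, 4:6]
  um <- matrix(strain$u, ncol = 3)
  df <- data.frame(idx, x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3],
                   ux_um = um[, 1], uy_um = um[, 2], uz_um = um[, 3],
                   ex = Em[, 1], ey = Em[, 2], ez = Em[, 3],
                   exy = Em[, 4], eyz = Em[, 5], exz = Em[, 6],
                   ep1 = as.vector(strain$principal[, , , 1]),
                   ep2 = as.vector(strain$principal[, , , 2]),
                   ep3 = as.vector(strain$principal[, , , 3]),
                   eqv = as.vector(strain$eqv),
                   keep = as.vector(strain$keep))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
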