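#' Construct a voxel map
#'
#' Lightweight container for a 3-D scalar field on a regular grid: the grid
#' values, an analysis mask, the voxel size and a semantic tag saying what
#' the values are.
#'
#' @param grid 3-D numeric array.
#' @param mask 3-D logical array of the same shape (default: all `TRUE`).
#' @param voxel_mm Isotropic voxel size in millimetres.
#' @param semantics One of `"volume"`, `"t_score"`, `"probability"`,
#'   `"binary"`.
#' @return Object of class `voxel_map`.
#' @export
voxel_map <- function(grid, mask = NULL, voxel_mm = 4,
                      semantics = c("volume", "t_score", "probability", "binary")) {
  semantics <- match.arg(semantics)
  stopifnot(length(dim(grid)) == 3)
  if (is.null(mask)) mask <- array(TRUE, dim(grid))
  stopifnot(identical(dim(mask), dim(grid)))
  if (semantics == "probability" &&
      (min(grid) < -1e-9 || max(grid) > 1 + 1e-9)) {
    stop("probability maps must lie in [0, 1]")
  }
  if (semantics == "binary" && !all(grid %in% c(0, 1))) {
    stop("binary maps must contain only 0 and 1")
  }
  if (sum(mask) == 0) stop("mask must contain at least one voxel")
  structure(list(grid = grid, mask = mask, voxel_mm = voxel_mm,
                 semantics = semantics),
            class = "voxel_map")
}

#' @export
print.voxel_map <- function(x, ...) {
  cat(sprintf("<voxel_map> %s, %s grid, %g mm voxels, %d mask voxels\n",
              x$semantics, paste(dim(x$grid), collapse = "x"),
              x$voxel_mm, sum(x$mask)))
  invisible(x)
}

#' Write a voxel map to NIfTI
#'
#' The mask is not stored separately; masked-out voxels are written as given.
#' The affine is diagonal with the voxel size.
#'
#' @param map A `voxel_map`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_voxel_map <- function(map, path) {
  img <- RNifti::asNifti(map$grid)
  RNifti::pixdim(img) <- rep(map$voxel_mm, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a voxel map from NIfTI
#'
#' @param path NIfTI file.
#' @param semantics Semantic tag to attach (see [voxel_map()]).
#' @param mask Optional logical mask array.
#' @return A `voxel_map`.
#' @export
read_voxel_map <- function(path, semantics = "volume", mask = NULL) {
  img <- RNifti::readNifti(path)
  voxel_mm <- RNifti::pixdim(img)[1]
  voxel_map(array(as.numeric(img), dim(img)), mask = mask,
            voxel_mm = voxel_mm, semantics = semantics)
}

#' Nearest-neighbour regridding of a voxel map
#'
#' Maps each target voxel to the nearest source voxel (index-space scaling).
#' Intended for probabilistic network maps delivered on a different grid;
#' synthetic maps share a grid and do not need it.
#'
#' @param map A `voxel_map`.
#' @param target_shape Integer vector of length 3.
#' @param target_voxel_mm Voxel size of the target grid.
#' @return A `voxel_map` on the target grid.
#' @export
regrid_nearest <- function(map, target_shape, target_voxel_mm = map$voxel_mm) {
  src_dim <- dim(map$grid)
  idx <- lapply(1:3, function(k) {
    # centre-aligned index mapping in physical units
    src_pos <- (seq_len(src_dim[k]) - 0.5) * map$voxel_mm
    tgt_pos <- (seq_len(target_shape[k]) - 0.5) * target_voxel_mm
    pmin(pmax(round(tgt_pos / map$voxel_mm + 0.5), 1), src_dim[k])
  })
  grid <- map$grid[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  mask <- map$mask[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  voxel_map(array(grid, target_shape), array(mask, target_shape),
            voxel_mm = target_voxel_mm, semantics = map$semantics)
}

# Squared distance field (in voxels) from a centre, on an arbitrary grid.
.distance_sq <- function(grid_shape, center) {
  dx <- (seq_len(grid_shape[1]) - center[1])^2
  dy <- (seq_len(grid_shape[2]) - center[2])^2
  dz <- (seq_len(grid_shape[3]) - center[3])^2
  outer(outer(dx, dy, "+"), dz, "+")
}

# Sum of isotropic Gaussian bumps: peak * exp(-r^2 / (2 sigma^2)) per centre.
.gaussian_bumps <- function(grid_shape, centers, sigma, peak = 1) {
  acc <- array(0, grid_shape)
  for (i in seq_len(nrow(centers))) {
    acc <- acc + peak * exp(-.distance_sq(grid_shape, centers[i, ]) /
                              (2 * sigma^2))
  }
  acc
}

# Ellipsoidal "brain" mask inscribed in the grid with a small margin.
.ellipsoid_mask <- function(grid_shape, margin = 1.5) {
  c0 <- (grid_shape + 1) / 2
  r <- grid_shape / 2 - margin
  dx <- ((seq_len(grid_shape[1]) - c0[1]) / r[1])^2
  dy <- ((seq_len(grid_shape[2]) - c0[2]) / r[2])^2
  dz <- ((seq_len(grid_shape[3]) - c0[3]) / r[3])^2
  outer(outer(dx, dy, "+"), dz, "+") <= 1
}
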