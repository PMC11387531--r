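#' Image sampling grid
#'
#' Axis-aligned sampling grid in world (scanner) coordinates. World
#' coordinates are in millimetres; voxel `(i, j, k)` (1-based, as R indexes
#' arrays) sits at `origin + (c(i, j, k) - 1) * voxel_size`, i.e. the origin
#' is the centre of the first voxel.
#'
#' @param shape integer vector of length 3, array dimensions.
#' @param voxel_size numeric length 3 (or scalar), voxel edge lengths in mm.
#' @param origin numeric length 3, world position of the first voxel centre, mm.
#' @return An object of class `image_grid`.
#' @export
image_grid <- function(shape, voxel_size, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(shape) != 3L || any(shape < 1L))
    stop("grid shape must be three positive integers")
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("voxel size must be three positive lengths (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("grid origin must be three finite coordinates (mm)")
  structure(list(shape = shape, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin), orientation = "RAS"),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("image_grid: %s voxels, %s mm, origin (%s) mm\n",
              paste(x$shape, collapse = "x"),
              paste(signif(x$voxel_size, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

#' Voxel-volume of one grid cell in cubic centimetres
#' @param grid an [image_grid()].
#' @return scalar, cc.
#' @export
voxel_volume_cc <- function(grid) prod(grid$voxel_size) / 1000

#' Mask volume in cubic centimetres
#'
#' @param mask logical 3D array.
#' @param grid the [image_grid()] the mask lives on.
#' @return scalar, cc (voxel count times voxel volume).
#' @export
mask_volume_cc <- function(mask, grid) sum(mask) * voxel_volume_cc(grid)

#' World coordinates of every voxel centre
#'
#' @param grid an [image_grid()].
#' @return n-voxel x 3 matrix of world coordinates (mm), voxels in R array
#'   (column-major) order.
#' @export
grid_world_coords <- function(grid) {
  idx <- arrayInd(seq_len(prod(grid$shape)), grid$shape)
  sweep(sweep(idx - 1, 2, grid$voxel_size, "*"), 2, grid$origin, "+")
}

#' World coordinate of the grid centre
#' @param grid an [image_grid()].
#' @return length-3 numeric, mm.
#' @export
grid_center_world <- function(grid) {
  grid$origin + (grid$shape - 1) / 2 * grid$voxel_size
}

# world (n x 3) -> continuous 1-based voxel coordinates
world_to_voxel <- function(points, grid) {
  sweep(sweep(points, 2, grid$origin, "-"), 2, grid$voxel_size, "/") + 1
}
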