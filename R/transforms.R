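#' Rigid (6-degree-of-freedom) spatial transform
#'
#' Represents a rotation plus translation in world coordinates. The
#' convention, carried on the object, is that the transform maps
#' moving-image world coordinates to fixed-image world coordinates.
#' Rotation angles are extrinsic x-y-z Euler angles (radians), applied as
#' `Rz %*% Ry %*% Rx` about `center`.
#'
#' @param angles length-3 numeric, rotations about x, y, z in radians.
#' @param translation length-3 numeric, mm.
#' @param center length-3 numeric, rotation centre in world mm.
#' @return An object of class `rigid_transform` holding the 4x4 homogeneous
#'   matrix.
#' @export
rigid_transform <- function(angles = c(0, 0, 0), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  stopifnot(length(angles) == 3L, length(translation) == 3L,
            length(center) == 3L)
  if (any(!is.finite(c(angles, translation, center))))
    stop("rigid transform parameters must be finite")
  R <- euler_to_matrix(angles)
  t <- translation + center - R %*% center
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- t
  new_rigid_transform(m)
}

new_rigid_transform <- function(m) {
  R <- m[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || det(R) < 0)
    stop("rotation block is not a proper rotation (orthonormal, det +1)")
  structure(list(matrix = m, convention = "moving_world_to_fixed_world"),
            class = "rigid_transform")
}

euler_to_matrix <- function(angles) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Extract Euler angles and translation from a rigid transform
#'
#' The translation reported is the one that, together with the angles and
#' the supplied rotation `center`, reconstructs the transform via
#' [rigid_transform()].
#'
#' @param tfm a `rigid_transform`.
#' @param center rotation centre used for the decomposition, world mm.
#' @return list with `angles` (radians) and `translation` (mm).
#' @export
transform_params <- function(tfm, center = c(0, 0, 0)) {
  m <- tfm$matrix
  R <- m[1:3, 1:3]
  ry <- asin(max(-1, min(1, -R[3, 1])))
  if (abs(cos(ry)) > 1e-8) {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  } else {  # gimbal lock; absorb into rx
    rx <- atan2(-R[2, 3], R[2, 2])
    rz <- 0
  }
  angles <- c(rx, ry, rz)
  translation <- m[1:3, 4] - center + R %*% center
  list(angles = angles, translation = as.numeric(translation))
}

#' Compose two rigid transforms
#' @param a,b `rigid_transform` objects; the result applies `b` first, then `a`.
#' @return a `rigid_transform`.
#' @export
compose_transform <- function(a, b) new_rigid_transform(a$matrix %*% b$matrix)

#' Invert a rigid transform
#' @param tfm a `rigid_transform`.
#' @return the inverse `rigid_transform`.
#' @export
invert_transform <- function(tfm) {
  m <- tfm$matrix
  R <- m[1:3, 1:3]
  inv <- diag(4)
  inv[1:3, 1:3] <- t(R)
  inv[1:3, 4] <- -t(R) %*% m[1:3, 4]
  new_rigid_transform(inv)
}

#' Identity transform
#' @return a `rigid_transform` equal to the identity mapping.
#' @export
identity_transform <- function() new_rigid_transform(diag(4))

# apply to an n x 3 matrix of world points
apply_transform <- function(tfm, points) {
  sweep(points %*% t(tfm$matrix[1:3, 1:3]), 2, tfm$matrix[1:3, 4], "+")
}

#' Write / read a rigid transform as a 4x4 row-major text matrix
#'
#' Plain-text interchange format: four lines of four numbers, row-major,
#' preceded by comment lines (`#`) recording the convention.
#'
#' @param tfm a `rigid_transform`.
#' @param path file path.
#' @export
write_transform <- function(tfm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# rigid transform, 4x4 homogeneous, row-major",
               paste0("# convention: ", tfm$convention)), con)
  for (i in 1:4)
    writeLines(paste(formatC(tfm$matrix[i, ], format = "g", digits = 17),
                     collapse = " "), con)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) != 4L)
    stop("transform file must contain exactly four matrix rows")
  m <- do.call(rbind, lapply(lines, function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  if (!all(dim(m) == c(4L, 4L)) || any(!is.finite(m)))
    stop("malformed 4x4 transform matrix")
  new_rigid_transform(m)
}

#' @export
print.rigid_transform <- function(x, ...) {
  p <- transform_params(x)
  cat(sprintf("rigid_transform: angles (%s) deg, translation (%s) mm\n",
              paste(signif(p$angles * 180 / pi, 4), collapse = ", "),
              paste(signif(p$translation, 4), collapse = ", ")))
  invisible(x)
}
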