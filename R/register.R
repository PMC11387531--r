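#' Resample a volume through a rigid transform
#'
#' Pulls values from `volume` (living on `source_grid`, the moving frame)
#' onto `target_grid` (the fixed frame). `transform` maps moving-world to
#' fixed-world coordinates; each target voxel centre is mapped through the
#' inverse transform into the source frame and interpolated. Target voxels
#' falling outside the source field of view are set to `NA` (the missing
#' code excluded by all downstream computations).
#'
#' @param volume 3D numeric array on `source_grid`.
#' @param source_grid,target_grid [image_grid()] objects.
#' @param transform a [rigid_transform()] (moving-world to fixed-world).
#' @param interpolation `"trilinear"` for intensity maps, `"nearest"` for
#'   masks and label maps.
#' @return 3D array on `target_grid`.
#' @export
resample <- function(volume, source_grid, transform, target_grid,
                     interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (!all(dim(volume) == source_grid$shape))
    stop("volume shape does not match source grid")
  if (abs(det(transform$matrix)) < 1e-12) stop("singular transform")
  pts_fixed <- grid_world_coords(target_grid)
  pts_src <- apply_transform(invert_transform(transform), pts_fixed)
  vc <- world_to_voxel(pts_src, source_grid)
  out <- if (interpolation == "nearest")
    sample_nearest(volume, vc) else sample_trilinear(volume, vc)
  array(out, target_grid$shape)
}

sample_nearest <- function(volume, vc) {
  d <- dim(volume)
  i <- round(vc)
  ok <- i[, 1] >= 1 & i[, 1] <= d[1] & i[, 2] >= 1 & i[, 2] <= d[2] &
    i[, 3] >= 1 & i[, 3] <= d[3]
  out <- rep(NA_real_, nrow(vc))
  lin <- (i[ok, 3] - 1) * d[1] * d[2] + (i[ok, 2] - 1) * d[1] + i[ok, 1]
  out[ok] <- volume[lin]
  out
}

sample_trilinear <- function(volume, vc) {
  d <- dim(volume)
  f0 <- floor(vc)
  w <- vc - f0
  # points sitting exactly on the far faces are still inside
  for (ax in 1:3) {
    on_face <- f0[, ax] == d[ax] & w[, ax] == 0
    f0[on_face, ax] <- d[ax] - 1
    w[on_face, ax] <- 1
  }
  ok <- f0[, 1] >= 1 & f0[, 1] <= d[1] - 1 &
    f0[, 2] >= 1 & f0[, 2] <= d[2] - 1 &
    f0[, 3] >= 1 & f0[, 3] <= d[3] - 1
  out <- rep(NA_real_, nrow(vc))
  if (!any(ok)) return(out)
  f0 <- f0[ok, , drop = FALSE]
  w <- w[ok, , drop = FALSE]
  n12 <- d[1] * d[2]
  base <- (f0[, 3] - 1) * n12 + (f0[, 2] - 1) * d[1] + f0[, 1]
  acc <- 0
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    wt <- (if (dx) w[, 1] else 1 - w[, 1]) *
      (if (dy) w[, 2] else 1 - w[, 2]) *
      (if (dz) w[, 3] else 1 - w[, 3])
    acc <- acc + wt * volume[base + dz * n12 + dy * d[1] + dx]
  }
  out[ok] <- acc
  out
}

#' Normalized mutual information of two co-sampled volumes
#'
#' Histogram-based NMI, `(H(A) + H(B)) / H(A, B)`, over voxels valid
#' (finite, non-NA) in both volumes. Invariant to monotone rescaling of
#' either image up to binning.
#'
#' @param a,b numeric vectors or arrays of equal length.
#' @param nbins histogram bins per image.
#' @return scalar NMI (>= 1).
#' @export
nmi <- function(a, b, nbins = 32L) {
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 100) return(NA_real_)
  # linear partial-volume (Parzen) binning: each sample splits between two
  # adjacent bins, making the metric continuous in the transform parameters
  pv <- function(x) {
    r <- range(x)
    if (r[1] == r[2]) {
      return(list(i0 = rep(1L, length(x)), w1 = rep(0, length(x))))
    }
    u <- (x - r[1]) / (r[2] - r[1]) * (nbins - 1) + 1
    i0 <- pmin(floor(u), nbins - 1)
    list(i0 = as.integer(i0), w1 = u - i0)
  }
  pa <- pv(a); pb <- pv(b)
  joint <- numeric(nbins * nbins)
  for (da in 0:1) for (db in 0:1) {
    idx <- (pb$i0 + db - 1L) * nbins + pa$i0 + da
    w <- (if (da) pa$w1 else 1 - pa$w1) * (if (db) pb$w1 else 1 - pb$w1)
    s <- rowsum(w, idx)
    joint[as.integer(rownames(s))] <- joint[as.integer(rownames(s))] + s
  }
  joint <- joint / n
  pj <- matrix(joint, nbins, nbins)
  ma <- rowSums(pj)
  mb <- colSums(pj)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  (ent(ma) + ent(mb)) / ent(joint)
}

#' Settings for rigid registration
#'
#' @param nbins NMI histogram bins.
#' @param levels multiresolution downsampling factors, coarse to fine.
#' @param maxit Nelder-Mead iterations per level.
#' @param restarts simplex restarts per level (re-initializes the
#'   Nelder-Mead simplex at the current optimum; guards against premature
#'   simplex collapse).
#' @param search_mm half-width of the exhaustive translation pre-search at
#'   the coarsest level (0 disables).
#' @param search_step_mm step of the translation pre-search.
#' @param init optional initial [rigid_transform()] (e.g. manual
#'   initialization); default identity.
#' @return list of class `register_settings`.
#' @export
register_settings <- function(nbins = 32L, levels = c(2L, 1L),
                              maxit = 250L, restarts = 0L, search_mm = 12,
                              search_step_mm = 6, init = NULL) {
  structure(list(nbins = nbins, levels = levels, maxit = maxit,
                 restarts = restarts, search_mm = search_mm,
                 search_step_mm = search_step_mm, init = init),
            class = "register_settings")
}

# 2x2x2 (or f^3) block-mean downsampling, returning volume + grid
downsample_volume <- function(volume, grid, f) {
  if (f == 1L) return(list(volume = volume, grid = grid))
  d <- dim(volume)
  nd <- d %/% f
  v <- volume[seq_len(nd[1] * f), seq_len(nd[2] * f), seq_len(nd[3] * f)]
  dim(v) <- c(f, nd[1], f, nd[2], f, nd[3])
  v <- apply(v, c(2, 4, 6), mean)
  g <- image_grid(nd, grid$voxel_size * f,
                  grid$origin + (f - 1) / 2 * grid$voxel_size)
  list(volume = v, grid = g)
}

#' Estimate the rigid transform aligning a moving volume to a fixed volume
#'
#' Six-parameter (three rotations, three translations) registration
#' maximizing normalized mutual information, suitable for multi-modal
#' pairs such as PET SUV onto the b = 0 diffusion image. Optimization is
#' Nelder-Mead over a coarse-to-fine resolution pyramid with rotation about
#' the fixed-volume centre; deterministic given the settings and
#' initialization.
#'
#' @param moving,fixed 3D numeric arrays.
#' @param moving_grid,fixed_grid their [image_grid()]s.
#' @param settings a [register_settings()].
#' @return a [rigid_transform()] mapping moving-world to fixed-world, with
#'   attributes `nmi` (final metric) and `trace` (per-level metric values).
#' @export
estimate_rigid <- function(moving, moving_grid, fixed, fixed_grid,
                           settings = register_settings()) {
  if (!all(is.finite(fixed)) || !all(is.finite(moving)))
    stop("registration inputs must be finite (fill missing values first)")
  center <- grid_center_world(fixed_grid)
  p <- if (is.null(settings$init)) rep(0, 6) else {
    tp <- transform_params(settings$init, center)
    c(tp$angles, tp$translation)
  }
  trace <- numeric(0)
  first_level <- TRUE
  for (f in settings$levels) {
    mv <- downsample_volume(moving, moving_grid, f)
    fx <- downsample_volume(fixed, fixed_grid, f)
    pts_fixed <- grid_world_coords(fx$grid)
    # mild blur of the fixed image symmetrizes the smoothing that trilinear
    # interpolation applies to the moving image, removing a sub-voxel bias
    # in the metric optimum
    fxv <- as.numeric(gaussian_smooth3d(fx$volume, 0.5))
    obj <- function(par) {
      tfm <- rigid_transform(par[1:3], par[4:6], center)
      pts_src <- apply_transform(invert_transform(tfm), pts_fixed)
      r <- sample_trilinear(mv$volume, world_to_voxel(pts_src, mv$grid))
      v <- nmi(r, fxv, settings$nbins)
      if (is.na(v)) 0 else -v
    }
    if (first_level) {
      if (settings$search_mm > 0) {
        # exhaustive translation pre-search at the coarsest level
        steps <- seq(-settings$search_mm, settings$search_mm,
                     by = settings$search_step_mm)
        tg <- as.matrix(expand.grid(tx = steps, ty = steps, tz = steps))
        vals <- apply(tg, 1, function(t) obj(c(p[1:3], p[4:6] + t)))
        p[4:6] <- p[4:6] + tg[which.min(vals), ]
      }
      # sequential per-axis rotation scan
      for (ax in 1:3) {
        angs <- seq(-6, 6, by = 1.5) * pi / 180
        vals <- vapply(angs, function(a) {
          q <- p; q[ax] <- q[ax] + a; obj(q)
        }, 0)
        p[ax] <- p[ax] + angs[which.min(vals)]
      }
      first_level <- FALSE
    }
    # scale so one optimizer unit ~ 2 deg / 2 mm
    for (r in seq_len(settings$restarts + 1L)) {
      opt <- stats::optim(p, obj, method = "Nelder-Mead",
                          control = list(maxit = settings$maxit,
                                         parscale = c(rep(0.035, 3),
                                                      rep(2, 3)),
                                         reltol = 1e-9))
      p <- opt$par
    }
    trace <- c(trace, -opt$value)
  }
  # final polish with a tight simplex (~0.1 deg / 0.1 mm scale)
  opt <- stats::optim(p, obj, method = "Nelder-Mead",
                      control = list(maxit = 200L,
                                     parscale = c(rep(0.002, 3),
                                                  rep(0.1, 3)),
                                     reltol = 1e-10))
  p <- opt$par
  trace <- c(trace, -opt$value)
  if (!is.finite(opt$value) || -opt$value <= 0)
    stop("registration metric degenerate; best-so-far transform discarded")
  out <- rigid_transform(p[1:3], p[4:6], center)
  attr(out, "nmi") <- -opt$value
  attr(out, "trace") <- trace
  out
}
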