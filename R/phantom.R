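#' Default tissue parameter means for the digital phantom
#'
#' Three tissue classes plus background. The tumor is an ellipsoid with a
#' rim/core structure: the core has lower perfusion fraction and diffusion
#' coefficient and higher FDG uptake than the rim, the spatial pattern seen
#' in responding cervical tumors. Values are chosen so the tumor
#' (rim + core) averages sit near typical pre-treatment cervical-cancer
#' measurements: D ~ 1.07e-3 mm^2/s, f ~ 0.127, D* ~ 13.7e-3 mm^2/s,
#' SUVmean ~ 3.7.
#'
#' @return named list of per-tissue parameter lists (`background`,
#'   `normal`, `rim`, `core`), each with `D`, `f`, `Dstar` (mm^2/s,
#'   fraction, mm^2/s), `S0` (signal units) and `SUV`.
#' @export
default_tissue_means <- function() {
  list(
    background = list(D = 1.0e-3, f = 0.05, Dstar = 10e-3, S0 = 0,   SUV = 0),
    normal     = list(D = 1.6e-3, f = 0.08, Dstar = 10e-3, S0 = 800, SUV = 1.5),
    rim        = list(D = 1.20e-3, f = 0.150, Dstar = 14.5e-3, S0 = 1000,
                      SUV = 3.0),
    core       = list(D = 0.94e-3, f = 0.104, Dstar = 12.9e-3, S0 = 1000,
                      SUV = 4.4))
}

# separable Gaussian smoothing with periodic boundaries (FFT); used only to
# texture noise fields, where wrap-around is harmless
gaussian_smooth3d <- function(x, sigma_vox) {
  d <- dim(x)
  k <- lapply(seq_len(3), function(ax) {
    n <- d[ax]
    u <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    g <- exp(-u^2 / (2 * sigma_vox^2))
    g / sum(g)
  })
  K <- outer(outer(Re(fft(k[[1]])), Re(fft(k[[2]]))), Re(fft(k[[3]])))
  Re(fft(fft(x) * K, inverse = TRUE)) / prod(d)
}

# unit-SD smooth random field on the grid
smooth_field <- function(shape, sigma_vox) {
  f <- gaussian_smooth3d(array(stats::rnorm(prod(shape)), shape), sigma_vox)
  s <- stats::sd(f)
  if (s == 0) f else f / s
}

# squared normalized ellipsoid radius of every voxel (<= 1 is inside)
ellipsoid_r2 <- function(grid, center, radii) {
  co <- grid_world_coords(grid)
  r2 <- sweep(sweep(co, 2, center, "-"), 2, radii, "/")^2
  array(rowSums(r2), dim = grid$shape)
}

#' Generate a single-patient digital phantom
#'
#' Builds an ellipsoidal tumor (rim + half-volume core) inside normal
#' pelvic tissue on an axis-aligned grid, with ground-truth IVIM parameter
#' maps (D, f, D*), proton-density signal S0 and an FDG-uptake (SUV) map.
#' Smooth spatial heterogeneity is added to each map as low-pass-filtered
#' Gaussian noise scaled relative to the tissue mean, then clipped to the
#' prior bounds.
#'
#' @param grid_shape integer length 3, voxels per axis.
#' @param voxel_size mm, scalar or length 3.
#' @param tumor_radii_mm ellipsoid semi-axes, mm.
#' @param tissue_means per-tissue parameter means, see
#'   [default_tissue_means()].
#' @param noise_frac relative SD of the smooth within-tissue heterogeneity
#'   (0 gives piecewise-constant maps).
#' @param smooth_sigma_mm spatial correlation length (Gaussian sigma) of
#'   the heterogeneity, mm.
#' @param center_mm tumor centre in world mm; default grid centre.
#' @param seed integer RNG seed; the result is bit-reproducible given the
#'   seed and parameters.
#' @param priors an [ivim_priors()] giving the clipping bounds.
#' @return a `phantom_truth` object: `label_map` (0 background, 1 normal,
#'   2 rim, 3 core), `true_D`, `true_f`, `true_Dstar`, `true_S0`,
#'   `true_SUV`, `gtv_mask`, `grid`, `geometry`, `seed`.
#' @export
make_phantom <- function(grid_shape = c(64, 64, 64), voxel_size = 2,
                         tumor_radii_mm = c(25, 25, 25),
                         tissue_means = default_tissue_means(),
                         noise_frac = 0.05, smooth_sigma_mm = 4,
                         center_mm = NULL, seed = 1,
                         priors = ivim_priors()) {
  grid <- image_grid(grid_shape, voxel_size)
  if (any(tumor_radii_mm <= 0)) stop("tumor radii must be positive")
  if (is.null(center_mm)) center_mm <- grid_center_world(grid)
  extent_lo <- grid$origin
  extent_hi <- grid$origin + (grid$shape - 1) * grid$voxel_size
  if (any(center_mm - tumor_radii_mm < extent_lo + grid$voxel_size) ||
      any(center_mm + tumor_radii_mm > extent_hi - grid$voxel_size))
    stop("tumor (radii ", paste(tumor_radii_mm, collapse = "x"),
         " mm) does not fit inside the grid with a one-voxel margin")
  for (tis in c("normal", "rim", "core")) {
    tm <- tissue_means[[tis]]
    if (tm$D < priors$D[1] || tm$D > priors$D[2] ||
        tm$f < priors$f[1] || tm$f > priors$f[2] ||
        tm$Dstar < priors$Dstar[1] || tm$Dstar > priors$Dstar[2])
      stop("tissue means for '", tis, "' fall outside the prior bounds")
  }

  set.seed(seed)
  r2 <- ellipsoid_r2(grid, center_mm, tumor_radii_mm)
  core_scale <- 0.5^(1 / 3)  # half-volume core
  label <- array(1L, grid$shape)
  label[r2 <= 1] <- 2L
  label[ellipsoid_r2(grid, center_mm, tumor_radii_mm * core_scale) <= 1] <- 3L
  # thin background shell at the grid boundary (air outside the body)
  edge <- array(FALSE, grid$shape)
  edge[c(1, grid$shape[1]), , ] <- TRUE
  edge[, c(1, grid$shape[2]), ] <- TRUE
  edge[, , c(1, grid$shape[3])] <- TRUE
  label[edge & label == 1L] <- 0L

  tnames <- c("background", "normal", "rim", "core")
  sigma_vox <- smooth_sigma_mm / mean(grid$voxel_size)
  bounds <- list(D = priors$D, f = priors$f,
                 Dstar = c(priors$Dstar[1] * 1.02, priors$Dstar[2]),
                 S0 = c(0, Inf), SUV = c(0, Inf))
  maps <- list()
  for (par in c("D", "f", "Dstar", "S0", "SUV")) {
    mu <- vapply(tissue_means[tnames], `[[`, 0, par)[label + 1L]
    m <- array(mu, grid$shape)
    if (noise_frac > 0) {
      fld <- smooth_field(grid$shape, sigma_vox)
      m <- m * (1 + noise_frac * fld)
    }
    maps[[par]] <- clip(m, bounds[[par]])
  }
  # keep the compartments separated voxel-wise
  maps$Dstar <- pmax(maps$Dstar, maps$D * 1.5 + 1e-3)

  structure(list(label_map = label, true_D = maps$D, true_f = maps$f,
                 true_Dstar = maps$Dstar, true_S0 = maps$S0,
                 true_SUV = maps$SUV, gtv_mask = label >= 2L,
                 grid = grid,
                 geometry = list(center = center_mm, radii = tumor_radii_mm,
                                 core_scale = core_scale),
                 tissue_means = tissue_means, noise_frac = noise_frac,
                 seed = seed),
            class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("phantom_truth: %s grid, GTV %.1f cc (%d voxels), seed %d\n",
              paste(x$grid$shape, collapse = "x"),
              mask_volume_cc(x$gtv_mask, x$grid), sum(x$gtv_mask), x$seed))
  invisible(x)
}

#' Simulate a multi-b-value DWI series from a phantom
#'
#' Evaluates the IVIM forward model at each voxel and b-value, then applies
#' Rician corruption: the magnitude `sqrt((s + n1)^2 + n2^2)` with
#' `n1, n2 ~ N(0, sigma^2)`. Background voxels (S0 = 0) thereby receive
#' pure Rayleigh noise.
#'
#' @param truth a `phantom_truth`.
#' @param bvalues b-value scheme (validated via [bvalue_scheme()]).
#' @param sigma noise SD in signal units; `NULL` gives SNR 50 at b = 0
#'   relative to the rim S0.
#' @param seed RNG seed.
#' @return a `dwi_series`: 4D `data` (x, y, z, b), `bvalues`, `grid`,
#'   `sigma`.
#' @export
simulate_dwi <- function(truth, bvalues = default_bvalues(), sigma = NULL,
                         seed = 1) {
  scheme <- bvalue_scheme(bvalues)
  b <- scheme$bvalues
  if (is.null(sigma)) sigma <- truth$tissue_means$rim$S0 / 50
  if (sigma < 0) stop("noise sigma must be non-negative")
  sp <- truth$grid$shape
  data <- array(0, c(sp, length(b)))
  for (i in seq_along(b))
    data[, , , i] <- ivim_signal(b[i], truth$true_S0, truth$true_D,
                                 truth$true_f, truth$true_Dstar)
  if (sigma > 0) {
    set.seed(seed)
    n <- length(data)
    data <- sqrt((data + stats::rnorm(n, 0, sigma))^2 +
                   stats::rnorm(n, 0, sigma)^2)
    dim(data) <- c(sp, length(b))
  }
  structure(list(data = data, bvalues = b, grid = truth$grid, sigma = sigma),
            class = "dwi_series")
}

#' @export
print.dwi_series <- function(x, ...) {
  cat(sprintf("dwi_series: %s x %d b-values (%s s/mm^2), sigma %.3g\n",
              paste(x$grid$shape, collapse = "x"), length(x$bvalues),
              paste(x$bvalues, collapse = ","), x$sigma))
  invisible(x)
}

#' Treatment-response parameters for the follow-up phantom
#'
#' @param volume_change_frac fractional GTV volume change (-0.5 = 50 %
#'   shrinkage).
#' @param delta_D additive change to tumor D, mm^2/s.
#' @param delta_f additive change to tumor f.
#' @param per_voxel_jitter_sd relative SD of multiplicative per-voxel
#'   jitter applied to the shifted tumor maps.
#' @return list of class `response_params`.
#' @export
response_params <- function(volume_change_frac = -0.5, delta_D = 0.12e-3,
                            delta_f = 0.03, per_voxel_jitter_sd = 0) {
  if (volume_change_frac <= -1)
    stop("volume change must leave a positive on-treatment volume")
  if (per_voxel_jitter_sd < 0) stop("jitter SD must be non-negative")
  structure(list(volume_change_frac = volume_change_frac, delta_D = delta_D,
                 delta_f = delta_f,
                 per_voxel_jitter_sd = per_voxel_jitter_sd),
            class = "response_params")
}

#' Simulate the on-treatment follow-up of a phantom
#'
#' Shrinks (or grows) the analytic tumor ellipsoid isotropically to match
#' the requested fractional volume change, and shifts tumor-voxel D and f
#' by the requested additive deltas plus optional multiplicative jitter,
#' clipped to the prior bounds. Voxels leaving the GTV are relabelled as
#' normal tissue but keep their parameter values (regressed tumor bed).
#'
#' @param truth a `phantom_truth` (pre-treatment).
#' @param resp a [response_params()].
#' @param seed RNG seed for the jitter.
#' @param priors clipping bounds, an [ivim_priors()].
#' @return a new `phantom_truth` for the on-treatment timepoint.
#' @export
simulate_followup <- function(truth, resp, seed = 1, priors = ivim_priors()) {
  scale <- (1 + resp$volume_change_frac)^(1 / 3)
  geom <- truth$geometry
  radii_on <- geom$radii * scale
  r2 <- ellipsoid_r2(truth$grid, geom$center, radii_on)
  gtv_on <- r2 <= 1
  if (!any(gtv_on))
    stop("requested shrinkage leaves no tumor voxels on the grid")

  out <- truth
  out$geometry$radii <- radii_on
  label <- truth$label_map
  label[truth$gtv_mask & !gtv_on] <- 1L
  label[gtv_on] <- 2L
  core_on <- ellipsoid_r2(truth$grid, geom$center,
                          radii_on * geom$core_scale) <= 1
  label[core_on] <- 3L
  out$label_map <- label
  out$gtv_mask <- gtv_on

  set.seed(seed)
  jit <- function(x) {
    if (resp$per_voxel_jitter_sd > 0)
      x * (1 + stats::rnorm(length(x), 0, resp$per_voxel_jitter_sd))
    else x
  }
  idx <- which(gtv_on)
  out$true_D[idx] <- clip(jit(truth$true_D[idx] + resp$delta_D), priors$D)
  out$true_f[idx] <- clip(jit(truth$true_f[idx] + resp$delta_f), priors$f)
  out$true_Dstar <- pmax(out$true_Dstar, out$true_D * 1.5 + 1e-3)
  out
}
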