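#' Cohort simulation parameters
#'
#' Per-patient distributions of tumor-mean imaging metrics (Normal, clipped
#' to plausible ranges) and the voxel-wise SUV-IVIM coupling targets.
#' Defaults reproduce typical pre-treatment cervical-cancer cohort
#' statistics: tumor-mean D 1.07e-3 (SD 0.2e-3) mm^2/s, f 12.7 (3.3) %,
#' D* 13.7e-3 (3.5e-3) mm^2/s, SUVmean 3.7 (1.6), GTV 65 (48) cc, and weak
#' negative voxel-wise rank correlations of SUV with D (-0.15) and f
#' (-0.08).
#'
#' @param n_patients cohort size (>= 2).
#' @param D_mean_sd,f_mean_sd,Dstar_mean_sd,suv_mean_sd,gtv_cc_mean_sd
#'   length-2 `c(mean, sd)` of the per-patient tumor means (D, D* in
#'   mm^2/s; f as a fraction; GTV in cc).
#' @param r_suv_d,r_suv_f target voxel-wise Spearman correlations of SUV
#'   with D and f, each in (-1, 1).
#' @param snr signal-to-noise ratio at b = 0 for the simulated DWI.
#' @param grid_shape,voxel_size phantom sampling grid (per patient).
#' @param bvalues acquisition scheme.
#' @param response_coupling strength of the link between the SUV^hi D^lo
#'   composition and shrinkage (see [simulate_cohort()]).
#' @param seed master RNG seed.
#' @return list of class `cohort_params`.
#' @export
cohort_params <- function(n_patients = 20L,
                          D_mean_sd = c(1.07e-3, 0.2e-3),
                          f_mean_sd = c(0.127, 0.033),
                          Dstar_mean_sd = c(13.7e-3, 3.5e-3),
                          suv_mean_sd = c(3.7, 1.6),
                          gtv_cc_mean_sd = c(65, 48),
                          r_suv_d = -0.15, r_suv_f = -0.08,
                          snr = 50, grid_shape = c(28, 28, 28),
                          voxel_size = 4,
                          bvalues = default_bvalues(),
                          response_coupling = 1.2, seed = 1L) {
  if (n_patients < 2) stop("a cohort needs at least two patients")
  for (ms in list(D_mean_sd, f_mean_sd, Dstar_mean_sd, suv_mean_sd,
                  gtv_cc_mean_sd))
    if (length(ms) != 2L || ms[2] < 0)
      stop("each distribution must be c(mean, sd) with sd >= 0")
  if (abs(r_suv_d) >= 1 || abs(r_suv_f) >= 1)
    stop("target correlations must lie in (-1, 1)")
  structure(list(n_patients = as.integer(n_patients),
                 D_mean_sd = D_mean_sd, f_mean_sd = f_mean_sd,
                 Dstar_mean_sd = Dstar_mean_sd, suv_mean_sd = suv_mean_sd,
                 gtv_cc_mean_sd = gtv_cc_mean_sd,
                 r_suv_d = r_suv_d, r_suv_f = r_suv_f, snr = snr,
                 grid_shape = grid_shape, voxel_size = voxel_size,
                 bvalues = bvalues, response_coupling = response_coupling,
                 seed = as.integer(seed)),
            class = "cohort_params")
}

rnorm_clipped <- function(n, mean, sd, lo, hi) clip(stats::rnorm(n, mean, sd),
                                                    c(lo, hi))

# Couple an SUV map to the (D, f) maps inside the GTV: build a latent
# Gaussian score with prescribed correlations to the normal scores of D and
# f, then map it through a monotone increasing transform to positive SUV
# values with the requested tumor mean. Spearman correlations are invariant
# to the monotone transform, so the realized rank correlations track the
# latent Pearson targets. The independent component is a smooth random
# field with the same correlation length as the parameter maps (not white
# noise), so later interpolation attenuates all components alike and the
# correlation survives resampling; it is orthogonalized in-sample, making
# the latent Pearson correlations exact.
couple_suv <- function(truth, idx, target_r_d, target_r_f, suv_mean, eps) {
  n <- length(idx)
  zs <- function(v) stats::qnorm((rank(v, ties.method = "average") - 0.5) / n)
  std <- function(v) (v - mean(v)) / stats::sd(v)
  zD <- std(zs(truth$true_D[idx]))
  zf <- std(zs(truth$true_f[idx]))
  r12 <- stats::cor(zD, zf)
  if (abs(r12) > 0.999) r12 <- sign(r12) * 0.999
  u2 <- std(stats::residuals(stats::lm.fit(cbind(1, zD), zf)))
  e3 <- std(stats::residuals(stats::lm.fit(cbind(1, zD, u2), eps)))
  c1 <- target_r_d
  c2 <- (target_r_f - target_r_d * r12) / sqrt(1 - r12^2)
  c3sq <- 1 - c1^2 - c2^2
  if (c3sq <= 0)
    stop("infeasible voxel-wise correlation targets (", target_r_d, ", ",
         target_r_f, ") given the D-f map correlation r = ",
         signif(r12, 3))
  s <- c1 * zD + c2 * u2 + sqrt(c3sq) * e3
  suv <- exp(0.4 * s)
  suv * suv_mean / mean(suv)
}

#' Simulate a multi-patient pre/on-treatment imaging cohort
#'
#' Generates `n_patients` digital phantoms with per-patient tumor means
#' drawn from the configured Normal distributions, each with:
#' a pre-treatment multi-b-value DWI series with Rician noise; a
#' ground-truth SUV map coupled voxel-wise to (D, f) at the target rank
#' correlations, acquired on a deliberately offset/rotated PET grid with
#' the true rigid transform stored; and an on-treatment follow-up with
#' volume shrinkage and increased tumor D and f. Shrinkage is coupled to
#' the tumor's SUV^hi D^lo composition (computed against the cohort's
#' generation-target means), so metabolically active, high-cellularity
#' tumors shrink more — giving ground-truth associations between
#' composition and volume change.
#'
#' @param params a [cohort_params()].
#' @return a `cohort_dataset`: list of per-patient records (`patient_id`,
#'   `truth_pre`, `truth_on`, `dwi_pre`, `dwi_on`, `suv_pet`, `suv_grid`,
#'   `true_transform`, `drawn` parameters, `vcf` applied volume change),
#'   plus `params`.
#' @export
simulate_cohort <- function(params = cohort_params()) {
  set.seed(params$seed)
  n <- params$n_patients
  draw <- data.frame(
    patient = sprintf("P%02d", seq_len(n)),
    D = rnorm_clipped(n, params$D_mean_sd[1], params$D_mean_sd[2],
                      0.5e-3, 2.0e-3),
    f = rnorm_clipped(n, params$f_mean_sd[1], params$f_mean_sd[2],
                      0.05, 0.30),
    Dstar = rnorm_clipped(n, params$Dstar_mean_sd[1], params$Dstar_mean_sd[2],
                          6e-3, 25e-3),
    suv = rnorm_clipped(n, params$suv_mean_sd[1], params$suv_mean_sd[2],
                        1.2, 9),
    gtv_cc = rnorm_clipped(n, params$gtv_cc_mean_sd[1],
                           params$gtv_cc_mean_sd[2], 12, 150),
    stringsAsFactors = FALSE)
  pet_angles <- matrix(stats::runif(3 * n, -3, 3) * pi / 180, ncol = 3)
  pet_shift <- matrix(stats::runif(3 * n, -6, 6), ncol = 3)
  resp_noise <- stats::rnorm(n, 0, 0.06)
  dD <- pmax(stats::rnorm(n, 0.12e-3, 0.04e-3), 0.02e-3)
  df_ <- pmax(stats::rnorm(n, 0.030, 0.010), 0.005)

  grid_extent <- params$grid_shape * params$voxel_size
  patients <- vector("list", n)
  frac_hilo <- numeric(n)
  for (i in seq_len(n)) {
    d <- draw[i, ]
    radius <- (3 * d$gtv_cc * 1000 / (4 * pi))^(1 / 3)
    if (any(2 * (radius + 2 * params$voxel_size) > grid_extent))
      stop("drawn tumor does not fit the cohort grid; enlarge grid_shape")
    tm <- default_tissue_means()
    split <- function(m, up) list(rim = m * (1 + up), core = m * (1 - up))
    sD <- split(d$D, 0.12); sf <- split(d$f, 0.18); sDs <- split(d$Dstar, 0.06)
    tm$rim$D <- sD$rim;  tm$core$D <- sD$core
    tm$rim$f <- sf$rim;  tm$core$f <- sf$core
    tm$rim$Dstar <- sDs$rim; tm$core$Dstar <- sDs$core
    seed_i <- params$seed * 1000L + i
    truth <- make_phantom(params$grid_shape, params$voxel_size,
                          tumor_radii_mm = rep(radius, 3),
                          tissue_means = tm, noise_frac = 0.08,
                          smooth_sigma_mm = 1.5 * params$voxel_size,
                          seed = seed_i)
    # SUV ground truth: coupled inside the GTV, quiet background elsewhere.
    # PET acquisition on an offset grid; transform maps PET-world -> MR-world
    set.seed(seed_i + 1L)
    idx <- which(truth$gtv_mask)
    tfm <- rigid_transform(pet_angles[i, ], pet_shift[i, ],
                           center = grid_center_world(truth$grid))
    pet_grid <- truth$grid
    # Calibrate the latent coupling so the rank correlation realized after
    # the PET acquisition (resampled back onto the MR grid) meets the
    # target. Interpolation at the GTV boundary mixes tumor and background
    # uptake, which by itself induces a negative edge correlation with the
    # (rim-high) D map, so the realized r is an affine-like function of the
    # latent target with a nonzero intercept; a secant iteration on a
    # frozen noise field solves for the latent targets that realize the
    # requested correlations.
    eps <- smooth_field(truth$grid$shape,
                        1.5 * params$voxel_size /
                          mean(truth$grid$voxel_size))[idx]
    realized <- function(t_d, t_f) {
      truth$true_SUV[idx] <<- couple_suv(truth, idx, t_d, t_f, d$suv, eps)
      suv_pet <<- resample(truth$true_SUV, truth$grid,
                           invert_transform(tfm), pet_grid, "trilinear")
      suv_pet[!is.finite(suv_pet)] <<- 0
      suv_rt <- resample(suv_pet, pet_grid, tfm, truth$grid, "trilinear")
      mm <- truth$gtv_mask & is.finite(suv_rt)
      c(voxelwise_correlation(suv_rt, truth$true_D, mm)$r,
        voxelwise_correlation(suv_rt, truth$true_f, mm)$r)
    }
    suv_pet <- NULL
    target <- c(params$r_suv_d, params$r_suv_f)
    t1 <- target
    r1 <- realized(t1[1], t1[2])
    if (max(abs(r1 - target)) > 0.02) {
      t2 <- clip(t1 + (target - r1), c(-0.7, 0.7))
      for (cal in 1:4) {
        r2 <- realized(t2[1], t2[2])
        if (max(abs(r2 - target)) < 0.02) break
        slope <- (r2 - r1) / ifelse(abs(t2 - t1) > 1e-6, t2 - t1, 1)
        slope[!is.finite(slope) | abs(slope) < 0.2] <- 1
        t3 <- clip(t2 + (target - r2) / slope, c(-0.7, 0.7))
        t1 <- t2; r1 <- r2; t2 <- t3
      }
    }
    sigma <- truth$tissue_means$rim$S0 / params$snr
    dwi_pre <- simulate_dwi(truth, params$bvalues, sigma, seed = seed_i + 2L)

    frac_hilo[i] <- mean(truth$true_SUV[idx] > params$suv_mean_sd[1] &
                           truth$true_D[idx] < params$D_mean_sd[1])
    patients[[i]] <- list(patient_id = d$patient, truth_pre = truth,
                          dwi_pre = dwi_pre, suv_pet = suv_pet,
                          suv_grid = pet_grid, true_transform = tfm,
                          drawn = d, seed = seed_i)
  }

  # shrinkage coupled to SUV^hi D^lo composition (centred within cohort)
  vcf <- clip(-0.45 - params$response_coupling *
                (frac_hilo - mean(frac_hilo)) + resp_noise, c(-0.85, -0.05))
  for (i in seq_len(n)) {
    resp <- response_params(volume_change_frac = vcf[i], delta_D = dD[i],
                            delta_f = df_[i], per_voxel_jitter_sd = 0.05)
    truth_on <- simulate_followup(patients[[i]]$truth_pre, resp,
                                  seed = patients[[i]]$seed + 3L)
    sigma <- truth_on$tissue_means$rim$S0 / params$snr
    patients[[i]]$truth_on <- truth_on
    patients[[i]]$dwi_on <- simulate_dwi(truth_on, params$bvalues, sigma,
                                         seed = patients[[i]]$seed + 4L)
    patients[[i]]$vcf <- vcf[i]
    patients[[i]]$response <- resp
  }
  structure(list(patients = patients, params = params,
                 frac_hilo_true = frac_hilo),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("cohort_dataset: %d patients, %s grid @ %g mm, seed %d\n",
              length(x$patients),
              paste(x$params$grid_shape, collapse = "x"),
              x$params$voxel_size[1], x$params$seed))
  invisible(x)
}
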