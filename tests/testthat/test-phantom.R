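test_that("voxelized GTV volume matches the analytic ellipsoid volume", {
  ph <- make_phantom(grid_shape = c(64, 64, 64), voxel_size = 2,
                     tumor_radii_mm = c(25, 25, 25), seed = 1)
  analytic <- 4 / 3 * pi * 25^3 / 1000
  expect_lt(abs(mask_volume_cc(ph$gtv_mask, ph$grid) - analytic) / analytic,
            0.01)
  expect_identical(ph$gtv_mask, ph$label_map >= 2L)
})

test_that("phantom respects parameter bounds and compartment separation", {
  ph <- make_phantom(seed = 4, noise_frac = 0.1)
  pri <- ivim_priors()
  for (m in list(ph$true_D, ph$true_f, ph$true_Dstar))
    expect_true(all(is.finite(m)))
  expect_true(all(ph$true_D >= pri$D[1] & ph$true_D <= pri$D[2]))
  expect_true(all(ph$true_f >= pri$f[1] & ph$true_f <= pri$f[2]))
  expect_true(all(ph$true_Dstar > ph$true_D))
  # core has lower D and f, higher SUV than the rim
  expect_lt(mean(ph$true_D[ph$label_map == 3]),
            mean(ph$true_D[ph$label_map == 2]))
  expect_lt(mean(ph$true_f[ph$label_map == 3]),
            mean(ph$true_f[ph$label_map == 2]))
  expect_gt(mean(ph$true_SUV[ph$label_map == 3]),
            mean(ph$true_SUV[ph$label_map == 2]))
})

test_that("zero spatial noise gives piecewise-constant maps and rejection guards fire", {
  ph <- tiny_phantom(noise_frac = 0)
  for (lab in 1:3)
    expect_length(unique(ph$true_D[ph$label_map == lab]), 1L)
  expect_error(make_phantom(grid_shape = c(20, 20, 20), voxel_size = 2,
                            tumor_radii_mm = c(30, 30, 30)),
               "does not fit")
  expect_error(make_phantom(voxel_size = -1), "positive")
})

test_that("phantom generation is bit-reproducible given the seed", {
  expect_identical(make_phantom(seed = 9), make_phantom(seed = 9))
  a <- simulate_dwi(tiny_phantom(), seed = 5)
  b <- simulate_dwi(tiny_phantom(), seed = 5)
  expect_identical(a, b)
})

test_that("zero-noise DWI equals the forward model exactly", {
  ph <- tiny_phantom(noise_frac = 0.05)
  dwi <- simulate_dwi(ph, sigma = 0)
  b <- dwi$bvalues
  expect_identical(dwi$data[, , , 1], ph$true_S0)
  i <- which(ph$gtv_mask)[c(1, 50, 200)]
  for (v in i) {
    ijk <- arrayInd(v, ph$grid$shape)
    expect_equal(dwi$data[ijk[1], ijk[2], ijk[3], ],
                 ivim_signal(b, ph$true_S0[v], ph$true_D[v], ph$true_f[v],
                             ph$true_Dstar[v]),
                 tolerance = 1e-12)
  }
  expect_error(simulate_dwi(ph, bvalues = c(10, 50, 200, 800)), "b = 0")
})

test_that("background magnitude noise has the Rayleigh mean", {
  ph <- tiny_phantom(noise_frac = 0)
  dwi <- simulate_dwi(ph, sigma = 40, seed = 2)
  bgv <- dwi$data[, , , 1][ph$label_map == 0L]
  expect_gt(length(bgv), 500)
  expect_equal(mean(bgv), 40 * sqrt(pi / 2), tolerance = 0.05)
})

test_that("follow-up shrinks the GTV to the requested volume and shifts D and f", {
  ph <- tiny_phantom(noise_frac = 0.05)
  v_pre <- mask_volume_cc(ph$gtv_mask, ph$grid)
  resp <- response_params(volume_change_frac = -0.5, delta_D = 0.1e-3,
                          delta_f = 0.02, per_voxel_jitter_sd = 0)
  on <- simulate_followup(ph, resp)
  v_on <- mask_volume_cc(on$gtv_mask, on$grid)
  expect_lt(abs(v_on - 0.5 * v_pre), 0.02 * v_pre + voxel_volume_cc(ph$grid))
  # jitter-free additive shift is exact where no clipping occurs
  idx <- which(on$gtv_mask)
  expect_equal(on$true_D[idx], pmin(ph$true_D[idx] + 0.1e-3, 3e-3),
               tolerance = 1e-12)
  expect_equal(on$true_f[idx], pmin(ph$true_f[idx] + 0.02, 0.5),
               tolerance = 1e-12)
})

test_that("identity response parameters leave the phantom unchanged inside the GTV", {
  ph <- tiny_phantom(noise_frac = 0.05)
  on <- simulate_followup(ph, response_params(0, 0, 0, 0))
  expect_identical(on$gtv_mask, ph$gtv_mask)
  idx <- which(ph$gtv_mask)
  expect_equal(on$true_D[idx], ph$true_D[idx])
  expect_equal(on$true_f[idx], ph$true_f[idx])
  expect_error(simulate_followup(ph, response_params(-0.99999)),
               "no tumor voxels")
})

test_that("cohort draws match the requested distributions and correlation targets", {
  co <- simulate_cohort(cohort_params(n_patients = 20, seed = 2))
  expect_length(co$patients, 20)
  truD <- vapply(co$patients, function(p)
    mean(p$truth_pre$true_D[p$truth_pre$gtv_mask]), 0)
  se <- 0.2e-3 / sqrt(20)
  expect_lt(abs(mean(truD) - 1.07e-3), 2 * se)
  # stored true transform composes with its inverse to the identity
  for (p in co$patients[1:3]) {
    m <- compose_transform(p$true_transform,
                           invert_transform(p$true_transform))$matrix
    expect_lt(max(abs(m - diag(4))), 1e-10)
  }
  # realized voxel-wise coupling close to target on the generated data
  rs <- vapply(co$patients, function(p) {
    suv_rt <- resample(p$suv_pet, p$suv_grid, p$true_transform,
                       p$truth_pre$grid, "trilinear")
    m <- p$truth_pre$gtv_mask & is.finite(suv_rt)
    voxelwise_correlation(suv_rt, p$truth_pre$true_D, m)$r
  }, 0)
  expect_lt(abs(mean(rs) - (-0.15)), 0.1)
  # on-treatment tumors shrank and D increased
  expect_true(all(vapply(co$patients, function(p) p$vcf, 0) < 0))
})

test_that("zero correlation target yields uncoupled SUV maps", {
  cp <- cohort_params(n_patients = 4, r_suv_d = 0, r_suv_f = 0,
                      grid_shape = c(24, 24, 24), voxel_size = 4,
                      gtv_cc_mean_sd = c(40, 10), seed = 5)
  co <- simulate_cohort(cp)
  rs <- vapply(co$patients, function(p) {
    suv_rt <- resample(p$suv_pet, p$suv_grid, p$true_transform,
                       p$truth_pre$grid, "trilinear")
    m <- p$truth_pre$gtv_mask & is.finite(suv_rt)
    voxelwise_correlation(suv_rt, p$truth_pre$true_D, m)$r
  }, 0)
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("infeasible correlation targets are rejected with a diagnostic", {
  expect_error(cohort_params(r_suv_d = -1.2), "target correlations")
  ph <- tiny_phantom(noise_frac = 0.05)
  idx <- which(ph$gtv_mask)
  eps <- rnorm(length(idx))
  expect_error(
    prmivim:::couple_suv(ph, idx, -0.9, 0.7, 3.7, eps),
    "infeasible")
})
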