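test_that("masked mean is the arithmetic mean over included voxels", {
  m <- array(c(1, 2, 3, 4, 99, 99), c(3, 2, 1))
  mask <- array(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE), c(3, 2, 1))
  expect_equal(as.numeric(masked_mean(m, mask)), 2.5)
  mask[4] <- FALSE
  expect_equal(as.numeric(masked_mean(m, mask)), 2)
  const <- array(7, c(2, 2, 2))
  expect_equal(as.numeric(masked_mean(const, array(TRUE, c(2, 2, 2)))), 7)
  # missing-coded voxels are excluded and counted
  m[2] <- NA
  mask2 <- array(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE), c(3, 2, 1))
  mm <- masked_mean(m, mask2)
  expect_equal(as.numeric(mm), (1 + 3 + 4) / 3)
  expect_identical(attr(mm, "n_missing"), 1L)
  expect_error(masked_mean(m, array(FALSE, c(3, 2, 1))), "empty mask")
})

test_that("population thresholds are exact unweighted means with provenance", {
  df <- data.frame(patient = c("a", "b", "c"),
                   mean_SUV = c(3, 4, 5),
                   mean_D = c(1.0e-3, 1.1e-3, 1.2e-3),
                   mean_f = c(0.1, 0.12, 0.14))
  thr <- cohort_thresholds(df)
  expect_identical(thr$mu_D, 1.1e-3)
  expect_identical(thr$mu_SUV, 4)
  expect_identical(thr$provenance, c("a", "b", "c"))
  one <- data.frame(patient = c("a", "b"), mean_SUV = c(2, 2),
                    mean_D = c(1e-3, 1e-3), mean_f = c(0.1, 0.1))
  expect_identical(cohort_thresholds(one)$mu_SUV, 2)
  expect_error(cohort_thresholds(df[c(1, 1, 2), ]), "duplicate")
  expect_error(cohort_thresholds(df[1, ]), "two patients")
})

test_that("joint-histogram classification follows the hi/lo rule with lo ties", {
  # single forced voxel: SUV above, D below the thresholds -> class 2
  a <- array(5.0, c(1, 1, 1)); b <- array(0.8e-3, c(1, 1, 1))
  mask <- array(TRUE, c(1, 1, 1))
  lab <- classify_prm(a, b, 3.7, 1.07e-3, mask, "SUVxD")
  expect_identical(lab$labels[1], 2L)
  expect_identical(lab$palette[["2"]], "magenta")
  # equality classifies lo
  lab_eq <- classify_prm(array(3.7, c(1, 1, 1)), b, 3.7, 1.07e-3, mask)
  expect_identical(lab_eq$labels[1], 3L)
  # one voxel in each quadrant
  a4 <- array(c(5, 5, 1, 1), c(2, 2, 1))
  b4 <- array(c(2, 0.5, 0.5, 2), c(2, 2, 1))
  l4 <- classify_prm(a4, b4, 3, 1, array(TRUE, c(2, 2, 1)))
  expect_setequal(as.integer(l4$labels), 1:4)
  expect_error(classify_prm(a4, b4, 3, 1, mask), "shape")
  expect_error(classify_prm(a4, b4, -1, 1, array(TRUE, c(2, 2, 1))),
               "positive")
})

test_that("classification agrees voxel-for-voxel with the naive reference", {
  set.seed(14)
  for (rep in 1:5) {
    d <- c(10, 10, 10)
    a <- array(rexp(1000, 1 / 3), d)
    b <- array(rnorm(1000, 1e-3, 4e-4), d)
    mask <- array(runif(1000) < 0.8, d)
    a[sample(1000, 20)] <- NA
    mu_a <- 3; mu_b <- 1e-3
    got <- suppressMessages(classify_prm(a, b, mu_a, mu_b, mask))
    expect_identical(got$labels, naive_prm_reference(a, b, mu_a, mu_b, mask))
  }
})

test_that("fractions normalize counts to relative volume percentages", {
  d <- c(2, 2, 1)
  lab <- classify_prm(array(c(5, 5, 1, 1), d), array(c(2, 0.5, 0.5, 2), d),
                      3, 1, array(TRUE, d))
  fr <- prm_fractions(lab)
  expect_equal(unname(fr$percent), rep(25, 4))
  expect_identical(fr$total_voxels, 4L)
  # all voxels in one class
  lab3 <- classify_prm(array(1, d), array(0.5, d), 3, 1, array(TRUE, d))
  expect_equal(unname(prm_fractions(lab3)$percent), c(0, 0, 100, 0))
  # random instance equals brute-force counting, sums to 100
  set.seed(2)
  a <- array(runif(1000), c(10, 10, 10))
  b <- array(runif(1000), c(10, 10, 10))
  fr2 <- prm_fractions(classify_prm(a, b, 0.5, 0.5,
                                    array(TRUE, c(10, 10, 10))))
  ref <- naive_prm_reference(a, b, 0.5, 0.5, array(TRUE, c(10, 10, 10)))
  expect_equal(unname(fr2$percent),
               vapply(1:4, function(k) sum(ref == k), 0) * 0.1)
  expect_equal(sum(fr2$percent), 100, tolerance = 1e-9)
  empty <- lab3; empty$labels[] <- 0L
  expect_error(prm_fractions(empty), "no classified voxels")
})

test_that("class fractions respond monotonically to the first threshold", {
  set.seed(6)
  a <- array(runif(1000, 0, 10), c(10, 10, 10))
  b <- array(runif(1000), c(10, 10, 10))
  mask <- array(TRUE, c(10, 10, 10))
  his <- vapply(seq(0.5, 9.5, length.out = 50), function(mu) {
    fr <- prm_fractions(classify_prm(a, b, mu, 0.5, mask))
    sum(fr$percent[c("hi_hi", "hi_lo")])
  }, 0)
  expect_true(all(diff(his) <= 0))
})

test_that("fractions are invariant to voxel relabeling and exact on a constructed phantom", {
  set.seed(10)
  a <- array(runif(512), c(8, 8, 8))
  b <- array(runif(512), c(8, 8, 8))
  mask <- array(TRUE, c(8, 8, 8))
  f1 <- prm_fractions(classify_prm(a, b, 0.4, 0.6, mask))
  perm <- sample(512)
  f2 <- prm_fractions(classify_prm(array(a[perm], dim(a)),
                                   array(b[perm], dim(b)), 0.4, 0.6, mask))
  expect_equal(f1$percent, f2$percent)
  # piecewise-constant phantom straddling thresholds: exact tissue ratios
  ph <- tiny_phantom(noise_frac = 0)
  lab <- classify_prm(ph$true_SUV, ph$true_D,
                      mean(range(ph$true_SUV[ph$gtv_mask])),
                      mean(range(ph$true_D[ph$gtv_mask])),
                      ph$gtv_mask, "SUVxD")
  fr <- prm_fractions(lab)
  n_core <- sum(ph$label_map == 3L); n_rim <- sum(ph$label_map == 2L)
  # core: SUV hi / D lo (class 2); rim: SUV lo / D hi (class 4)
  expect_equal(unname(fr$percent["hi_lo"]), 100 * n_core / (n_core + n_rim))
  expect_equal(unname(fr$percent["lo_hi"]), 100 * n_rim / (n_core + n_rim))
})
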