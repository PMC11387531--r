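# Small shared fixtures, built once per test run.

table1_params <- function() {
  list(S0 = 1000, D = 1.07e-3, f = 0.127, Dstar = 13.7e-3)
}

# tiny noiseless phantom used across modules
tiny_phantom <- function(seed = 11, noise_frac = 0) {
  make_phantom(grid_shape = c(20, 20, 20), voxel_size = 4,
               tumor_radii_mm = c(22, 20, 24), noise_frac = noise_frac,
               seed = seed)
}

# moderate phantom for registration tests
reg_phantom <- function() {
  make_phantom(grid_shape = c(32, 32, 32), voxel_size = 4,
               tumor_radii_mm = c(30, 26, 28), seed = 3)
}

# simulate one Rician-noised voxel signal at the given parameters
rician_signal <- function(b, pars, sigma) {
  s <- ivim_signal(b, pars$S0, pars$D, pars$f, pars$Dstar)
  sqrt((s + stats::rnorm(length(b), 0, sigma))^2 +
         stats::rnorm(length(b), 0, sigma)^2)
}

# independent naive PRM reference: explicit per-voxel double loop
naive_prm_reference <- function(map_A, map_B, mu_A, mu_B, mask) {
  labels <- array(0L, dim(mask))
  for (i in seq_along(mask)) {
    if (!mask[i]) next
    a <- map_A[i]; b <- map_B[i]
    if (!is.finite(a) || !is.finite(b)) next
    labels[i] <- if (a > mu_A) {
      if (b > mu_B) 1L else 2L
    } else {
      if (b > mu_B) 4L else 3L
    }
  }
  labels
}

# exact Wilcoxon signed-rank enumeration oracle (mid-ranks, all 2^n signs)
enum_wilcoxon_p <- function(x, y) {
  d <- (y - x)
  d <- d[d != 0]
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), length(d))))
  Vs <- as.numeric(signs %*% r)
  min(1, 2 * min(mean(Vs >= V), mean(Vs <= V)))
}

# exact Spearman permutation oracle (all n! permutations)
enum_spearman_p <- function(x, y) {
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  obs <- stats::cor(x, y, method = "spearman")
  ry <- rank(y)
  rhos <- vapply(perms(seq_along(x)),
                 function(p) stats::cor(rank(x), ry[p]), 0)
  mean(abs(rhos) >= abs(obs) - 1e-12)
}
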