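#' IVIM bi-exponential forward signal model
#'
#' Two-compartment intravoxel incoherent motion model:
#' \deqn{S(b) = S_0 [ f e^{-b D^*} + (1 - f) e^{-b D} ]}
#' where `D` is the tissue diffusion coefficient (mm^2/s), `f` the perfusion
#' fraction and `Dstar` the pseudo-diffusion coefficient of the capillary
#' compartment (mm^2/s).
#'
#' @param b diffusion weighting, s/mm^2 (vectorised).
#' @param S0 signal at b = 0, arbitrary units.
#' @param D diffusion coefficient, mm^2/s.
#' @param f perfusion fraction in [0, 1].
#' @param Dstar pseudo-diffusion coefficient, mm^2/s.
#' @return noiseless signal, same length as `b`.
#' @export
ivim_signal <- function(b, S0, D, f, Dstar) {
  if (any(b < 0)) stop("b-values must be non-negative")
  S0 * (f * exp(-b * Dstar) + (1 - f) * exp(-b * D))
}

#' b-value acquisition scheme
#'
#' @param bvalues numeric vector of diffusion weightings, s/mm^2. Must be
#'   strictly increasing, non-negative, contain 0, and have at least four
#'   entries (the minimum to identify S0, D, f and D*).
#' @return object of class `bvalue_scheme`.
#' @export
bvalue_scheme <- function(bvalues = default_bvalues()) {
  bvalues <- as.numeric(bvalues)
  if (length(bvalues) < 4L)
    stop("at least four b-values are required to identify S0, D, f and D*")
  if (any(bvalues < 0)) stop("b-values must be non-negative")
  if (any(diff(bvalues) <= 0)) stop("b-values must be strictly increasing")
  if (bvalues[1] != 0)
    stop("the scheme must contain b = 0 (required to anchor S0)")
  structure(list(bvalues = bvalues), class = "bvalue_scheme")
}

#' Default 11-b-value scheme
#'
#' Dense sampling below 200 s/mm^2 (needed to separate the perfusion
#' compartment) plus diffusion-dominated points up to 800 s/mm^2.
#' @return numeric vector of 11 b-values, s/mm^2.
#' @export
default_bvalues <- function() c(0, 10, 20, 30, 50, 80, 100, 150, 200, 500, 800)

#' Prior bounds for IVIM parameters
#'
#' Uniform box priors. The upper bound on D sits below the lower bound on
#' D*, which enforces identifiability of the two compartments.
#'
#' @param D,f,Dstar,S0 length-2 numeric bounds `c(lower, upper)`. The S0
#'   default is resolved against the data as `c(0, 2 * max(signal))` at fit
#'   time when `NULL`.
#' @return object of class `ivim_priors`.
#' @export
ivim_priors <- function(D = c(1e-5, 3e-3), f = c(0, 0.5),
                        Dstar = c(3e-3, 0.3), S0 = NULL) {
  for (b in list(D = D, f = f, Dstar = Dstar))
    if (length(b) != 2L || b[1] >= b[2])
      stop("each prior bound must be c(lower, upper) with lower < upper")
  if (D[2] > Dstar[1])
    stop("upper bound of D must lie below the lower bound of D* ",
         "(compartment identifiability)")
  structure(list(D = D, f = f, Dstar = Dstar, S0 = S0, family = "uniform"),
            class = "ivim_priors")
}

#' Settings for the grid-marginalised Bayesian fitter
#'
#' The posterior over (D, f, D*) is evaluated on a dense grid with S0 and
#' the noise scale marginalised analytically, then refined on successively
#' finer local grids around the posterior bulk.
#'
#' @param n_D,n_f,n_Dstar coarse grid sizes per dimension (D and f linear,
#'   D* log-spaced).
#' @param n_refine points per dimension of each local refinement grid.
#' @param refine_stages number of refinement passes.
#' @return list of class `ivim_sampler_settings`.
#' @export
ivim_sampler_settings <- function(n_D = 48L, n_f = 40L, n_Dstar = 24L,
                                  n_refine = 15L, refine_stages = 3L) {
  structure(list(n_D = as.integer(n_D), n_f = as.integer(n_f),
                 n_Dstar = as.integer(n_Dstar),
                 n_refine = as.integer(n_refine),
                 refine_stages = as.integer(refine_stages)),
            class = "ivim_sampler_settings")
}

new_ivim_estimate <- function(D, f, Dstar, S0, sds = rep(NA_real_, 4),
                              flag = "ok", method = "lsq") {
  list(D_hat = D, f_hat = f, Dstar_hat = Dstar, S0_hat = S0,
       D_sd = sds[1], f_sd = sds[2], Dstar_sd = sds[3], S0_sd = sds[4],
       flag = flag, method = method)
}

failed_estimate <- function(method, flag = "failed") {
  new_ivim_estimate(NA_real_, NA_real_, NA_real_, NA_real_,
                    flag = flag, method = method)
}

# TRUE when the scheme carries no b-value in (0, b_split): without
# perfusion-sensitive low-b points, f and D* are not identifiable.
scheme_identifies_perfusion <- function(scheme, b_split = 200) {
  any(scheme$bvalues > 0 & scheme$bvalues < b_split)
}

clip <- function(x, bounds) pmin(pmax(x, bounds[1]), bounds[2])

#' Segmented least-squares IVIM fit of one voxel
#'
#' Reference fitter: log-linear regression on the diffusion-dominated
#' segment (b >= `b_split`) gives D and the extrapolated zero-b intercept;
#' the perfusion fraction follows as `1 - intercept / S(0)`; D* is then
#' refined by bounded one-dimensional least squares with (S0, D, f) held.
#'
#' @param signal numeric vector, one value per b-value.
#' @param scheme a [bvalue_scheme()].
#' @param priors an [ivim_priors()]; estimates are clipped to these bounds
#'   and flagged when clipping occurs.
#' @param b_split boundary (s/mm^2) between perfusion- and
#'   diffusion-dominated regimes.
#' @return an IVIM estimate (list with `D_hat`, `f_hat`, `Dstar_hat`,
#'   `S0_hat`, posterior/fit SDs, `flag`, `method`).
#' @export
fit_voxel_lsq <- function(signal, scheme, priors = ivim_priors(),
                          b_split = 200) {
  b <- scheme$bvalues
  if (length(signal) != length(b))
    stop("signal length (", length(signal), ") does not match the number of ",
         "b-values (", length(b), ")")
  if (any(!is.finite(signal)) || all(signal == 0) || signal[b == 0] <= 0)
    return(failed_estimate("lsq"))
  if (!scheme_identifies_perfusion(scheme, b_split)) {
    s0 <- signal[b == 0]
    hi <- b >= b_split | b == 0
    dfit <- mono_exp_fit(b[hi], signal[hi])
    est <- failed_estimate("lsq", flag = "unidentifiable")
    est$D_hat <- clip(dfit$D, priors$D); est$S0_hat <- s0
    return(est)
  }

  s0_obs <- signal[b == 0]
  hi <- b >= b_split
  dfit <- mono_exp_fit(b[hi], signal[hi])
  if (is.null(dfit)) return(failed_estimate("lsq"))
  D <- dfit$D
  f <- 1 - dfit$intercept / s0_obs
  flag <- "ok"
  if (D < priors$D[1] || D > priors$D[2] || f < priors$f[1] ||
      f > priors$f[2]) flag <- "clipped"
  D <- clip(D, priors$D)
  f <- clip(f, priors$f)
  S0 <- s0_obs

  # bounded 1-D refinement of D* with (S0, D, f) held
  rss <- function(ds) sum((signal - ivim_signal(b, S0, D, f, ds))^2)
  Dstar <- if (f > 1e-6)
    stats::optimize(rss, interval = priors$Dstar)$minimum
  else priors$Dstar[1]

  # perfusion-subtraction iterations: the high-b segment still carries a
  # slowly decaying perfusion remnant that tilts the log-linear slope;
  # alternately removing the fitted perfusion signal, refitting (D, f) and
  # re-refining D* converges to the exact parameters on noiseless input
  for (it in 1:4) {
    if (f <= 1e-6) break
    corr <- signal - S0 * f * exp(-b * Dstar)
    dfit2 <- mono_exp_fit(b[hi], corr[hi])
    if (is.null(dfit2)) break
    D <- clip(dfit2$D, priors$D)
    f <- clip(1 - dfit2$intercept / s0_obs, priors$f)
    Dstar <- stats::optimize(rss, interval = priors$Dstar,
                             tol = 1e-6)$minimum
  }
  new_ivim_estimate(D, f, Dstar, S0, flag = flag, method = "lsq")
}

# log-linear mono-exponential fit; NULL when degenerate
mono_exp_fit <- function(b, s) {
  ok <- s > 0
  if (sum(ok) < 2L) return(NULL)
  co <- stats::lsfit(b[ok], log(s[ok]))$coefficients
  list(intercept = exp(co[1]), D = max(-co[2], 0))
}

# ---- grid-marginalised Bayesian machinery ----------------------------------

# decay-curve design matrix: one row per (D, f, Dstar) grid point, one
# column per b-value; value f*exp(-b*Dstar) + (1-f)*exp(-b*D)
decay_matrix <- function(D, f, Dstar, b) {
  ed <- exp(-outer(D, b))        # nG x nb
  es <- exp(-outer(Dstar, b))
  f * es + (1 - f) * ed
}

coarse_grid <- function(priors, settings) {
  g <- expand.grid(
    D = seq(priors$D[1], priors$D[2], length.out = settings$n_D),
    f = seq(priors$f[1], priors$f[2], length.out = settings$n_f),
    Dstar = exp(seq(log(priors$Dstar[1]), log(priors$Dstar[2]),
                    length.out = settings$n_Dstar)))
  list(D = g$D, f = g$f, Dstar = g$Dstar,
       step = c(D = diff(priors$D) / (settings$n_D - 1),
                f = diff(priors$f) / (settings$n_f - 1),
                Dstar_logstep = diff(log(priors$Dstar)) /
                  (settings$n_Dstar - 1)))
}

# Log marginal posterior of (D, f, Dstar) given signal y, with S0 (flat
# prior) and noise sigma (Jeffreys prior) integrated out analytically:
#   log p = -0.5*log(a) - ((n-1)/2)*log(c - b^2/a),   a = g'g, b = g'y, c = y'y
# G is the nG x nb decay matrix; Y an nb x V matrix of voxel signals.
# Returns list(logp = nG x V, s0 = nG x V conditional S0 estimates b/a).
grid_log_posterior <- function(G, Y) {
  n <- nrow(Y)
  a <- rowSums(G * G)
  Bm <- G %*% Y                      # nG x V
  cv <- colSums(Y * Y)
  rss <- sweep(-Bm^2 / a, 2, cv, "+")
  rss <- pmax(rss, rep(cv * 1e-14, each = nrow(rss)) + 1e-300)
  logp <- -0.5 * log(a) - ((n - 1) / 2) * log(rss)
  list(logp = logp, s0 = Bm / a)
}

# posterior summaries for one voxel given grid values and log-weights;
# the point estimate carried forward is the posterior mode (the mean is
# badly tail-biased for D* under the wide box prior)
grid_posterior_summary <- function(gr, logp, s0) {
  j <- which.max(logp)
  w <- exp(logp - logp[j])
  w <- w / sum(w)
  mom <- function(x, mode) {
    m <- sum(w * x)
    c(mode = mode, mean = m, sd = sqrt(max(sum(w * x^2) - m^2, 0)))
  }
  list(D = mom(gr$D, gr$D[j]), f = mom(gr$f, gr$f[j]),
       Dstar = mom(gr$Dstar, gr$Dstar[j]), S0 = mom(s0, s0[j]))
}

refine_grid <- function(center, sd, span_min, bounds, n) {
  half <- max(span_min, 3 * sd)
  lo <- max(bounds[1], center - half)
  hi <- min(bounds[2], center + half)
  seq(lo, hi, length.out = n)
}

# one refinement pass around the current posterior mode for one voxel
refine_voxel <- function(y, b, priors, settings, summ, coarse_step) {
  Dax <- refine_grid(summ$D["mode"], summ$D["sd"],
                     2 * coarse_step["D"], priors$D, settings$n_refine)
  fax <- refine_grid(summ$f["mode"], summ$f["sd"],
                     2 * coarse_step["f"], priors$f, settings$n_refine)
  ds_span <- summ$Dstar["mode"] *
    (exp(2 * coarse_step["Dstar_logstep"]) - 1)
  dax <- refine_grid(summ$Dstar["mode"], summ$Dstar["sd"], ds_span,
                     priors$Dstar, settings$n_refine)
  g <- expand.grid(D = Dax, f = fax, Dstar = dax)
  gr <- list(D = g$D, f = g$f, Dstar = g$Dstar)
  G <- decay_matrix(gr$D, gr$f, gr$Dstar, b)
  post <- grid_log_posterior(G, matrix(y, ncol = 1))
  # shrink the follow-up span to the new local cell size
  step <- c(D = diff(range(Dax)) / (settings$n_refine - 1),
            f = diff(range(fax)) / (settings$n_refine - 1),
            Dstar_logstep = diff(log(range(dax))) / (settings$n_refine - 1))
  list(summary = grid_posterior_summary(gr, post$logp[, 1], post$s0[, 1]),
       step = step)
}

bayes_estimate_from_summary <- function(summ, priors, y) {
  s0_bounds <- if (is.null(priors$S0)) c(0, 2 * max(y)) else priors$S0
  flag <- "ok"
  S0 <- summ$S0["mode"]
  if (S0 < s0_bounds[1] || S0 > s0_bounds[2]) {
    S0 <- clip(S0, s0_bounds); flag <- "clipped"
  }
  new_ivim_estimate(unname(summ$D["mode"]), unname(summ$f["mode"]),
                    unname(summ$Dstar["mode"]), unname(S0),
                    sds = unname(c(summ$D["sd"], summ$f["sd"],
                                   summ$Dstar["sd"], summ$S0["sd"])),
                    flag = flag, method = "bayesian")
}

#' Bayesian IVIM fit of one voxel
#'
#' Posterior over (D, f, D*) under a Gaussian likelihood with the noise
#' scale marginalised (Jeffreys prior) and S0 marginalised analytically
#' (flat prior), with uniform box priors on (D, f, D*). The posterior is
#' evaluated by dense-grid marginalisation followed by local grid
#' refinement. The point estimate is the posterior mode: with the wide
#' physiological box prior on D*, the posterior mean is strongly biased
#' upward by the heavy right tail of the weakly identified pseudo-diffusion
#' coefficient, while the mode respects the known recovery hierarchy
#' (D most stable, D* least). Posterior SDs accompany the estimates. The
#' computation is deterministic; `seed` is accepted for interface
#' stability and ignored.
#'
#' @inheritParams fit_voxel_lsq
#' @param sampler an [ivim_sampler_settings()].
#' @param seed unused (the grid estimator is deterministic).
#' @return an IVIM estimate list; on failure the flag is set and, where the
#'   segmented initialiser succeeded, its values are carried as fallback.
#' @export
fit_voxel_bayesian <- function(signal, scheme, priors = ivim_priors(),
                               sampler = ivim_sampler_settings(),
                               seed = NULL) {
  b <- scheme$bvalues
  if (length(signal) != length(b))
    stop("signal length (", length(signal), ") does not match the number of ",
         "b-values (", length(b), ")")
  if (any(!is.finite(signal)) || all(signal == 0) || signal[b == 0] <= 0)
    return(failed_estimate("bayesian"))
  if (!scheme_identifies_perfusion(scheme)) {
    est <- fit_voxel_lsq(signal, scheme, priors)
    est$method <- "bayesian"
    est$flag <- "unidentifiable"
    return(est)
  }
  gr <- coarse_grid(priors, sampler)
  G <- decay_matrix(gr$D, gr$f, gr$Dstar, b)
  post <- grid_log_posterior(G, matrix(signal, ncol = 1))
  summ <- grid_posterior_summary(gr, post$logp[, 1], post$s0[, 1])
  step <- gr$step
  for (k in seq_len(sampler$refine_stages)) {
    r <- refine_voxel(signal, b, priors, sampler, summ, step)
    summ <- r$summary
    step <- r$step
  }
  bayes_estimate_from_summary(summ, priors, signal)
}

#' Fit IVIM maps over a masked volume
#'
#' Applies the chosen per-voxel fitter to every voxel of `mask`. Voxels
#' with non-positive b = 0 signal are excluded from the fit mask. The result
#' is independent of voxel iteration order (the Bayesian path is evaluated
#' in vectorised batches; both fitters are deterministic per voxel).
#'
#' @param dwi a `dwi_series` (see [simulate_dwi()] / [read_dwi()]).
#' @param mask logical 3D array matching the DWI spatial dimensions.
#' @param method `"bayesian"` or `"lsq"`.
#' @param priors an [ivim_priors()].
#' @param sampler an [ivim_sampler_settings()] (Bayesian method only).
#' @param seed unused (deterministic fitters); kept for interface stability.
#' @param chunk voxels per vectorised batch in the Bayesian coarse pass.
#' @return an `ivim_maps` object: 3D `D_map`, `f_map`, `Dstar_map`,
#'   `S0_map` (NA outside `fit_mask`), the logical `fit_mask`, the grid,
#'   and the count of flagged voxels.
#' @export
fit_volume <- function(dwi, mask, method = c("bayesian", "lsq"),
                       priors = ivim_priors(),
                       sampler = ivim_sampler_settings(), seed = NULL,
                       chunk = 128L) {
  method <- match.arg(method)
  sp <- dim(dwi$data)[1:3]
  if (!all(dim(mask) == sp))
    stop("mask shape does not match DWI spatial shape")
  if (!any(mask)) stop("empty mask: no voxels to fit")
  b <- dwi$bvalues
  scheme <- bvalue_scheme(b)
  nb <- length(b)
  vox <- which(mask)
  sig <- matrix(aperm(dwi$data, c(4, 1, 2, 3)), nrow = nb)[, vox, drop = FALSE]

  b0_pos <- sig[which(b == 0), ] > 0 & apply(is.finite(sig), 2, all)
  fit_idx <- vox[b0_pos]
  Y <- sig[, b0_pos, drop = FALSE]

  empty <- array(NA_real_, sp)
  maps <- list(D_map = empty, f_map = empty, Dstar_map = empty,
               S0_map = empty)
  flags <- character(length(fit_idx))

  if (length(fit_idx)) {
    if (method == "lsq") {
      est <- lapply(seq_len(ncol(Y)), function(j)
        fit_voxel_lsq(Y[, j], scheme, priors))
    } else {
      est <- fit_volume_bayes_batched(Y, scheme, priors, sampler, chunk)
    }
    maps$D_map[fit_idx] <- vapply(est, `[[`, 0, "D_hat")
    maps$f_map[fit_idx] <- vapply(est, `[[`, 0, "f_hat")
    maps$Dstar_map[fit_idx] <- vapply(est, `[[`, 0, "Dstar_hat")
    maps$S0_map[fit_idx] <- vapply(est, `[[`, 0, "S0_hat")
    flags <- vapply(est, `[[`, "", "flag")
  }

  fit_mask <- array(FALSE, sp)
  fit_mask[fit_idx] <- TRUE
  structure(c(maps, list(fit_mask = fit_mask, grid = dwi$grid,
                         method = method,
                         n_flagged = sum(flags != "ok"),
                         n_excluded = sum(!b0_pos))),
            class = "ivim_maps")
}

# batched coarse grid pass + per-voxel refinement
fit_volume_bayes_batched <- function(Y, scheme, priors, sampler, chunk) {
  b <- scheme$bvalues
  if (!scheme_identifies_perfusion(scheme)) {
    return(lapply(seq_len(ncol(Y)), function(j)
      fit_voxel_bayesian(Y[, j], scheme, priors, sampler)))
  }
  gr <- coarse_grid(priors, sampler)
  G <- decay_matrix(gr$D, gr$f, gr$Dstar, b)
  V <- ncol(Y)
  out <- vector("list", V)
  for (start in seq(1L, V, by = chunk)) {
    idx <- start:min(start + chunk - 1L, V)
    post <- grid_log_posterior(G, Y[, idx, drop = FALSE])
    for (jj in seq_along(idx)) {
      y <- Y[, idx[jj]]
      summ <- grid_posterior_summary(gr, post$logp[, jj], post$s0[, jj])
      step <- gr$step
      for (k in seq_len(sampler$refine_stages)) {
        r <- refine_voxel(y, b, priors, sampler, summ, step)
        summ <- r$summary
        step <- r$step
      }
      out[[idx[jj]]] <- bayes_estimate_from_summary(summ, priors, y)
    }
  }
  out
}

#' @export
print.ivim_maps <- function(x, ...) {
  cat(sprintf("ivim_maps (%s): %d fitted voxels, %d flagged, %d excluded\n",
              x$method, sum(x$fit_mask), x$n_flagged, x$n_excluded))
  invisible(x)
}
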