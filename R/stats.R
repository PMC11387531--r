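#' Relative percentage change in gross tumor volume
#'
#' Signed convention: `100 * (on - pre) / pre`, so shrinkage is negative.
#'
#' @param gtv_pre_cc,gtv_on_cc tumor volumes in cc, both positive.
#' @return percent change (scalar, signed).
#' @export
delta_gtv <- function(gtv_pre_cc, gtv_on_cc) {
  if (any(!is.finite(c(gtv_pre_cc, gtv_on_cc))) ||
      any(c(gtv_pre_cc, gtv_on_cc) <= 0))
    stop("tumor volumes must be positive and finite")
  100 * (gtv_on_cc - gtv_pre_cc) / gtv_pre_cc
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired differences; zero differences are
#' dropped and ties take mid-ranks (base `wilcox.test` conventions). The
#' exact distribution is used below n = 26 when no ties or zeros are
#' present, the normal approximation with continuity correction otherwise.
#'
#' For small samples with tied absolute differences (where the standard
#' exact distribution is unavailable), the exact conditional distribution
#' is computed by direct enumeration of all sign assignments on the
#' mid-ranks.
#'
#' @param x,y equal-length numeric vectors (pre- and on-treatment values).
#' @return list with `statistic` (V), `p`, `n_effective`, `exact`.
#' @export
wilcoxon_paired <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  d <- y - x
  d <- d[is.finite(d)]
  if (length(d) < 2) stop("too few finite pairs")
  nz <- d[d != 0]
  n <- length(nz)
  if (n == 0) {
    warning("all paired differences are zero; p = 1")
    return(list(statistic = NA_real_, p = 1, n_effective = 0L,
                exact = TRUE))
  }
  r <- rank(abs(nz))
  V <- sum(r[nz > 0])
  ties <- any(duplicated(abs(nz)))
  if (n <= 12) {
    # exact by enumeration of all 2^n sign assignments (valid under ties)
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Vs <- as.numeric(signs %*% r)
    p <- min(1, 2 * min(mean(Vs >= V), mean(Vs <= V)))
    return(list(statistic = V, p = p, n_effective = n, exact = TRUE))
  }
  exact <- n < 26 && !ties
  wt <- suppressWarnings(stats::wilcox.test(y, x, paired = TRUE,
                                            exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       n_effective = n, exact = exact)
}

#' Spearman rank correlation
#'
#' Mid-ranks for ties with the tie-corrected statistic (Pearson correlation
#' of ranks); two-sided p from the exact permutation distribution for
#' n <= 9 without ties, the t approximation otherwise.
#'
#' @param x,y equal-length numeric vectors, n >= 3.
#' @return list with `r`, `p`, `n`; for a constant input, `r` and `p` are
#'   `NA` with `flag = "constant_input"`.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("Spearman correlation needs at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, flag = "constant_input"))
  ties <- anyDuplicated(x) || anyDuplicated(y)
  exact <- n <= 9 && !ties
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = exact))
  list(r = unname(ct$estimate), p = ct$p.value, n = n, flag = "ok")
}

#' Shapiro-Wilk normality test
#'
#' Standard W statistic and p-value; used to justify the fixed choice of
#' non-parametric tests in the cohort reports.
#'
#' @param x numeric vector, 3 <= n <= 5000, non-constant.
#' @return list with `W` and `p`.
#' @export
shapiro_wilk <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3 || length(x) > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::sd(x) == 0) stop("Shapiro-Wilk is undefined for constant input")
  sw <- stats::shapiro.test(x)
  list(W = unname(sw$statistic), p = sw$p.value)
}

#' Voxel-wise Spearman correlation of two co-registered maps
#'
#' Spearman r over masked voxel pairs, excluding missing-coded voxels.
#' Cohorts report the per-patient values as mean +/- SD.
#'
#' @param map_A,map_B co-registered 3D maps.
#' @param mask logical analysis mask.
#' @param min_voxels minimum valid pairs; below it the result is flagged
#'   missing (`NA`).
#' @return list with `r`, `p`, `n_voxels`, `flag`.
#' @export
voxelwise_correlation <- function(map_A, map_B, mask, min_voxels = 10L) {
  if (!all(dim(map_A) == dim(map_B)) || !all(dim(map_A) == dim(mask)))
    stop("maps and mask must share one grid shape")
  a <- map_A[mask]; b <- map_B[mask]
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < min_voxels)
    return(list(r = NA_real_, p = NA_real_, n_voxels = sum(ok),
                flag = "too_few_voxels"))
  s <- spearman(a[ok], b[ok])
  list(r = s$r, p = s$p, n_voxels = s$n, flag = s$flag)
}

#' Associations between pre-treatment metrics and tumor-volume change
#'
#' Spearman correlation of each pre-treatment metric with the relative
#' tumor-volume change. Expected metric columns: `gtv_pre_cc`, `suv_max`,
#' `suv_mean`, `D`, `f`, `Dstar`, the eight SUV-pair PRM percentages
#' (`prm_suv_d_*`, `prm_suv_f_*`) and the four D x f percentages
#' (`prm_d_f_*`). Raw two-sided p-values are reported with a significance
#' flag at alpha = 0.05; a Benjamini-Hochberg column is appended as
#' supplementary output (no correction is applied to the primary flags).
#'
#' @param metrics data.frame, one row per patient, containing `patient`,
#'   `delta_gtv` and the metric columns.
#' @param alpha two-sided significance level.
#' @return data.frame with columns `variable`, `r`, `p`, `n`, `flag`,
#'   `significant`, `p_bh`.
#' @export
association_table <- function(metrics, alpha = 0.05) {
  if (!all(c("patient", "delta_gtv") %in% names(metrics)))
    stop("metrics must contain 'patient' and 'delta_gtv' columns")
  vars <- setdiff(names(metrics), c("patient", "delta_gtv"))
  n_pat <- nrow(metrics)
  rows <- lapply(vars, function(v) {
    x <- metrics[[v]]
    dg <- metrics$delta_gtv
    if (any(!is.finite(x)) || any(!is.finite(dg)))
      return(data.frame(variable = v, r = NA_real_, p = NA_real_,
                        n = n_pat, flag = "missing_values"))
    if (n_pat < 6)
      return(data.frame(variable = v, r = NA_real_, p = NA_real_,
                        n = n_pat, flag = "underpowered"))
    s <- spearman(x, dg)
    data.frame(variable = v, r = s$r, p = s$p, n = s$n, flag = s$flag)
  })
  out <- do.call(rbind, rows)
  out$significant <- !is.na(out$p) & out$p < alpha
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Cohort summary table (mean and SD per metric)
#'
#' @param metrics data.frame, one row per patient; all numeric columns are
#'   summarized.
#' @return data.frame with `variable`, `mean`, `sd`, `n`.
#' @export
summary_table <- function(metrics) {
  num <- vapply(metrics, is.numeric, TRUE)
  vars <- names(metrics)[num]
  data.frame(variable = vars,
             mean = vapply(vars, function(v)
               mean(metrics[[v]], na.rm = TRUE), 0),
             sd = vapply(vars, function(v)
               stats::sd(metrics[[v]], na.rm = TRUE), 0),
             n = vapply(vars, function(v)
               sum(is.finite(metrics[[v]])), 0L),
             row.names = NULL)
}
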