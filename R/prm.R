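#' Mean of a map over a mask
#'
#' Arithmetic mean over masked voxels, excluding (and counting)
#' missing-coded (`NA`/non-finite) voxels.
#'
#' @param map 3D numeric array.
#' @param mask logical array of the same shape.
#' @return scalar mean; attribute `n_missing` carries the excluded count.
#' @export
masked_mean <- function(map, mask) {
  if (!all(dim(map) == dim(mask))) stop("map and mask shapes differ")
  if (!any(mask)) stop("empty mask")
  v <- map[mask]
  miss <- !is.finite(v)
  if (all(miss)) stop("no finite voxels under the mask")
  out <- mean(v[!miss])
  attr(out, "n_missing") <- sum(miss)
  out
}

#' Population-mean PRM thresholds
#'
#' Unweighted means across patients of the spatially averaged pre-treatment
#' SUV, D and f within each patient's GTV. These population means are the
#' hi/lo classification thresholds for all parametric response maps, and
#' are a frozen cohort artifact: they carry the patient ids they were
#' derived from.
#'
#' @param per_patient_means data.frame with columns `patient`, `mean_SUV`,
#'   `mean_D`, `mean_f` (one pre-treatment row per patient).
#' @return object of class `prm_thresholds` with `mu_SUV`, `mu_D`, `mu_f`
#'   and `provenance`.
#' @export
cohort_thresholds <- function(per_patient_means) {
  req <- c("patient", "mean_SUV", "mean_D", "mean_f")
  if (!all(req %in% names(per_patient_means)))
    stop("per-patient means must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(per_patient_means$patient))
    stop("duplicate patient ids in threshold derivation")
  if (nrow(per_patient_means) < 2)
    stop("population thresholds require at least two patients")
  vals <- per_patient_means[, c("mean_SUV", "mean_D", "mean_f")]
  if (any(!is.finite(as.matrix(vals))))
    stop("non-finite per-patient means")
  structure(list(mu_SUV = mean(vals$mean_SUV), mu_D = mean(vals$mean_D),
                 mu_f = mean(vals$mean_f),
                 provenance = as.character(per_patient_means$patient)),
            class = "prm_thresholds")
}

#' @export
print.prm_thresholds <- function(x, ...) {
  cat(sprintf(paste0("prm_thresholds (n = %d patients): mu_SUV %.3g, ",
                     "mu_D %.3g mm^2/s, mu_f %.3g\n"),
              length(x$provenance), x$mu_SUV, x$mu_D, x$mu_f))
  invisible(x)
}

#' PRM class codes and colors
#'
#' Label 1: A^hi B^hi (cyan); 2: A^hi B^lo (magenta); 3: A^lo B^lo (red);
#' 4: A^lo B^hi (green); 0: outside mask / missing.
#' @return named character vector of colors keyed by label.
#' @export
prm_palette <- function() c(`1` = "cyan", `2` = "magenta", `3` = "red",
                            `4` = "green")

#' Voxel-wise joint-histogram PRM classification
#'
#' Classifies every masked voxel of two co-registered maps against the
#' population-mean thresholds: "hi" means strictly above the threshold
#' (values equal to the threshold classify "lo" — a fixed convention,
#' measure-zero for continuous data). Voxels with a missing value in either
#' map receive label 0 and are counted.
#'
#' @param map_A,map_B co-registered 3D maps (A is the first-named metric of
#'   the pair, e.g. SUV in SUV x D).
#' @param mu_A,mu_B positive classification thresholds.
#' @param mask logical analysis mask (the pre-treatment GTV).
#' @param metric_pair tag, e.g. `"SUVxD"`, `"SUVxf"`, `"Dxf"`.
#' @return a `prm_label_map`: integer `labels` array (0 outside mask or
#'   missing), `metric_pair`, `palette`, `n_missing`.
#' @export
classify_prm <- function(map_A, map_B, mu_A, mu_B, mask,
                         metric_pair = "AxB") {
  if (!all(dim(map_A) == dim(map_B)) || !all(dim(map_A) == dim(mask)))
    stop("maps and mask must share one grid shape")
  if (!is.finite(mu_A) || !is.finite(mu_B) || mu_A <= 0 || mu_B <= 0)
    stop("thresholds must be finite and positive")
  labels <- array(0L, dim(mask))
  idx <- which(mask)
  a <- map_A[idx]; b <- map_B[idx]
  ok <- is.finite(a) & is.finite(b)
  hiA <- a[ok] > mu_A
  hiB <- b[ok] > mu_B
  lab <- ifelse(hiA, ifelse(hiB, 1L, 2L), ifelse(hiB, 4L, 3L))
  labels[idx[ok]] <- lab
  n_missing <- sum(!ok)
  if (n_missing > 0)
    message(n_missing, " masked voxel(s) missing in '", metric_pair,
            "' maps; labelled 0")
  structure(list(labels = labels, metric_pair = metric_pair,
                 palette = prm_palette(), n_missing = n_missing),
            class = "prm_label_map")
}

#' Relative PRM sub-volume percentages
#'
#' Normalizes the four class counts to the total labelled tumor volume,
#' producing relative volume percentages (counts times 100 divided by the
#' total, one division per class).
#'
#' @param labels a `prm_label_map`.
#' @return a `prm_fractions` object: named numeric `percent` (classes
#'   `hi_hi`, `hi_lo`, `lo_lo`, `lo_hi`), `counts`, `total_voxels`,
#'   `metric_pair`.
#' @export
prm_fractions <- function(labels) {
  counts <- vapply(1:4, function(k) sum(labels$labels == k), 0L)
  total <- sum(counts)
  if (total == 0) stop("label map has no classified voxels")
  percent <- counts * 100 / total
  names(percent) <- names(counts) <- c("hi_hi", "hi_lo", "lo_lo", "lo_hi")
  structure(list(percent = percent, counts = counts, total_voxels = total,
                 metric_pair = labels$metric_pair),
            class = "prm_fractions")
}

#' @export
print.prm_fractions <- function(x, ...) {
  cat(sprintf("prm_fractions [%s] over %d voxels:\n", x$metric_pair,
              x$total_voxels))
  print(round(x$percent, 2))
  invisible(x)
}
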