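#' Write a volume to NIfTI
#'
#' Writes 3D or 4D arrays as NIfTI-1 with the grid geometry (voxel size and
#' origin) in the header. Masks should be written with
#' `datatype = "uint8"`; intensity maps default to float32. `NA` values are
#' stored as-is (float) and round-trip as the missing code.
#'
#' @param volume numeric or logical array (3D, or 4D for DWI).
#' @param grid the [image_grid()] of the spatial dimensions.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype `"float"` or `"uint8"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, grid, path, datatype = "float") {
  if (is.logical(volume)) {
    volume <- array(as.integer(volume), dim(volume))
    datatype <- "uint8"
  }
  if (!all(dim(volume)[1:3] == grid$shape))
    stop("volume spatial shape does not match grid")
  img <- RNifti::asNifti(volume)
  pd <- RNifti::pixdim(img)
  pd[1:3] <- grid$voxel_size
  RNifti::pixdim(img) <- pd
  m <- diag(4)
  diag(m)[1:3] <- grid$voxel_size
  m[1:3, 4] <- grid$origin
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a NIfTI volume and its grid
#'
#' @param path NIfTI file path.
#' @return list with `data` (array, header stripped) and `grid`
#'   ([image_grid()] from the stored voxel size and origin).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  d <- dim(img)
  grid <- image_grid(d[1:3], abs(diag(xf)[1:3]), xf[1:3, 4])
  list(data = array(as.numeric(img), d), grid = grid)
}

#' Write / read the b-value sidecar of a 4D DWI volume
#'
#' JSON sidecar `{"bvalues": [...]}` stored next to the DWI NIfTI.
#'
#' @param bvalues numeric vector, s/mm^2.
#' @param path path of the sidecar JSON file.
#' @export
write_bvalue_sidecar <- function(bvalues, path) {
  jsonlite::write_json(list(bvalues = bvalues), path, digits = NA)
  invisible(path)
}

#' @rdname write_bvalue_sidecar
#' @export
read_bvalue_sidecar <- function(path) {
  as.numeric(jsonlite::read_json(path, simplifyVector = TRUE)$bvalues)
}

sidecar_path <- function(dwi_path) sub("\\.nii(\\.gz)?$", ".json", dwi_path)

#' Write / read a DWI series (4D NIfTI plus b-value sidecar)
#'
#' @param dwi a `dwi_series`.
#' @param path `.nii`/`.nii.gz` path; the sidecar is written alongside with
#'   extension `.json`.
#' @export
write_dwi <- function(dwi, path) {
  write_volume(dwi$data, dwi$grid, path)
  write_bvalue_sidecar(dwi$bvalues, sidecar_path(path))
  invisible(path)
}

#' @rdname write_dwi
#' @export
read_dwi <- function(path) {
  v <- read_volume(path)
  if (length(dim(v$data)) != 4L)
    stop("DWI volume must be 4D (x, y, z, b)")
  b <- read_bvalue_sidecar(sidecar_path(path))
  if (length(b) != dim(v$data)[4])
    stop("sidecar lists ", length(b), " b-values but the DWI has ",
         dim(v$data)[4], " frames")
  structure(list(data = v$data, bvalues = b, grid = v$grid, sigma = NA_real_),
            class = "dwi_series")
}

#' Write / read PRM thresholds with provenance
#'
#' Frozen cohort artifact: thresholds plus the patient ids they were
#' derived from, as TSV. Re-deriving thresholds is an explicit operation —
#' adding patients never silently shifts existing classifications.
#'
#' @param thr a `prm_thresholds`.
#' @param path TSV path.
#' @export
write_thresholds <- function(thr, path) {
  df <- data.frame(mu_SUV = thr$mu_SUV, mu_D = thr$mu_D, mu_f = thr$mu_f,
                   n_patients = length(thr$provenance),
                   provenance = paste(thr$provenance, collapse = ","))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  df <- utils::read.delim(path)
  structure(list(mu_SUV = df$mu_SUV, mu_D = df$mu_D, mu_f = df$mu_f,
                 provenance = strsplit(df$provenance, ",")[[1]]),
            class = "prm_thresholds")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a simulated cohort to disk
#'
#' Lays out one directory per patient with pre/on-treatment DWI (4D NIfTI +
#' b-value sidecar), GTV masks (uint8), the PET SUV volume, the true rigid
#' transform (4x4 text matrix) and the ground-truth parameter maps, plus a
#' cohort `manifest.tsv` and a ready-to-run pipeline `config.yaml`.
#'
#' @param cohort a `cohort_dataset` from [simulate_cohort()].
#' @param dir output directory (created).
#' @param compress write `.nii.gz` (default) or plain `.nii`.
#' @return the config file path, invisibly.
#' @export
write_cohort <- function(cohort, dir, compress = TRUE) {
  ext <- if (compress) ".nii.gz" else ".nii"
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  pat_cfg <- list()
  for (p in cohort$patients) {
    pd <- file.path(dir, p$patient_id)
    dir.create(pd, showWarnings = FALSE)
    f <- function(name) file.path(pd, paste0(name, ext))
    write_dwi(p$dwi_pre, f("dwi_pre"))
    write_dwi(p$dwi_on, f("dwi_on"))
    write_volume(p$truth_pre$gtv_mask, p$truth_pre$grid, f("gtv_pre"))
    write_volume(p$truth_on$gtv_mask, p$truth_on$grid, f("gtv_on"))
    write_volume(p$suv_pet, p$suv_grid, f("suv"))
    for (m in c("true_D", "true_f", "true_Dstar", "true_SUV"))
      write_volume(p$truth_pre[[m]], p$truth_pre$grid, f(m))
    write_transform(p$true_transform, file.path(pd, "true_transform.txt"))
    rows[[p$patient_id]] <- data.frame(
      patient_id = p$patient_id,
      dwi_pre = f("dwi_pre"), dwi_on = f("dwi_on"),
      gtv_pre = f("gtv_pre"), gtv_on = f("gtv_on"), suv = f("suv"),
      true_transform = file.path(pd, "true_transform.txt"),
      true_D = p$drawn$D, true_f = p$drawn$f, true_Dstar = p$drawn$Dstar,
      true_suv_mean = p$drawn$suv, true_gtv_cc = p$drawn$gtv_cc,
      true_volume_change = p$vcf)
    pat_cfg[[p$patient_id]] <- list(
      id = p$patient_id, dwi_pre = f("dwi_pre"), dwi_on = f("dwi_on"),
      gtv_pre = f("gtv_pre"), gtv_on = f("gtv_on"), suv = f("suv"))
  }
  write_tsv(do.call(rbind, rows), file.path(dir, "manifest.tsv"))
  cfg <- list(patients = unname(pat_cfg),
              fit_method = "bayesian",
              seed = cohort$params$seed,
              out_dir = file.path(dir, "results"))
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(file.path(dir, "config.yaml"))
}
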