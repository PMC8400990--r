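#' Construct a volume grid
#'
#' A `volume_grid` is the carrier for every volumetric input of the pipeline:
#' the (skull-stripped, MNI-registered) T1 scan, its binary brain mask, and
#' the integer atlas label image. It holds a 3D scalar array together with the
#' NIfTI-style 4x4 voxel-to-world affine (mm). Voxel indices are 0-based when
#' mapped through the affine; all downstream geometry is in world millimetres.
#'
#' @param data 3D numeric array of intensities (arbitrary units).
#' @param affine 4x4 voxel-to-world transform (mm). Defaults to identity,
#'   i.e. 1 mm isotropic voxels with the world origin at voxel (0,0,0).
#' @return An object of class `volume_grid` with elements `data`, `affine`
#'   and `spacing` (mm/voxel, derived from the affine columns).
#' @export
volume_grid <- function(data, affine = diag(4)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume must be 3D")
  if (any(dim(data) < 2L))
    stop("volume must have at least 2 voxels along every axis")
  if (!all(dim(as.matrix(affine)) == c(4L, 4L)))
    stop("affine must be a 4x4 matrix")
  affine <- matrix(as.numeric(affine), 4L, 4L)
  if (abs(det(affine)) < 1e-12)
    stop("affine is singular")
  spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(spacing <= 0)) stop("voxel spacings must be positive")
  structure(list(data = data, affine = affine, spacing = spacing),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("<volume_grid> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = "/"),
      " mm\n", sep = "")
  invisible(x)
}

#' Read a NIfTI-1 volume
#'
#' Thin wrapper over [RNifti::readNifti()]. Intensities are returned as
#' stored, up to the format's own scl slope/intercept scaling; no other
#' rescaling is applied.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [volume_grid()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) != 3L) {
    # tolerate trailing singleton dims (4D files with one frame)
    if (length(dm) > 3L && all(dm[-(1:3)] == 1L)) {
      img2 <- array(as.numeric(img), dim = dm[1:3])
      return(volume_grid(img2, affine = unclass(RNifti::xform(img))))
    }
    stop("volume must be 3D")
  }
  volume_grid(array(as.numeric(img), dim = dm),
              affine = unclass(RNifti::xform(img)))
}

#' Write a volume grid as NIfTI-1
#'
#' @param vol A [volume_grid()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume_grid"))
  img <- RNifti::asNifti(vol$data)
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Apply a brain mask to a scan
#'
#' Voxelwise masking: every voxel of `scan` where the mask is zero (or
#' negative) is set to 0, the background value used throughout the pipeline.
#' Grid metadata is preserved. Masking is idempotent.
#'
#' @param scan,mask [volume_grid()]s on the identical grid (same shape;
#'   affines equal within `tol` entrywise).
#' @param tol Tolerance on affine agreement (default 1e-4).
#' @return A [volume_grid()] with masked intensities.
#' @export
apply_brain_mask <- function(scan, mask, tol = 1e-4) {
  stopifnot(inherits(scan, "volume_grid"), inherits(mask, "volume_grid"))
  if (!identical(dim(scan$data), dim(mask$data)))
    stop("scan and mask shapes differ")
  if (max(abs(scan$affine - mask$affine)) > tol)
    stop("scan and mask affines differ beyond tolerance")
  out <- scan
  out$data <- scan$data * (mask$data > 0)
  out
}

#' Construct a label volume
#'
#' Pairs an integer atlas label array with a region dictionary. Label 0 is
#' reserved for background / non-cortex. Labels present in the image but
#' absent from the dictionary are demoted to background with a warning, so
#' third-party atlas dialects still load.
#'
#' @param labels 3D array of non-negative integers (integral floats accepted).
#' @param region_table data.frame with columns `label_id`, `region_name`.
#' @param affine 4x4 voxel-to-world transform.
#' @return An object of class `label_volume` with elements `labels`, `affine`,
#'   `spacing`, `region_table`.
#' @export
label_volume <- function(labels, region_table, affine = diag(4)) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("label volume must be 3D")
  if (max(abs(labels - round(labels))) > 1e-6)
    stop("labels must be integer-valued")
  labels <- array(as.integer(round(labels)), dim = dim(labels))
  if (any(labels < 0L)) stop("labels must be non-negative")
  if (is.null(region_table) || nrow(region_table) == 0L)
    stop("region table is empty")
  if (!all(c("label_id", "region_name") %in% names(region_table)))
    stop("region table needs columns label_id, region_name")
  region_table$label_id <- as.integer(region_table$label_id)
  present <- setdiff(unique(as.vector(labels)), 0L)
  unknown <- setdiff(present, region_table$label_id)
  if (length(unknown)) {
    warning("label ids absent from region table treated as background: ",
            paste(unknown, collapse = ", "))
    labels[labels %in% unknown] <- 0L
  }
  grid <- volume_grid(array(0, dim = dim(labels)), affine)
  structure(list(labels = labels, affine = grid$affine,
                 spacing = grid$spacing, region_table = region_table),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat("<label_volume> ", paste(dim(x$labels), collapse = " x "),
      " voxels, ", nrow(x$region_table), " regions\n", sep = "")
  invisible(x)
}

#' Load an atlas label image with its region dictionary
#'
#' @param path NIfTI label image (integer-valued).
#' @param region_table_path Two-column TSV (`label_id`, `region_name`);
#'   defaults to the packaged AAL cortical table.
#' @return A [label_volume()].
#' @seealso [aal_region_table()]
#' @export
load_atlas <- function(path,
                       region_table_path = system.file(
                         "extdata", "aal_cortical_regions.tsv",
                         package = "cortexcad")) {
  vol <- read_volume(path)
  tab <- utils::read.delim(region_table_path, sep = "\t",
                           stringsAsFactors = FALSE)
  label_volume(vol$data, tab, vol$affine)
}

#' The packaged AAL cortical region dictionary
#'
#' The 76 cortical regions of the AAL single-subject parcellation used for
#' region-wise analysis: the 90-region cerebrum scheme minus the
#' non-cortical structures (olfactory cortex and the subcortical nuclei:
#' hippocampus, amygdala, caudate, putamen, pallidum, thalamus; both
#' hemispheres). Standard AAL numeric codes are retained.
#'
#' @return data.frame with columns `label_id` (int) and `region_name`.
#' @export
aal_region_table <- function() {
  utils::read.delim(system.file("extdata", "aal_cortical_regions.tsv",
                                package = "cortexcad"),
                    sep = "\t", stringsAsFactors = FALSE)
}
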