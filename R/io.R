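#' Masked volume series container
#'
#' Holds a V x T matrix of within-mask voxel time series together with the
#' voxel coordinates, the 3D grid dimensions, an affine and the TR. Voxel
#' order is the fixed linearization of the mask: ascending x, then y, then z
#' (R's native column-major order over the 3D array), so two loads of the
#' same files always produce identical matrices.
#'
#' @param data V x T numeric matrix.
#' @param coords V x 3 integer matrix of (x, y, z) voxel indices (1-based).
#' @param dim3 length-3 integer grid dimensions.
#' @param tr_seconds repetition time in seconds.
#' @param affine 4 x 4 affine matrix (defaults to identity-like with the
#'   voxel size on the diagonal).
#' @return a `masked_series` object.
#' @export
masked_series <- function(data, coords, dim3, tr_seconds = 2,
                          affine = diag(4)) {
  data <- as.matrix(data)
  coords <- as.matrix(coords)
  stopifnot(nrow(data) == nrow(coords), ncol(coords) == 3L,
            length(dim3) == 3L, tr_seconds > 0)
  structure(list(data = data, coords = coords, dim3 = as.integer(dim3),
                 tr_seconds = tr_seconds, affine = affine),
            class = "masked_series")
}

#' @export
print.masked_series <- function(x, ...) {
  cat(sprintf("masked_series: %d voxels x %d TRs (grid %s, TR %gs)\n",
              nrow(x$data), ncol(x$data),
              paste(x$dim3, collapse = "x"), x$tr_seconds))
  invisible(x)
}

series_data <- function(x) {
  if (inherits(x, "masked_series")) x$data else as.matrix(x)
}

series_set_data <- function(x, data) {
  if (inherits(x, "masked_series")) { x$data <- data; x } else data
}

#' Load a masked 4D series from NIfTI files
#'
#' Reads a 4D volume and a 3D binary mask, checks shape compatibility, and
#' extracts the within-mask voxel time series in the fixed x-then-y-then-z
#' linearization. Constant (zero-variance) voxel time series cannot be
#' z-scored and are dropped from the mask with a warning.
#'
#' @param volume_path path to a 4D NIfTI-1 file.
#' @param mask_path path to a 3D NIfTI-1 mask (values 0/1).
#' @param tr_seconds override for the TR; by default read from the volume
#'   header (`pixdim[4]`).
#' @param drop_constant drop zero-variance voxels (default TRUE).
#' @return a [masked_series()].
#' @export
load_masked_series <- function(volume_path, mask_path, tr_seconds = NULL,
                               drop_constant = TRUE) {
  vol <- RNifti::readNifti(volume_path)
  msk <- RNifti::readNifti(mask_path)
  dv <- dim(vol); dm <- dim(msk)
  if (length(dv) != 4L) stop("volume must be 4D, got ", length(dv), "D")
  if (length(dm) != 3L) stop("mask must be 3D, got ", length(dm), "D")
  if (!all(dv[1:3] == dm)) {
    stop("volume grid ", paste(dv[1:3], collapse = "x"),
         " does not match mask grid ", paste(dm, collapse = "x"))
  }
  if (dv[4] < 3L) stop("need at least 3 timepoints, got ", dv[4])
  mv <- as.vector(msk)
  if (!all(mv %in% c(0, 1))) stop("mask must be binary (0/1)")
  if (!any(mv == 1)) stop("empty mask: no voxels selected")
  if (is.null(tr_seconds)) {
    pd <- RNifti::pixdim(vol)
    tr_seconds <- if (length(pd) >= 4L && pd[4] > 0) pd[4] else 2
  }
  idx <- which(array(mv, dim = dm) == 1, arr.ind = TRUE) # col-major: x fastest
  flat <- matrix(as.vector(vol), prod(dv[1:3]), dv[4])
  dat <- flat[which(mv == 1), , drop = FALSE]
  if (drop_constant) {
    sdv <- apply(dat, 1L, stats::sd)
    keep <- sdv > 0 & is.finite(sdv)
    if (!all(keep)) {
      warning(sum(!keep), " constant voxel time series excluded from mask")
      dat <- dat[keep, , drop = FALSE]
      idx <- idx[keep, , drop = FALSE]
    }
    if (nrow(dat) == 0L) stop("empty mask after excluding constant voxels")
  }
  masked_series(dat, idx, dm, tr_seconds)
}

#' Write a masked series as 4D NIfTI plus 3D mask
#'
#' Voxels outside the mask are written as 0. Data are stored as float32 on
#' disk (standard neuroimaging practice; the analysis is tercile-based and
#' insensitive to the precision loss).
#'
#' @param series a [masked_series()].
#' @param volume_path,mask_path output paths (`.nii` / `.nii.gz`).
#' @return invisibly, the two paths.
#' @export
write_masked_series <- function(series, volume_path, mask_path) {
  d3 <- series$dim3; T <- ncol(series$data)
  lin <- series$coords[, 1] + (series$coords[, 2] - 1L) * d3[1] +
    (series$coords[, 3] - 1L) * d3[1] * d3[2]
  arr <- array(0, dim = c(d3, T))
  flat <- matrix(0, prod(d3), T)
  flat[lin, ] <- series$data
  arr[] <- flat
  img <- RNifti::asNifti(arr)
  img <- RNifti::`pixdim<-`(img, c(1, 1, 1, series$tr_seconds))
  RNifti::writeNifti(img, volume_path, datatype = "float")
  mask <- array(0L, dim = d3)
  mask[lin] <- 1L
  RNifti::writeNifti(RNifti::asNifti(mask), mask_path, datatype = "uint8")
  invisible(c(volume_path, mask_path))
}

#' Write a voxel map (V-vector) as a 3D NIfTI image
#'
#' @param values V-vector aligned with `coords`.
#' @param coords V x 3 voxel indices.
#' @param dim3 grid dimensions.
#' @param path output path.
#' @export
write_voxel_map <- function(values, coords, dim3, path) {
  lin <- coords[, 1] + (coords[, 2] - 1L) * dim3[1] +
    (coords[, 3] - 1L) * dim3[1] * dim3[2]
  arr <- array(0, dim = dim3)
  arr[lin] <- values
  RNifti::writeNifti(RNifti::asNifti(arr), path, datatype = "float")
  invisible(path)
}

STATE_MODEL_SCHEMA <- 1L

#' Serialize / deserialize a fitted state model as JSON
#'
#' Round-trips the clustering artifact shared by the regime, participation
#' map, co-polarization and connectivity-state stages: centroids, per-subject
#' label sequences, occupancy matrix, k and seed.
#'
#' @param model a `state_model` (see [fit_dpr()]).
#' @param path output path.
#' @return `read_state_model` returns the reconstructed `state_model`.
#' @export
write_state_model <- function(model, path) {
  obj <- list(schema = STATE_MODEL_SCHEMA,
              k = model$k, seed = model$seed,
              centroids = model$centroids,
              labels = model$labels,
              occupancy = model$occupancy,
              inertia_curve = model$inertia_curve)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_state_model
#' @export
read_state_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema) || obj$schema != STATE_MODEL_SCHEMA) {
    stop("unsupported state model schema version: ",
         if (is.null(obj$schema)) "<missing>" else obj$schema)
  }
  structure(list(centroids = as.matrix(obj$centroids),
                 labels = lapply(obj$labels, as.integer),
                 occupancy = as.matrix(obj$occupancy),
                 k = as.integer(obj$k),
                 seed = as.integer(obj$seed),
                 inertia_curve = obj$inertia_curve),
            class = "state_model")
}
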