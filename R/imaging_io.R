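#' Read a 3D NIfTI-1 volume as a parametric map
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param space,kind passed to [parametric_map()].
#' @return A [parametric_map()] carrying the file's voxel size and affine.
#' @export
load_volume <- function(path, space = "native", kind = NULL) {
  if (!file.exists(path)) stop("no such volume file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- array(as.array(img)[, , , 1], d[1:3])
    d <- d[1:3]
  } else if (length(d) != 3L) {
    stop("expected a 3D volume but '", path, "' has ", length(d),
         " dimensions; use load_dynamic_volume() for 4D data")
  }
  vox <- RNifti::pixdim(img)[1:3]
  aff <- unclass(RNifti::xform(img))[1:4, 1:4]
  parametric_map(array(as.vector(img), d), voxel_size = vox, affine = aff,
                 space = space, kind = kind)
}

#' Write a parametric map as NIfTI-1
#'
#' Round-trip through [load_volume()] reproduces values bit-exactly and the
#' affine to single float precision.
#'
#' @param map a [parametric_map()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
save_volume <- function(map, path) {
  img <- RNifti::asNifti(map$values)
  RNifti::pixdim(img) <- map$voxel_size
  RNifti::sform(img) <- structure(map$affine, code = 2L)
  RNifti::qform(img) <- structure(map$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a dynamic (4D) NIfTI-1 volume
#'
#' @param path path to a 4D NIfTI file.
#' @return A list with `values` (4D array, frames last), `voxel_size`,
#'   `affine` and `n_frames`.
#' @export
load_dynamic_volume <- function(path) {
  if (!file.exists(path)) stop("no such volume file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop("expected a 4D dynamic volume but '", path, "' has ",
         length(d), " dimensions")
  list(values = as.array(img), voxel_size = RNifti::pixdim(img)[1:3],
       affine = unclass(RNifti::xform(img))[1:4, 1:4], n_frames = d[4])
}

gaussian_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

convolve_axis <- function(arr, kernel, axis) {
  if (length(kernel) == 1L) return(arr)
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  n <- d[axis]
  m <- matrix(a, nrow = n)
  r <- (length(kernel) - 1L) / 2L
  pad <- matrix(0, nrow = n + 2L * r, ncol = ncol(m))
  pad[(r + 1L):(r + n), ] <- m
  out <- matrix(0, nrow = n, ncol = ncol(m))
  for (j in seq_along(kernel))
    out <- out + kernel[j] * pad[j:(j + n - 1L), , drop = FALSE]
  aperm(array(out, d[perm]), order(perm))
}

#' Gaussian smoothing of a parametric map
#'
#' Separable Gaussian convolution with per-axis standard deviation
#' `sigma = fwhm_mm / (voxel_size * sqrt(8 * log(2)))` voxels, so the kernel
#' has the requested full width at half maximum in mm regardless of
#' (possibly anisotropic) voxel size. Boundaries are zero-padded.
#'
#' @param map a [parametric_map()].
#' @param fwhm_mm kernel full width at half maximum in mm; 0 is the identity.
#' @return The smoothed [parametric_map()].
#' @export
smooth_gaussian <- function(map, fwhm_mm) {
  if (!inherits(map, "parametric_map")) stop("map must be a parametric_map")
  if (length(fwhm_mm) != 1L || !is.finite(fwhm_mm) || fwhm_mm < 0)
    stop("fwhm_mm must be a single non-negative number")
  if (fwhm_mm == 0) return(map)
  sigma_vox <- fwhm_mm / (map$voxel_size * sqrt(8 * log(2)))
  out <- map$values
  for (ax in 1:3)
    out <- convolve_axis(out, gaussian_kernel_1d(sigma_vox[ax]), ax)
  map$values <- out
  map
}

#' Assemble a subjects x voxels data matrix from parametric maps
#'
#' Stacks each subject's masked voxel values into one row of the imaging
#' block entering PLS. Voxel columns follow a fixed raster order (x fastest,
#' then y, then z) so runs are reproducible. The analysis mask is the
#' intersection of the supplied mask and the voxels finite in every subject;
#' dropped voxel counts are recorded in `n_dropped_nonfinite`.
#'
#' @param maps list of [parametric_map()]s, one per subject, sharing
#'   dimensions and affine with `mask`.
#' @param mask a [parametric_map()] whose values are interpreted as logical
#'   (non-zero = inside).
#' @param subject_ids optional character vector of subject labels.
#' @return An object of class `datamat`: `matrix` (n x v), `voxel_index`
#'   (1-based column-major linear indices of the mask voxels), plus the
#'   grid geometry needed by [datamat_to_map()].
#' @export
build_datamat <- function(maps, mask, subject_ids = NULL) {
  if (!length(maps)) stop("need at least one subject map")
  if (!inherits(mask, "parametric_map")) stop("mask must be a parametric_map")
  dm <- dim(mask$values)
  for (s in seq_along(maps)) {
    if (!inherits(maps[[s]], "parametric_map"))
      stop("maps must be parametric_map objects")
    if (!all(dim(maps[[s]]$values) == dm))
      stop("map ", s, " dimensions do not match the mask")
    if (max(abs(maps[[s]]$affine - mask$affine)) > 1e-6)
      stop("map ", s, " affine does not match the mask")
  }
  inside <- which(mask$values != 0 & !is.na(mask$values))
  if (!length(inside)) stop("mask is empty")
  X <- vapply(maps, function(m) as.numeric(m$values[inside]),
              numeric(length(inside)))
  X <- t(X)
  finite_cols <- colSums(!is.finite(X)) == 0L
  n_dropped <- sum(!finite_cols)
  if (n_dropped == length(inside))
    stop("all mask voxels are non-finite in at least one subject")
  X <- X[, finite_cols, drop = FALSE]
  inside <- inside[finite_cols]
  if (is.null(subject_ids)) subject_ids <- sprintf("S%03d", seq_along(maps))
  structure(list(matrix = X, voxel_index = inside, dims = dm,
                 voxel_size = mask$voxel_size, affine = mask$affine,
                 space = mask$space, subject_ids = subject_ids,
                 n_dropped_nonfinite = n_dropped),
            class = "datamat")
}

#' @export
dim.datamat <- function(x) dim(x$matrix)

#' @export
print.datamat <- function(x, ...) {
  cat(sprintf("<datamat> %d subjects x %d voxels (grid %s)\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(x$dims, collapse = "x")))
  invisible(x)
}

#' Map a per-voxel column vector back into a volume
#'
#' Inverse of the flattening performed by [build_datamat()]: values are
#' written at the datamat's mask voxels, zeros (or `fill`) elsewhere.
#'
#' @param datamat a `datamat` from [build_datamat()].
#' @param values numeric vector, one value per datamat column.
#' @param kind value kind tag for the resulting map.
#' @param fill value for off-mask voxels (default 0).
#' @return A [parametric_map()].
#' @export
datamat_to_map <- function(datamat, values, kind = NULL, fill = 0) {
  if (length(values) != ncol(datamat$matrix))
    stop("values length must equal the number of datamat columns")
  arr <- array(fill, datamat$dims)
  arr[datamat$voxel_index] <- values
  parametric_map(arr, voxel_size = datamat$voxel_size,
                 affine = datamat$affine, space = datamat$space, kind = kind)
}

#' Threshold a grey-matter probability map into an analysis mask
#'
#' @param gm_map a [parametric_map()] of grey-matter probabilities.
#' @param threshold absolute threshold; voxels with value > threshold are
#'   kept (default 0.2).
#' @return A binary [parametric_map()].
#' @export
gm_mask <- function(gm_map, threshold = 0.2) {
  m <- gm_map
  m$values <- array(as.numeric(gm_map$values > threshold), dim(gm_map$values))
  m$kind <- "mask"
  m
}

#' Read a behaviour table from CSV
#'
#' The behaviour block: one row per subject, a `subject_id` column plus
#' numeric behavioural variables (demographics and cognitive scores). The
#' table must be complete and every variable must vary across subjects.
#'
#' @param path CSV file with a header row and a `subject_id` column.
#' @param required optional character vector of column names that must be
#'   present.
#' @return A data.frame with `subject_id` first.
#' @export
read_behaviour_table <- function(path, required = NULL) {
  if (!file.exists(path)) stop("no such behaviour table: ", path)
  tab <- utils::read.csv(path, check.names = FALSE)
  if (!"subject_id" %in% names(tab))
    stop("behaviour table must contain a 'subject_id' column")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("behaviour table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  validate_behaviour_table(tab)
  tab[, c("subject_id", setdiff(names(tab), "subject_id"))]
}

validate_behaviour_table <- function(tab) {
  vars <- setdiff(names(tab), c("subject_id", "group"))
  for (v in vars) {
    col <- tab[[v]]
    if (!is.numeric(col)) stop("behaviour column '", v, "' is not numeric")
    if (anyNA(col)) stop("behaviour column '", v, "' has missing values")
  }
  invisible(tab)
}

behaviour_matrix <- function(behaviour) {
  if (is.matrix(behaviour)) return(behaviour)
  vars <- setdiff(names(behaviour), c("subject_id", "group"))
  as.matrix(behaviour[, vars, drop = FALSE])
}
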