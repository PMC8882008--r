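#' Parametric 3D map
#'
#' A `parametric_map` is a 3D voxel grid plus the geometry needed to report
#' voxel locations in millimetres: voxel size, a 4x4 affine mapping 0-based
#' voxel indices (i, j, k) to mm, and a space tag (`native`, `MNI` or
#' `Talairach`). It houses DVR images, grey-matter probability maps, BSR
#' maps, correlation maps and t maps alike; `kind` records which.
#'
#' @param values 3D numeric array.
#' @param voxel_size numeric length 3, voxel edge lengths in mm.
#' @param affine 4x4 matrix mapping 0-based voxel indices to mm; defaults to
#'   a diagonal scaling by `voxel_size` with the origin at voxel (0,0,0).
#' @param space one of `"native"`, `"MNI"`, `"Talairach"`.
#' @param kind optional value kind, e.g. `"DVR"`, `"GM_probability"`,
#'   `"BSR"`, `"correlation"`, `"t"`.
#' @return An object of class `parametric_map`.
#' @export
parametric_map <- function(values, voxel_size = c(1, 1, 1), affine = NULL,
                           space = c("native", "MNI", "Talairach"),
                           kind = NULL) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("parametric_map requires a 3D array, got ",
         length(dim(values)), "D")
  if (any(dim(values) < 1L)) stop("grid dimensions must be positive")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be 3 positive values (mm)")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be a 4x4 matrix")
  if (abs(det(affine)) < .Machine$double.eps)
    stop("affine must be invertible")
  space <- match.arg(space)
  structure(list(values = values, voxel_size = voxel_size, affine = affine,
                 space = space, kind = kind),
            class = "parametric_map")
}

#' @export
dim.parametric_map <- function(x) dim(x$values)

#' @export
print.parametric_map <- function(x, ...) {
  cat(sprintf("<parametric_map%s> %s voxels @ %s mm, space %s\n",
              if (is.null(x$kind)) "" else paste0(" ", x$kind),
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$voxel_size, 3), collapse = "x"), x$space))
  invisible(x)
}

#' Convert 0-based voxel indices to mm coordinates
#'
#' @param map a [parametric_map()].
#' @param ijk integer vector of length 3 or an n x 3 matrix of 0-based
#'   voxel indices.
#' @return mm coordinates, same shape as the input (vector or n x 3 matrix).
#' @export
voxel_to_mm <- function(map, ijk) {
  one <- is.null(dim(ijk))
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  mm <- cbind(ijk, 1) %*% t(map$affine)
  mm <- mm[, 1:3, drop = FALSE]
  if (one) drop(mm) else mm
}

linear_to_ijk <- function(idx, dims) {
  # 0-based (i, j, k) from 1-based column-major linear index; x fastest
  idx0 <- idx - 1L
  i <- idx0 %% dims[1]
  j <- (idx0 %/% dims[1]) %% dims[2]
  k <- idx0 %/% (dims[1] * dims[2])
  cbind(i, j, k)
}
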