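neighbour_offsets <- function(connectivity = 26) {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  switch(as.character(connectivity),
         "6"  = g[rowSums(abs(g)) == 1, , drop = FALSE],
         "18" = g[rowSums(abs(g)) <= 2, , drop = FALSE],
         "26" = g,
         stop("connectivity must be 6, 18 or 26"))
}

# queue-based flood fill over the TRUE voxels of a logical 3D array;
# returns an integer label array (0 = background)
label_components <- function(mask, connectivity = 26) {
  dims <- dim(mask)
  offs <- neighbour_offsets(connectivity)
  labels <- array(0L, dims)
  idx_all <- which(mask)
  lab <- 0L
  for (start in idx_all) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    queue <- start
    labels[start] <- lab
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ijk <- linear_to_ijk(cur, dims)  # 0-based
      ni <- sweep(offs, 2, as.numeric(ijk), "+")
      ok <- ni[, 1] >= 0 & ni[, 1] < dims[1] &
        ni[, 2] >= 0 & ni[, 2] < dims[2] &
        ni[, 3] >= 0 & ni[, 3] < dims[3]
      ni <- ni[ok, , drop = FALSE]
      lin <- 1L + ni[, 1] + dims[1] * ni[, 2] + dims[1] * dims[2] * ni[, 3]
      lin <- lin[mask[lin] & labels[lin] == 0L]
      if (length(lin)) {
        labels[lin] <- lab
        queue <- c(queue, lin)
      }
    }
  }
  labels
}

#' Extract supra-threshold clusters from a statistic map
#'
#' Supra-threshold voxels (`|value| >= threshold` when `two_sided`,
#' `value >= threshold` otherwise; `NaN`/`NA` treated as sub-threshold) are
#' grouped into connected components (26-neighbour connectivity by
#' default); positive and negative components are never merged. Clusters
#' with at least `min_size` voxels are returned sorted by absolute peak
#' value, largest first. The peak is the maximum-|value| voxel, ties broken
#' by raster order. Peak coordinates are reported as 0-based voxel indices,
#' in mm via the map's affine and — when the map is in MNI space — in
#' Talairach mm via [mni_to_talairach()].
#'
#' @param map a [parametric_map()].
#' @param threshold non-negative when `two_sided`.
#' @param min_size minimum cluster extent in voxels (inclusive; default 50).
#' @param two_sided threshold on |value| (default `TRUE`).
#' @param connectivity 6, 18 or 26 (default 26).
#' @param transform MNI-to-Talairach affine for peak reporting (default
#'   [mni_talairach_transform()]).
#' @return A list of `cluster` objects: `voxel_count`, `peak_value`,
#'   `peak_ijk` (0-based), `peak_mm`, `peak_talairach_mm` (MNI-space maps
#'   only), `sign` and `voxels` (1-based linear indices).
#' @export
extract_clusters <- function(map, threshold, min_size = 50,
                             two_sided = TRUE, connectivity = 26,
                             transform = mni_talairach_transform()) {
  if (!inherits(map, "parametric_map")) stop("map must be a parametric_map")
  if (two_sided && threshold < 0)
    stop("threshold must be non-negative for two-sided extraction")
  vals <- map$values
  finite <- is.finite(vals)
  clusters <- list()
  signs <- if (two_sided) c(1, -1) else 1
  for (sgn in signs) {
    supra <- array(FALSE, dim(vals))
    supra[finite] <- (sgn * vals[finite]) >= threshold
    if (two_sided && threshold == 0)  # keep signed components disjoint
      supra[finite] <- supra[finite] & (sgn * vals[finite] > 0 |
                                          (sgn > 0 & vals[finite] == 0))
    if (!any(supra)) next
    labels <- label_components(supra, connectivity)
    for (lab in seq_len(max(labels))) {
      vox <- which(labels == lab)
      if (length(vox) < min_size) next
      av <- abs(vals[vox])
      peak <- vox[which.max(av)]  # which.max takes the first = raster order
      cl <- list(voxel_count = length(vox), peak_value = vals[peak],
                 peak_ijk = drop(linear_to_ijk(peak, dim(vals))),
                 peak_mm = drop(voxel_to_mm(map,
                                            linear_to_ijk(peak, dim(vals)))),
                 sign = sgn, voxels = vox)
      if (identical(map$space, "MNI"))
        cl$peak_talairach_mm <- mni_to_talairach(cl$peak_mm, transform)
      clusters[[length(clusters) + 1L]] <- structure(cl, class = "cluster")
    }
  }
  ord <- order(vapply(clusters, function(cl) abs(cl$peak_value),
                      numeric(1)), decreasing = TRUE)
  clusters[ord]
}

#' @export
print.cluster <- function(x, ...) {
  cat(sprintf("<cluster> %d voxels, peak %.3f at (%s) mm\n",
              x$voxel_count, x$peak_value,
              paste(round(x$peak_mm, 1), collapse = ", ")))
  invisible(x)
}

#' MNI to Talairach affine transform
#'
#' The default is the Lancaster pooled affine for SPM-normalised images
#' (`icbm_spm2tal`); an identity option is provided. The matrix maps MNI mm
#' coordinates to Talairach mm coordinates.
#'
#' @param name `"lancaster"` (default) or `"identity"`.
#' @return A 4x4 affine matrix.
#' @export
mni_talairach_transform <- function(name = c("lancaster", "identity")) {
  name <- match.arg(name)
  if (name == "identity") return(diag(4))
  matrix(c(0.9254,  0.0024, -0.0118, -1.0207,
           -0.0048, 0.9316, -0.0871, -1.7667,
           0.0152,  0.0883,  0.8924,  4.0926,
           0, 0, 0, 1), 4, 4, byrow = TRUE)
}

#' Map coordinates between MNI and Talairach space
#'
#' Applies an affine to mm coordinates. Coordinates are kept at full
#' precision; rounding to the nearest mm happens only at report time in
#' [make_cluster_table()]. `talairach_to_mni()` applies the inverse.
#'
#' @param xyz_mm length-3 vector or n x 3 matrix of mm coordinates.
#' @param transform a 4x4 invertible affine (default
#'   [mni_talairach_transform()]).
#' @return Transformed coordinates, same shape as the input.
#' @export
mni_to_talairach <- function(xyz_mm, transform = mni_talairach_transform()) {
  transform <- as.matrix(transform)
  if (abs(det(transform)) < .Machine$double.eps)
    stop("transform matrix is singular")
  one <- is.null(dim(xyz_mm))
  xyz <- matrix(as.numeric(xyz_mm), ncol = 3)
  out <- cbind(xyz, 1) %*% t(transform)
  out <- out[, 1:3, drop = FALSE]
  if (one) drop(out) else out
}

#' @rdname mni_to_talairach
#' @export
talairach_to_mni <- function(xyz_mm, transform = mni_talairach_transform()) {
  mni_to_talairach(xyz_mm, solve(transform))
}

#' Tabulate clusters in report form
#'
#' One row per cluster: extent, peak statistic, peak MNI and Talairach
#' coordinates rounded to the nearest mm, optional anatomical label, and —
#' when per-behaviour correlation maps are supplied — the correlation value
#' sampled at each cluster's peak voxel. An empty cluster list yields an
#' empty but fully headered table.
#'
#' @param clusters list of clusters from [extract_clusters()].
#' @param map_kind statistic name for the peak column (e.g. `"BSR"`,
#'   `"R"`, `"t"`).
#' @param correlation_maps optional named list of [parametric_map()]s; each
#'   contributes a column `R_<name>` with its value at the cluster peaks.
#' @param labels optional character vector of anatomical labels.
#' @return A data.frame ready for CSV export.
#' @export
make_cluster_table <- function(clusters, map_kind = "BSR",
                               correlation_maps = NULL, labels = NULL) {
  base_cols <- data.frame(cluster = integer(), n_voxels = integer(),
                          peak = numeric(),
                          peak_i = integer(), peak_j = integer(),
                          peak_k = integer(),
                          mni_x = numeric(), mni_y = numeric(),
                          mni_z = numeric(),
                          tal_x = numeric(), tal_y = numeric(),
                          tal_z = numeric(), label = character())
  names(base_cols)[names(base_cols) == "peak"] <- paste0("peak_", map_kind)
  if (!length(clusters)) {
    for (nm in names(correlation_maps))
      base_cols[[paste0("R_", nm)]] <- numeric()
    return(base_cols)
  }
  rows <- lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    tal <- cl$peak_talairach_mm %||% rep(NA_real_, 3)
    row <- data.frame(cluster = i, n_voxels = cl$voxel_count,
                      peak = cl$peak_value,
                      peak_i = cl$peak_ijk[1], peak_j = cl$peak_ijk[2],
                      peak_k = cl$peak_ijk[3],
                      mni_x = round(cl$peak_mm[1]),
                      mni_y = round(cl$peak_mm[2]),
                      mni_z = round(cl$peak_mm[3]),
                      tal_x = round(tal[1]), tal_y = round(tal[2]),
                      tal_z = round(tal[3]),
                      label = if (is.null(labels)) NA_character_
                              else labels[i])
    names(row)[names(row) == "peak"] <- paste0("peak_", map_kind)
    for (nm in names(correlation_maps)) {
      m <- correlation_maps[[nm]]
      lin <- 1L + cl$peak_ijk[1] + dim(m$values)[1] * cl$peak_ijk[2] +
        dim(m$values)[1] * dim(m$values)[2] * cl$peak_ijk[3]
      row[[paste0("R_", nm)]] <- m$values[lin]
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
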