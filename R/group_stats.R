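new_group_stats <- function(kind, value, df, p, extra = list()) {
  structure(c(list(kind = kind, value = value, df = df, p = p), extra),
            class = "group_stats")
}

#' @export
print.group_stats <- function(x, ...) {
  cat(sprintf("<group_stats> %s = %.4g, df = (%s), p = %.4g\n", x$kind,
              x$value, paste(x$df, collapse = ", "), x$p))
  invisible(x)
}

#' Two-group one-way ANOVA
#'
#' Pooled-variance one-way ANOVA for two groups; F equals the square of the
#' pooled two-sample t statistic, with df (1, n1 + n2 - 2).
#' `anova_from_summary()` is the algebraically identical form computed from
#' printed means, SDs and group sizes, so rows of a published cohort table
#' can be re-tested directly.
#'
#' @param a,b numeric score vectors for the two groups (n >= 2 each).
#' @return A `group_stats` with `kind = "F"`, the F value, df and p.
#' @export
anova_two_group <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) stop("need at least 2 per group")
  anova_from_summary(mean(a), stats::sd(a), length(a),
                     mean(b), stats::sd(b), length(b))
}

#' @rdname anova_two_group
#' @param m1,sd1,n1,m2,sd2,n2 per-group mean, SD (> 0) and size (>= 2).
#' @export
anova_from_summary <- function(m1, sd1, n1, m2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("need at least 2 per group")
  if (sd1 <= 0 || sd2 <= 0) stop("group SDs must be positive")
  df2 <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df2
  f <- (m1 - m2)^2 / (sp2 * (1 / n1 + 1 / n2))
  new_group_stats("F", f, c(1, df2), stats::pf(f, 1, df2, lower.tail = FALSE))
}

#' Pearson chi-square test for a 2x2 contingency table
#'
#' @param table 2x2 matrix of non-negative counts with positive marginals.
#' @param correction apply the Yates continuity correction
#'   (default `FALSE`).
#' @return A `group_stats` with `kind = "chi2"`, df = 1.
#' @export
chi_square_2x2 <- function(table, correction = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("table must be 2x2")
  if (any(table < 0)) stop("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("all row and column marginals must be positive")
  ht <- suppressWarnings(stats::chisq.test(table, correct = correction))
  new_group_stats("chi2", unname(ht$statistic), unname(ht$parameter),
                  unname(ht$p.value))
}

#' Simple (ordinary least squares) regression
#'
#' Slope, intercept, Pearson R and the two-sided p-value from the t
#' distribution with n - 2 df. A constant response is handled by
#' convention (slope 0, R 0, p 1), not as an error.
#'
#' @param x predictor (non-constant, n >= 3).
#' @param y response.
#' @return A `group_stats` with `kind = "slope"` and extra elements
#'   `intercept` and `r`.
#' @export
simple_regression <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0) stop("x is constant")
  n <- length(x)
  if (stats::sd(y) == 0)
    return(new_group_stats("slope", 0, c(1, n - 2), 1,
                           list(intercept = mean(y), r = 0)))
  fit <- stats::lm(y ~ x)
  # summary.lm warns on perfect fits, which are fine here
  co <- suppressWarnings(summary(fit))$coefficients
  r <- stats::cor(x, y)
  new_group_stats("slope", unname(co["x", "Estimate"]), c(1, n - 2),
                  unname(co["x", "Pr(>|t|)"]),
                  list(intercept = unname(co["(Intercept)", "Estimate"]),
                       r = r))
}

#' Voxel-wise two-sample t map with extent thresholding
#'
#' Pooled two-sample t statistic at every voxel of a common mask, kept
#' where the uncorrected one-sided p is at or below `height_p` (each
#' direction separately, so the thresholded map is signed), then grouped
#' into clusters of at least `extent_k` voxels via [extract_clusters()].
#' This is the simplified uncorrected-threshold + extent analysis; no
#' random-field family-wise correction is applied.
#'
#' @param maps_a,maps_b lists of [parametric_map()]s for the two groups
#'   (>= 2 each).
#' @param mask binary [parametric_map()] shared by both groups.
#' @param height_p one-sided voxel height threshold (default 1e-4).
#' @param extent_k cluster extent threshold in voxels (default 50).
#' @param connectivity passed to [extract_clusters()].
#' @return A list with `t_map` (full t values as a [parametric_map()]),
#'   `thresholded` (t values, sub-threshold voxels zeroed), `clusters`,
#'   `t_critical` and `df`.
#' @export
voxelwise_ttest <- function(maps_a, maps_b, mask, height_p = 1e-4,
                            extent_k = 50, connectivity = 26) {
  if (length(maps_a) < 2 || length(maps_b) < 2)
    stop("need at least 2 maps per group")
  da <- build_datamat(maps_a, mask)
  db <- build_datamat(maps_b, mask)
  if (!identical(da$voxel_index, db$voxel_index))
    stop("groups resolve to different analysis masks")
  na <- nrow(da$matrix)
  nb <- nrow(db$matrix)
  df <- na + nb - 2
  ma <- colMeans(da$matrix)
  mb <- colMeans(db$matrix)
  va <- col_sds(da$matrix)^2
  vb <- col_sds(db$matrix)^2
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
  tval <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
  tval[sp2 == 0] <- NaN
  t_crit <- stats::qt(1 - height_p, df)
  thr <- ifelse(is.finite(tval) & abs(tval) >= t_crit, tval, 0)
  t_map <- datamat_to_map(da, tval, kind = "t")
  thr_map <- datamat_to_map(da, thr, kind = "t")
  clusters <- extract_clusters(thr_map, threshold = t_crit,
                               min_size = extent_k, two_sided = TRUE,
                               connectivity = connectivity)
  list(t_map = t_map, thresholded = thr_map, clusters = clusters,
       t_critical = t_crit, df = df)
}
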