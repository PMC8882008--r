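#' Cumulative integral of a time-activity curve
#'
#' Trapezoidal cumulative integral of frame activities evaluated at frame
#' mid-times, anchored at (t = 0, activity = 0). Units: activity x minutes.
#'
#' @param x a [tac()].
#' @return Numeric vector, one cumulative integral per frame.
#' @export
integrate_tac <- function(x) {
  if (!inherits(x, "tac")) stop("x must be a tac")
  if (length(x) == 0L) stop("empty time-activity curve")
  t <- c(0, x$schedule$mid_min)
  a <- c(0, x$activity)
  cumsum(diff(t) * (a[-length(a)] + a[-1]) / 2)
}

cumtrapz_weights <- function(mid_min) {
  # W such that (V %*% t(W))[, k] is the trapezoid integral of each row of V
  # at frame k, anchored at (0, 0); used to vectorise per-voxel integrals.
  n <- length(mid_min)
  dt <- diff(c(0, mid_min))
  W <- matrix(0, n, n)
  for (k in seq_len(n)) {
    w <- numeric(n)
    w[seq_len(k)] <- w[seq_len(k)] + dt[seq_len(k)] / 2           # right ends
    if (k > 1) w[seq_len(k - 1)] <- w[seq_len(k - 1)] + dt[2:k] / 2 # left ends
    W[k, ] <- w
  }
  W
}

new_kinetic_fit <- function(coefficients, k2prime, dvr, condition_number,
                            model) {
  structure(list(coefficients = coefficients, k2prime = k2prime, DVR = dvr,
                 condition_number = condition_number, model = model),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit %s> DVR = %.4f, k2' = %s /min (cond %.3g)\n",
              x$model, x$DVR,
              if (is.na(x$k2prime)) "fixed" else sprintf("%.4f", x$k2prime),
              x$condition_number))
  invisible(x)
}

mrtm_design_fit <- function(X, y, model) {
  d <- svd(X, nu = 0, nv = 0)$d
  cn <- if (d[length(d)] > 0) d[1] / d[length(d)] else Inf
  if (!is.finite(cn) || cn > 1e10)
    stop("degenerate ", model, " fit: design condition number ",
         format(cn, digits = 3), " exceeds 1e10")
  list(beta = unname(qr.solve(X, y)), condition_number = cn)
}

#' Multilinear reference tissue model (three-parameter MRTM)
#'
#' Least-squares fit, over frames with mid-time at or after `t_star`, of
#' \deqn{C_T(T) = b_1 \int_0^T C_R + b_2 \int_0^T C_T + b_3 C_R(T)}
#' yielding the reference-region clearance `k2prime = b1 / b3` and
#' `DVR = -b1 / b2`. This is the first-pass fit used on a high-binding
#' region to supply `k2prime` for the voxel-wise two-parameter fit
#' ([fit_mrtm2()]). The sign conventions are those under which the fit is
#' exact for curves generated by the simplified reference tissue model.
#'
#' @param target,ref target and reference [tac()]s on the same schedule.
#' @param t_star start of the multilinear phase, minutes (default 20).
#' @return A `kinetic_fit` with `k2prime` (1/min), `DVR`, the regression
#'   coefficients and the design condition number.
#' @export
fit_mrtm <- function(target, ref, t_star = 20) {
  if (!inherits(target, "tac") || !inherits(ref, "tac"))
    stop("target and ref must be tac objects")
  stopifnot_same_schedule(target, ref)
  keep <- target$schedule$mid_min >= t_star
  if (sum(keep) < 4L)
    stop("need at least 4 frames at or after t_star = ", t_star, " min")
  int_r <- integrate_tac(ref)[keep]
  int_t <- integrate_tac(target)[keep]
  X <- cbind(int_ref = int_r, int_target = int_t, ref = ref$activity[keep])
  fit <- mrtm_design_fit(X, target$activity[keep], "MRTM")
  beta <- fit$beta
  new_kinetic_fit(beta, k2prime = beta[1] / beta[3], dvr = -beta[1] / beta[2],
                  condition_number = fit$condition_number, model = "MRTM")
}

#' Two-parameter multilinear reference tissue model (MRTM2)
#'
#' With the reference clearance `k2prime` fixed (typically from
#' [fit_mrtm()] on a high-binding region), fits over frames at or after
#' `t_star`
#' \deqn{C_T(T) = b_1 [\int_0^T C_R + C_R(T)/k_2'] + b_2 \int_0^T C_T}
#' and reports `DVR = -b1 / b2`. This is the per-voxel model producing DVR
#' parametric images with cerebellar grey matter as reference.
#'
#' @param target,ref target and reference [tac()]s on the same schedule.
#' @param k2prime reference-region clearance, 1/min; must be positive.
#' @param t_star start of the multilinear phase, minutes (default 20).
#' @return A `kinetic_fit`.
#' @export
fit_mrtm2 <- function(target, ref, k2prime, t_star = 20) {
  if (!inherits(target, "tac") || !inherits(ref, "tac"))
    stop("target and ref must be tac objects")
  stopifnot_same_schedule(target, ref)
  if (length(k2prime) != 1L || !is.finite(k2prime) || k2prime <= 0)
    stop("k2prime must be a single positive rate (1/min)")
  keep <- target$schedule$mid_min >= t_star
  if (sum(keep) < 3L)
    stop("need at least 3 frames at or after t_star = ", t_star, " min")
  w <- integrate_tac(ref)[keep] + ref$activity[keep] / k2prime
  X <- cbind(ref_comb = w, int_target = integrate_tac(target)[keep])
  fit <- mrtm_design_fit(X, target$activity[keep], "MRTM2")
  beta <- fit$beta
  new_kinetic_fit(beta, k2prime = NA_real_, dvr = -beta[1] / beta[2],
                  condition_number = fit$condition_number, model = "MRTM2")
}

#' Voxel-wise DVR parametric map from a dynamic PET image
#'
#' Computes the reference time-activity curve as the frame-wise mean over
#' `ref_mask` (cerebellar grey matter in practice), estimates `k2prime` by
#' [fit_mrtm()] on the mean curve of `highbind_mask`, then fits [fit_mrtm2()]
#' at every voxel inside `fit_mask` (the whole grid by default) via closed
#' form 2x2 normal equations. Voxels with degenerate fits are set to `NaN`
#' and counted.
#'
#' @param dynamic 4D array (x, y, z, frame) or the list returned by
#'   [load_dynamic_volume()].
#' @param ref_mask,highbind_mask [parametric_map()]s (non-zero = inside).
#' @param schedule a [frame_schedule()] matching the 4th dimension.
#' @param t_star minutes (default 20).
#' @param fit_mask optional [parametric_map()] restricting fitted voxels.
#' @param voxel_size,affine geometry for the output map; defaults taken from
#'   `ref_mask`.
#' @return A [parametric_map()] of DVR with attributes `k2prime` and
#'   `n_degenerate`.
#' @export
dvr_map_from_dynamic <- function(dynamic, ref_mask, highbind_mask, schedule,
                                 t_star = 20, fit_mask = NULL,
                                 voxel_size = NULL, affine = NULL) {
  if (is.list(dynamic) && !is.null(dynamic$values)) dynamic <- dynamic$values
  d <- dim(dynamic)
  if (length(d) != 4L) stop("dynamic must be a 4D array")
  if (d[4] != length(schedule))
    stop("dynamic has ", d[4], " frames but the schedule has ",
         length(schedule))
  dims <- d[1:3]
  mask_idx <- function(m, what) {
    if (!all(dim(m$values) == dims))
      stop(what, " dimensions do not match the dynamic image")
    idx <- which(m$values != 0)
    if (!length(idx)) stop(what, " is empty")
    idx
  }
  ref_idx <- mask_idx(ref_mask, "ref_mask")
  hb_idx <- mask_idx(highbind_mask, "highbind_mask")
  V <- matrix(dynamic, nrow = prod(dims), ncol = d[4])
  ref_tac <- tac(schedule, colMeans(V[ref_idx, , drop = FALSE]))
  hb_tac <- tac(schedule, colMeans(V[hb_idx, , drop = FALSE]))
  k2prime <- fit_mrtm(hb_tac, ref_tac, t_star = t_star)$k2prime
  if (!is.finite(k2prime) || k2prime <= 0)
    stop("k2prime estimated from the high-binding region is not positive (",
         format(k2prime, digits = 3), "); check the region choices")

  fit_idx <- if (is.null(fit_mask)) seq_len(prod(dims))
             else mask_idx(fit_mask, "fit_mask")
  keep <- schedule$mid_min >= t_star
  W <- cumtrapz_weights(schedule$mid_min)
  a <- integrate_tac(ref_tac)[keep] + ref_tac$activity[keep] / k2prime
  Vt <- V[fit_idx, , drop = FALSE]
  int_t <- (Vt %*% t(W))[, keep, drop = FALSE]
  y <- Vt[, keep, drop = FALSE]
  # per-voxel normal equations for C_T = b1 * a + b2 * int_t
  S11 <- sum(a * a)
  S12 <- as.numeric(int_t %*% a)
  S22 <- rowSums(int_t^2)
  b1v <- as.numeric(y %*% a)
  b2v <- rowSums(y * int_t)
  det <- S11 * S22 - S12^2
  # relative determinant guards near-collinear designs (cond^2 ~ 1e10 cutoff)
  degenerate <- !is.finite(det) | det <= (S11 * S22) * 1e-10 | S22 == 0
  beta1 <- (S22 * b1v - S12 * b2v) / det
  beta2 <- (S11 * b2v - S12 * b1v) / det
  dvr <- -beta1 / beta2
  dvr[degenerate | !is.finite(dvr)] <- NaN
  out <- array(NaN, dims)
  out[fit_idx] <- dvr
  map <- parametric_map(out,
                        voxel_size = voxel_size %||% ref_mask$voxel_size,
                        affine = affine %||% ref_mask$affine,
                        space = ref_mask$space, kind = "DVR")
  attr(map, "k2prime") <- k2prime
  attr(map, "n_degenerate") <- sum(!is.finite(dvr))
  map
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify mean cortical amyloid burden against validated DVR cut-offs
#'
#' Status is `low` when mean cortical DVR <= `low` (a value associated with
#' a 90% likelihood of being a low accumulator), `high` when >= `high`
#' (90% likelihood of being a high accumulator), and `indeterminate`
#' between. Accepts a scalar, a vector of subject DVRs (optionally with
#' group labels, yielding per-group counts and percentages to one decimal),
#' or a DVR [parametric_map()] plus a cortical mask (NaN voxels excluded
#' and counted).
#'
#' @param dvr scalar, numeric vector, or [parametric_map()].
#' @param cortical_mask required when `dvr` is a map.
#' @param group optional group labels parallel to a vector `dvr`.
#' @param low,high DVR cut-offs (defaults 1.08 and 1.20).
#' @return An `amyloid_summary` list: `mean_cortical_dvr`, `status` and,
#'   for cohorts, a `table` of counts and one-decimal percentages per group.
#' @export
summarize_cortical_amyloid <- function(dvr, cortical_mask = NULL,
                                       group = NULL, low = 1.08,
                                       high = 1.20) {
  if (low >= high) stop("low cut-off must be below the high cut-off")
  status_of <- function(v)
    ifelse(v <= low, "low", ifelse(v >= high, "high", "indeterminate"))
  n_excluded <- 0L
  if (inherits(dvr, "parametric_map")) {
    if (is.null(cortical_mask)) stop("a cortical mask is required for a map")
    idx <- which(cortical_mask$values != 0)
    if (!length(idx)) stop("cortical mask is empty")
    vals <- dvr$values[idx]
    n_excluded <- sum(!is.finite(vals))
    dvr <- mean(vals[is.finite(vals)])
  }
  dvr <- as.numeric(dvr)
  res <- list(mean_cortical_dvr = dvr, status = status_of(dvr),
              low = low, high = high, n_excluded_voxels = n_excluded)
  if (length(dvr) > 1L) {
    if (is.null(group)) group <- rep("all", length(dvr))
    if (length(group) != length(dvr))
      stop("group labels must parallel the DVR vector")
    tab <- do.call(rbind, lapply(split(seq_along(dvr), group), function(i) {
      st <- status_of(dvr[i])
      data.frame(group = group[i[1]], n = length(i),
                 n_low = sum(st == "low"),
                 n_indeterminate = sum(st == "indeterminate"),
                 n_high = sum(st == "high"),
                 pct_low = round(100 * sum(st == "low") / length(i), 1),
                 pct_high = round(100 * sum(st == "high") / length(i), 1),
                 mean_dvr = mean(dvr[i]))
    }))
    rownames(tab) <- NULL
    res$table <- tab
  }
  structure(res, class = "amyloid_summary")
}

#' @export
print.amyloid_summary <- function(x, ...) {
  if (length(x$mean_cortical_dvr) == 1L) {
    cat(sprintf("<amyloid_summary> mean cortical DVR %.3f: %s\n",
                x$mean_cortical_dvr, x$status))
  } else {
    cat("<amyloid_summary> cohort:\n")
    print(x$table)
  }
  invisible(x)
}
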