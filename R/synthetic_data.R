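#' Default behaviour loading preset
#'
#' Ten behavioural variables mirroring a typical elderly-cohort design:
#' demographics (age, sex coded female = 0 / male = 1, years of education,
#' APOE4 allele count) and six cognitive scores (category and letter
#' fluency, verbal immediate/delayed recall, visual-spatial immediate/
#' delayed recall). The signs follow the pattern typically seen for amyloid
#' burden — age, male sex and APOE4 positive; memory and semantic fluency
#' negative; education and phonemic fluency near zero. Purely a demo
#' preset for the generator, not a claim about any cohort.
#'
#' @return Named numeric vector of loadings in \[-1, 1\].
#' @export
default_behaviour_loadings <- function() {
  c(age = 0.27, sex = 0.27, education = 0, apoe4 = 0.24,
    category_fluency = -0.33, letter_fluency = 0,
    cvlt_immediate = -0.46, cvlt_delayed = -0.39,
    bvmt_immediate = -0.39, bvmt_delayed = -0.45)
}

#' Configuration for the planted-latent-variable PLS generator
#'
#' Describes a cohort of subject maps and behaviour scores whose cross-block
#' covariance is dominated by a single planted latent variable: each subject
#' draws a latent score `z ~ N(0, 1)`; their map is
#' `effect_size * z * voxel_salience_pattern` on the signal region plus
#' `N(0, noise_sd)` everywhere, and behaviour column `j` is
#' `loading_j * z + N(0, 1)`. The population cross-block correlation matrix
#' is therefore rank 1.
#'
#' The default scenario is a scaled-down stand-in for a whole-brain study:
#' 60 subjects on a 20^3 grid of 8 mm voxels (a head-sized field of view at
#' coarse resolution), a 6x6x6-voxel signal cube, effect size 1.5 against
#' unit noise, and the [default_behaviour_loadings()].
#'
#' @param n_subjects number of subjects (>= 3).
#' @param grid_dims 3 positive integers.
#' @param voxel_size_mm 3 positive reals (mm).
#' @param behaviour_loadings named vector in \[-1, 1\]; not all zero when
#'   `effect_size > 0`.
#' @param signal_region integer vector of 1-based column-major voxel
#'   indices; default: a centred 6x6x6 cube.
#' @param voxel_salience_pattern values on `signal_region` (default all 1).
#' @param effect_size scales the latent signal against unit-SD z (>= 0).
#' @param noise_sd voxel noise SD (> 0).
#' @param seed integer seed.
#' @return A `synthetic_pls_config` list.
#' @export
synthetic_pls_config <- function(n_subjects = 60, grid_dims = c(20, 20, 20),
                                 voxel_size_mm = c(8, 8, 8),
                                 behaviour_loadings =
                                   default_behaviour_loadings(),
                                 signal_region = NULL,
                                 voxel_salience_pattern = NULL,
                                 effect_size = 1.5, noise_sd = 1,
                                 seed = 1L) {
  grid_dims <- as.integer(grid_dims)
  if (length(grid_dims) != 3L || any(grid_dims < 1L))
    stop("grid_dims must be 3 positive integers")
  if (n_subjects < 3L) stop("n_subjects must be at least 3")
  if (any(voxel_size_mm <= 0)) stop("voxel sizes must be positive")
  if (effect_size < 0) stop("effect_size must be non-negative")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (any(abs(behaviour_loadings) > 1))
    stop("behaviour loadings must lie in [-1, 1]")
  if (effect_size > 0 && all(behaviour_loadings == 0))
    stop("behaviour loadings must not all be zero when effect_size > 0")
  if (is.null(signal_region)) {
    lo <- pmax(1L, grid_dims %/% 2L - 2L)
    hi <- pmin(grid_dims, lo + 5L)
    cube <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2],
                                  k = lo[3]:hi[3]))
    signal_region <- cube[, 1] + grid_dims[1] * (cube[, 2] - 1L) +
      grid_dims[1] * grid_dims[2] * (cube[, 3] - 1L)
  }
  signal_region <- as.integer(signal_region)
  if (any(signal_region < 1L) || any(signal_region > prod(grid_dims)))
    stop("signal_region indices lie outside the grid")
  if (is.null(voxel_salience_pattern))
    voxel_salience_pattern <- rep(1, length(signal_region))
  if (length(voxel_salience_pattern) != length(signal_region))
    stop("voxel_salience_pattern must match signal_region in length")
  structure(list(n_subjects = as.integer(n_subjects), grid_dims = grid_dims,
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 behaviour_loadings = behaviour_loadings,
                 signal_region = signal_region,
                 voxel_salience_pattern = as.numeric(voxel_salience_pattern),
                 effect_size = effect_size, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_pls_config")
}

#' Generate a paired imaging/behaviour cohort with one planted latent variable
#'
#' @param config a [synthetic_pls_config()].
#' @return A list with `maps` (list of [parametric_map()]s, one per
#'   subject), `behaviour` (data.frame with `subject_id` plus one column per
#'   loading), and `ground_truth` (`latent_scores`, unit-norm
#'   `true_voxel_salience` over the full grid, unit-norm
#'   `true_behaviour_salience`, and the `signal_region` indices).
#' @export
generate_pls_dataset <- function(config) {
  if (!inherits(config, "synthetic_pls_config"))
    stop("config must be a synthetic_pls_config")
  set.seed(config$seed)
  n <- config$n_subjects
  nv <- prod(config$grid_dims)
  b <- length(config$behaviour_loadings)
  z <- stats::rnorm(n)

  signal <- numeric(nv)
  signal[config$signal_region] <- config$voxel_salience_pattern
  maps <- vector("list", n)
  for (i in seq_len(n)) {
    vals <- config$effect_size * z[i] * signal +
      stats::rnorm(nv, sd = config$noise_sd)
    maps[[i]] <- parametric_map(array(vals, config$grid_dims),
                                voxel_size = config$voxel_size_mm,
                                space = "MNI", kind = "DVR")
  }
  Y <- matrix(stats::rnorm(n * b), n, b) +
    outer(z, config$behaviour_loadings)
  colnames(Y) <- names(config$behaviour_loadings)
  behaviour <- data.frame(subject_id = sprintf("S%03d", seq_len(n)), Y,
                          check.names = FALSE)

  unit <- function(v) v / sqrt(sum(v^2))
  list(maps = maps, behaviour = behaviour,
       ground_truth = list(
         latent_scores = z,
         true_voxel_salience = unit(signal),
         true_behaviour_salience = unit(config$behaviour_loadings),
         signal_region = config$signal_region))
}

biexp_frame_means <- function(schedule, amp, lambda1, lambda2) {
  a <- schedule$start / 60
  bnd <- (schedule$start + schedule$duration) / 60
  # exact frame average of amp * (exp(-l1 t) - exp(-l2 t))
  amp * ((exp(-lambda1 * a) - exp(-lambda1 * bnd)) / lambda1 -
           (exp(-lambda2 * a) - exp(-lambda2 * bnd)) / lambda2) / (bnd - a)
}

#' Simulate a reference-region time-activity curve
#'
#' Bi-exponential input shape `amp * (exp(-lambda1 t) - exp(-lambda2 t))`
#' (zero at injection, single peak, slow washout), frame-averaged exactly
#' over the schedule. The defaults give a curve peaking around 6 minutes
#' with slow clearance, a plausible shape for a cerebellar grey reference
#' region. The continuous curve sampled on a fine 0.05 min grid is attached
#' (attribute `fine`) for downstream forward modelling.
#'
#' @param schedule a [frame_schedule()].
#' @param amp amplitude (activity units, default 100).
#' @param lambda1 slow rate, 1/min (default 0.03).
#' @param lambda2 fast rate, 1/min (default 0.5); requires
#'   `lambda2 > lambda1 > 0`.
#' @return A [tac()].
#' @export
generate_reference_tac <- function(schedule = default_frame_schedule(),
                                   amp = 100, lambda1 = 0.03,
                                   lambda2 = 0.5) {
  if (!(lambda2 > lambda1 && lambda1 > 0))
    stop("rates must satisfy lambda2 > lambda1 > 0")
  out <- tac(schedule, biexp_frame_means(schedule, amp, lambda1, lambda2))
  t_end <- (schedule$start[length(schedule)] +
              schedule$duration[length(schedule)]) / 60
  tt <- seq(0, t_end, by = 0.05)
  attr(out, "fine") <- list(
    time = tt, activity = amp * (exp(-lambda1 * tt) - exp(-lambda2 * tt)))
  out
}

fine_reference_curve <- function(ref) {
  fine <- attr(ref, "fine")
  if (!is.null(fine)) return(fine)
  # fall back to linear interpolation of frame means through (0, 0)
  sched <- ref$schedule
  t_end <- (sched$start[length(sched)] + sched$duration[length(sched)]) / 60
  tt <- seq(0, t_end, by = 0.05)
  list(time = tt,
       activity = stats::approx(c(0, sched$mid_min), c(0, ref$activity),
                                xout = tt, rule = 2)$y)
}

#' Simulate a target-tissue curve from the simplified reference tissue model
#'
#' Forward SRTM solution
#' \deqn{C_T(t) = R_1 C_R(t) + (k_2 - R_1 k_{2a}) [C_R \otimes
#'   e^{-k_{2a} t}](t), \quad k_{2a} = k_2 / DVR,}
#' computed on a fine uniform grid (0.05 min, so every frame boundary of
#' the standard schedule falls on a grid point; convolution by an exact
#' trapezoid-exponential recursion). The direct-delivery term uses the
#' reference frame activities themselves and only the convolution term is
#' frame-averaged (trapezoid), so the model collapses exactly to the
#' reference curve when `R1 = 1, DVR = 1`. Optional additive Gaussian
#' frame noise. Because the curve satisfies the SRTM
#' relation exactly, it carries a known ground-truth DVR and serves as the
#' recovery oracle for [fit_mrtm()] and [fit_mrtm2()].
#'
#' @param ref reference [tac()] (ideally from [generate_reference_tac()],
#'   whose attached fine-grid curve is used).
#' @param R1 delivery ratio (> 0).
#' @param k2 target-tissue clearance, 1/min (> 0).
#' @param DVR distribution volume ratio (>= 1 typical); `k2a = k2 / DVR`
#'   must be positive.
#' @param noise_sd additive Gaussian SD per frame (0 = noiseless).
#' @param seed optional seed for the noise draw.
#' @return A [tac()] on the same schedule as `ref`.
#' @export
generate_target_tac <- function(ref, R1 = 1, k2 = 0.15, DVR = 1.5,
                                noise_sd = 0, seed = NULL) {
  if (!inherits(ref, "tac")) stop("ref must be a tac")
  if (R1 <= 0 || k2 <= 0) stop("R1 and k2 must be positive")
  k2a <- k2 / DVR
  if (!is.finite(k2a) || k2a <= 0) stop("k2a = k2 / DVR must be positive")
  fine <- fine_reference_curve(ref)
  tt <- fine$time
  cr <- fine$activity
  dt <- tt[2] - tt[1]
  # y_i = e^{-k2a dt} y_{i-1} + trapezoid increment of C_R against the
  # exponential kernel (exact for piecewise-linear C_R up to O(dt^2))
  e <- exp(-k2a * dt)
  conv <- numeric(length(tt))
  for (i in 2:length(tt))
    conv[i] <- e * conv[i - 1] + dt / 2 * (cr[i] + e * cr[i - 1])
  sched <- ref$schedule
  a <- sched$start / 60
  bnd <- (sched$start + sched$duration) / 60
  conv_frame <- vapply(seq_along(a), function(f) {
    inside <- which(tt >= a[f] - 1e-9 & tt <= bnd[f] + 1e-9)
    w <- conv[inside]
    sum((w[-1] + w[-length(w)]) / 2 * diff(tt[inside])) / (bnd[f] - a[f])
  }, numeric(1))
  act <- R1 * ref$activity + (k2 - R1 * k2a) * conv_frame
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    act <- act + stats::rnorm(length(act), sd = noise_sd)
  }
  tac(sched, act)
}

#' Two-group cohort specification
#'
#' Per-group label, size and per-variable mean and SD, from which
#' [generate_cohort_scores()] draws independent Gaussian scores. The
#' summary-statistics form mirrors how cohort tables are printed in study
#' reports, so a printed table can be used directly as a generator input.
#'
#' @param groups a named list; each element is a list with `n` (>= 2) and
#'   `mean` / `sd` named numeric vectors over the same variables.
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(groups) {
  if (!length(groups) || is.null(names(groups)))
    stop("groups must be a named list")
  vars <- names(groups[[1]]$mean)
  for (g in names(groups)) {
    spec <- groups[[g]]
    if (is.null(spec$n) || spec$n < 2) stop("group '", g, "' needs n >= 2")
    if (!identical(names(spec$mean), vars) ||
        !identical(names(spec$sd), vars))
      stop("all groups must specify mean and sd for the same variables")
    if (any(spec$sd <= 0)) stop("group '", g, "' has non-positive SDs")
  }
  structure(list(groups = groups, variables = vars), class = "cohort_spec")
}

#' Draw per-subject scores from a cohort specification
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed.
#' @return data.frame with `subject_id`, `group` and one column per
#'   variable; independent Gaussian draws at the specified means/SDs.
#' @export
generate_cohort_scores <- function(spec, seed = 1L) {
  if (!inherits(spec, "cohort_spec")) stop("spec must be a cohort_spec")
  set.seed(seed)
  rows <- lapply(names(spec$groups), function(g) {
    gs <- spec$groups[[g]]
    scores <- vapply(spec$variables, function(v)
      stats::rnorm(gs$n, gs$mean[[v]], gs$sd[[v]]), numeric(gs$n))
    data.frame(group = g, as.data.frame(scores), check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  data.frame(subject_id = sprintf("S%03d", seq_len(nrow(out))), out,
             check.names = FALSE)
}

#' Built-in reference cohort summary (two-group MCI study design)
#'
#' Printed summary statistics for a 47-subject multi-domain amnestic MCI
#' group versus a 37-subject healthy comparison group: neuropsychological
#' score means and SDs, sex counts, and amyloid-status counts against the
#' 1.08 / 1.20 DVR cut-offs. Used as a realistic [cohort_spec()] preset and
#' as the input for summary-statistic group tests.
#'
#' @return A list with `spec` (a [cohort_spec()]), `summary` (data.frame of
#'   variable, per-group mean/sd/n), `sex_counts` (2x2 F/M by group) and
#'   `amyloid_counts` (per-group n, n at or below the low cut-off, n at or
#'   above the high cut-off).
#' @export
mci_cohort_reference <- function() {
  vars <- c(age = NA, education = NA, letter_fluency = NA,
            category_fluency = NA, cvlt_immediate = NA, cvlt_delayed = NA,
            bvmt_immediate = NA, bvmt_delayed = NA)
  mci_mean <- c(age = 69, education = 15, letter_fluency = 37.47,
                category_fluency = 33.83, cvlt_immediate = 44.17,
                cvlt_delayed = 8.17, bvmt_immediate = 15.30,
                bvmt_delayed = 5.81)
  mci_sd <- c(age = 7, education = 3, letter_fluency = 10.94,
              category_fluency = 9.65, cvlt_immediate = 12.20,
              cvlt_delayed = 3.92, bvmt_immediate = 7.84,
              bvmt_delayed = 3.17)
  hc_mean <- c(age = 67, education = 16, letter_fluency = 44.68,
               category_fluency = 40.68, cvlt_immediate = 55.22,
               cvlt_delayed = 11.89, bvmt_immediate = 18.92,
               bvmt_delayed = 7.68)
  hc_sd <- c(age = 7, education = 3, letter_fluency = 12.51,
             category_fluency = 8.24, cvlt_immediate = 10.71,
             cvlt_delayed = 2.98, bvmt_immediate = 6.09,
             bvmt_delayed = 2.58)
  spec <- cohort_spec(list(
    mci = list(n = 47, mean = mci_mean, sd = mci_sd),
    comparison = list(n = 37, mean = hc_mean, sd = hc_sd)))
  summary <- data.frame(
    variable = names(vars),
    mci_mean = unname(mci_mean), mci_sd = unname(mci_sd), mci_n = 47,
    comparison_mean = unname(hc_mean), comparison_sd = unname(hc_sd),
    comparison_n = 37)
  list(spec = spec, summary = summary,
       sex_counts = matrix(c(20, 27, 15, 21), 2,
                           dimnames = list(c("F", "M"),
                                           c("mci", "comparison"))),
       amyloid_counts = data.frame(
         group = c("mci", "comparison"), n = c(47, 37),
         n_low = c(6, 6), n_high = c(24, 7)))
}
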