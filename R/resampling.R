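#' Orthogonal Procrustes alignment of singular-vector matrices
#'
#' Finds the orthogonal rotation `Q` minimising the Frobenius distance
#' `|| sample %*% Q - reference ||`, via the SVD of
#' `t(reference) %*% sample`. Resampled SVDs are determined only up to
#' reflection/rotation of their axes; aligning each resample's saliences to
#' the original fit makes them comparable across bootstrap iterations.
#'
#' @param reference matrix with orthonormal columns (e.g. original
#'   behaviour saliences).
#' @param sample matrix of the same shape.
#' @return A list with `rotation` (the orthogonal Q) and `aligned`
#'   (`sample %*% Q`).
#' @export
procrustes_align <- function(reference, sample) {
  reference <- as.matrix(reference)
  sample <- as.matrix(sample)
  if (!all(dim(reference) == dim(sample)))
    stop("reference and sample must have the same shape")
  sv <- svd(crossprod(reference, sample))
  rotation <- sv$v %*% t(sv$u)
  list(rotation = rotation, aligned = sample %*% rotation)
}

#' Permutation test for latent-variable significance
#'
#' Each iteration permutes the subject rows of the behaviour block (a
#' uniform random permutation — sampling without replacement), refits the
#' PLS, and records the singular values. The p-value of latent variable `l`
#' is the proportion of permutations whose l-th largest singular value
#' strictly exceeds the observed `s[l]`; an add-one smoothed variant
#' `(1 + count) / (1 + n_perm)` is available.
#'
#' @param X,Y blocks as in [fit_pls()].
#' @param n_perm number of permutations (>= 1; default 100).
#' @param seed integer seed.
#' @param smoothed use the add-one estimator (default `FALSE`).
#' @return A `permutation_result`: `n_perm`, `observed_singular_values`,
#'   `null_singular_values` (n_perm x L) and `p_values`.
#' @export
permutation_test <- function(X, Y, n_perm = 100, seed = NULL,
                             smoothed = FALSE) {
  if (n_perm < 1) stop("n_perm must be at least 1")
  blocks <- as_pls_blocks(X, Y)
  Zx <- zscore_cols(blocks$X, "imaging")
  Zy <- zscore_cols(blocks$Y, "behaviour")
  obs <- fit_pls_core(Zx, Zy, drop_tol = 1e-12)
  L <- length(obs$singular_values)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(Zx)
  null_s <- matrix(NA_real_, n_perm, L)
  for (p in seq_len(n_perm)) {
    perm <- sample.int(n)
    null_s[p, ] <- fit_pls_core(Zx, Zy[perm, , drop = FALSE],
                                ncomp = L)$singular_values
  }
  exceed <- colSums(null_s > rep(obs$singular_values, each = n_perm))
  p_values <- if (smoothed) (1 + exceed) / (1 + n_perm) else exceed / n_perm
  structure(list(n_perm = n_perm,
                 observed_singular_values = obs$singular_values,
                 null_singular_values = null_s, p_values = p_values),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> %d permutations\n", x$n_perm))
  cat("  p:", paste(sprintf("%.3g", x$p_values), collapse = ", "), "\n")
  invisible(x)
}

#' Bootstrap standard errors for saliences and behaviour correlations
#'
#' Each iteration resamples subjects with replacement (identical rows in
#' both blocks), refits the PLS, and aligns the resampled saliences to the
#' original fit by [procrustes_align()] on the behaviour saliences (the
#' same rotation is applied to the voxel saliences and brain scores).
#' Voxel salience standard errors are the standard deviation across
#' aligned iterations; the bootstrap salience ratio (BSR) — a pseudo-z
#' used to threshold voxels that contribute reliably to a latent variable —
#' is the original salience divided by its bootstrap SE. Behaviour
#' correlations are recomputed per resample; their SEs and percentile
#' 2.5/97.5 confidence intervals are reported. A resample that produces a
#' constant column is redrawn (at most 100 attempts).
#'
#' @param X,Y blocks as in [fit_pls()].
#' @param n_boot bootstrap iterations (>= 2; default 1000).
#' @param seed integer seed.
#' @param ci_level confidence level for behaviour-correlation percentile
#'   intervals (default 0.95).
#' @return A `bootstrap_result`: `n_boot`, `voxel_salience_se` and `bsr`
#'   (v x L), `behaviour_correlation_se` (b x L) and
#'   `behaviour_correlation_ci` (b x L x 2, lower/upper).
#' @export
bootstrap_saliences <- function(X, Y, n_boot = 1000, seed = NULL,
                                ci_level = 0.95) {
  if (n_boot < 2) stop("n_boot must be at least 2")
  blocks <- as_pls_blocks(X, Y)
  n <- nrow(blocks$X)
  if (n < 10)
    warning("bootstrap with fewer than 10 subjects is unreliable")
  Zx <- zscore_cols(blocks$X, "imaging")
  Zy <- zscore_cols(blocks$Y, "behaviour")
  orig <- fit_pls_core(Zx, Zy, drop_tol = 1e-12)
  L <- length(orig$singular_values)
  b <- ncol(Zy)
  v <- ncol(Zx)
  if (!is.null(seed)) set.seed(seed)

  v_sum <- matrix(0, v, L)
  v_sumsq <- matrix(0, v, L)
  r_boot <- array(NA_real_, c(b, L, n_boot))
  for (it in seq_len(n_boot)) {
    idx <- NULL
    for (attempt in seq_len(100)) {
      cand <- sample.int(n, replace = TRUE)
      Xb <- blocks$X[cand, , drop = FALSE]
      Yb <- blocks$Y[cand, , drop = FALSE]
      ok <- all(col_sds(Xb) > 0) &&
        all(col_sds(Yb) > 0)
      if (ok) {
        idx <- cand
        break
      }
    }
    if (is.null(idx))
      stop("bootstrap resample produced a constant column in 100 draws")
    fit <- fit_pls_core(scale(Xb), scale(Yb), ncomp = L)
    Lb <- length(fit$singular_values)
    if (Lb < L) {
      # rank-deficient resample: pad with zero saliences
      pad <- function(M) cbind(M, matrix(0, nrow(M), L - Lb))
      fit$behaviour_saliences <- pad(fit$behaviour_saliences)
      fit$voxel_saliences <- pad(fit$voxel_saliences)
      fit$brain_scores <- pad(fit$brain_scores)
    }
    rot <- procrustes_align(orig$behaviour_saliences,
                            fit$behaviour_saliences)$rotation
    Vb <- fit$voxel_saliences %*% rot
    v_sum <- v_sum + Vb
    v_sumsq <- v_sumsq + Vb^2
    r_boot[, , it] <- stats::cor(Yb, fit$brain_scores %*% rot)
  }
  v_se <- sqrt(pmax(0, (v_sumsq - v_sum^2 / n_boot) / (n_boot - 1)))
  bsr <- orig$voxel_saliences / v_se
  bsr[v_se == 0] <- NaN
  alpha <- (1 - ci_level) / 2
  ci <- apply(r_boot, c(1, 2), stats::quantile,
              probs = c(alpha, 1 - alpha), na.rm = TRUE)
  ci <- aperm(ci, c(2, 3, 1))
  dimnames(ci)[[3]] <- c("lower", "upper")
  structure(list(n_boot = n_boot, voxel_salience_se = v_se, bsr = bsr,
                 behaviour_correlation_se = apply(r_boot, c(1, 2),
                                                  stats::sd, na.rm = TRUE),
                 behaviour_correlation_ci = ci, ci_level = ci_level),
            class = "bootstrap_result")
}

# fast column SDs for resample validity checks
col_sds <- function(M) {
  mu <- colMeans(M)
  sqrt(colSums(sweep(M, 2, mu)^2) / (nrow(M) - 1))
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> %d iterations, %d voxels x %d LV\n",
              x$n_boot, nrow(x$bsr), ncol(x$bsr)))
  invisible(x)
}
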