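as_pls_blocks <- function(X, Y) {
  Xm <- if (inherits(X, "datamat")) X$matrix else as.matrix(X)
  Ym <- behaviour_matrix(Y)
  if (nrow(Xm) != nrow(Ym))
    stop("imaging and behaviour blocks have different subject counts (",
         nrow(Xm), " vs ", nrow(Ym), ")")
  storage.mode(Xm) <- "double"
  storage.mode(Ym) <- "double"
  list(X = Xm, Y = Ym)
}

zscore_cols <- function(M, block) {
  sds <- apply(M, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)[1]
    nm <- colnames(M)[bad] %||% as.character(bad)
    stop("constant column in the ", block, " block: ", nm)
  }
  scale(M)
}

#' Fit brain-behaviour partial least squares correlation (PLS-C)
#'
#' Both blocks are column-wise z-scored (SD with denominator n - 1), the
#' cross-block matrix `R = t(Zy) %*% Zx / (n - 1)` — whose entries are the
#' Pearson correlations of every behaviour variable with every voxel — is
#' decomposed by SVD `R = U diag(s) t(V)`. Each latent variable pairs a
#' behavioural salience profile (column of U) with a topographic voxel
#' salience profile (column of V); its covariance explained is
#' `100 * s^2 / sum(s^2)`. Brain (subject) scores are the projections
#' `Zx %*% V`, and each behaviour's Pearson correlation with each latent
#' variable's brain score is reported. The global sign of every latent
#' variable is fixed so that the largest-magnitude behaviour salience
#' element is positive; latent variables with singular value below
#' `1e-12 * s[1]` are dropped as rank-deficient.
#'
#' @param X imaging block: a `datamat` from [build_datamat()] or an
#'   n x v matrix.
#' @param Y behaviour block: data.frame (columns other than `subject_id` /
#'   `group`) or n x b matrix; no constant columns.
#' @return A `pls_result` with `behaviour_saliences` (b x L),
#'   `voxel_saliences` (v x L), `singular_values`, `covariance_explained`
#'   (percent), `brain_scores` (n x L) and `behaviour_correlations` (b x L).
#' @export
fit_pls <- function(X, Y) {
  blocks <- as_pls_blocks(X, Y)
  n <- nrow(blocks$X)
  if (n < 3) stop("need at least 3 subjects")
  Zx <- zscore_cols(blocks$X, "imaging")
  Zy <- zscore_cols(blocks$Y, "behaviour")
  fit <- fit_pls_core(Zx, Zy, drop_tol = 1e-12)
  fit$behaviour_correlations <- stats::cor(blocks$Y, fit$brain_scores)
  rownames(fit$behaviour_saliences) <- colnames(blocks$Y)
  rownames(fit$behaviour_correlations) <- colnames(blocks$Y)
  fit$n_subjects <- n
  class(fit) <- "pls_result"
  fit
}

# SVD of the cross-block correlation matrix on pre-z-scored blocks.
# ncomp > 0 keeps exactly that many components (bootstrap refits need a
# fixed L); drop_tol removes trailing components with s < drop_tol * s1.
fit_pls_core <- function(Zx, Zy, ncomp = 0L, drop_tol = 0) {
  n <- nrow(Zx)
  R <- crossprod(Zy, Zx) / (n - 1)
  sv <- svd(R)
  L <- length(sv$d)
  if (ncomp > 0L) L <- min(L, ncomp)
  else if (drop_tol > 0 && sv$d[1] > 0) L <- sum(sv$d >= drop_tol * sv$d[1])
  U <- sv$u[, seq_len(L), drop = FALSE]
  V <- sv$v[, seq_len(L), drop = FALSE]
  s <- sv$d[seq_len(L)]
  for (l in seq_len(L)) {
    j <- which.max(abs(U[, l]))
    if (U[j, l] < 0) {
      U[, l] <- -U[, l]
      V[, l] <- -V[, l]
    }
  }
  list(behaviour_saliences = U, voxel_saliences = V, singular_values = s,
       covariance_explained = 100 * s^2 / sum(sv$d^2),
       brain_scores = Zx %*% V)
}

#' @export
print.pls_result <- function(x, ...) {
  cat(sprintf("<pls_result> %d latent variable(s), n = %d\n",
              length(x$singular_values), x$n_subjects))
  cat("  covariance explained (%):",
      paste(sprintf("%.1f", x$covariance_explained), collapse = ", "), "\n")
  invisible(x)
}

#' Per-voxel Pearson correlation map for one behaviour measure
#'
#' The "datamat correlation map": Pearson correlation of every voxel's
#' values across subjects with a single behaviour column, mapped back into
#' a volume. Zero-variance voxels are flagged as `NaN`, not zero.
#'
#' @param X a `datamat` from [build_datamat()].
#' @param y numeric vector, one value per subject; must be non-constant.
#' @return A [parametric_map()] of correlations (`kind = "correlation"`).
#' @export
datamat_correlation_map <- function(X, y) {
  if (!inherits(X, "datamat")) stop("X must be a datamat")
  y <- as.numeric(y)
  if (length(y) != nrow(X$matrix))
    stop("y length must equal the number of subjects")
  if (stats::sd(y) == 0) stop("behaviour column is constant")
  r <- suppressWarnings(as.numeric(stats::cor(X$matrix, y)))
  r[is.na(r)] <- NaN
  datamat_to_map(X, r, kind = "correlation", fill = NA_real_)
}
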