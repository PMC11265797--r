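#' Least-squares (Kabsch) superposition of coordinate frames
#'
#' Rigidly superposes each frame (a flattened 3N coordinate vector) onto a
#' reference shape, removing global rotation and translation. Two passes are
#' made: frames are first fitted to the mean of the raw frames, then refitted
#' to the mean of the fitted frames.
#'
#' @param frames matrix (n_frames x 3N) of flattened coordinates
#' @return matrix of superposed frames, same shape
#' @export
kabsch_align <- function(frames) {
  frames <- as.matrix(frames)
  if (ncol(frames) %% 3 != 0)
    stop("kabsch_align: columns must be a multiple of 3 (flattened xyz)")
  fit_all <- function(frames, ref_flat) {
    ref <- matrix(ref_flat, ncol = 3, byrow = TRUE)
    ref <- sweep(ref, 2, colMeans(ref))
    t(apply(frames, 1, function(f) {
      m <- matrix(f, ncol = 3, byrow = TRUE)
      m <- sweep(m, 2, colMeans(m))
      s <- svd(t(m) %*% ref)
      d <- sign(det(s$v %*% t(s$u)))
      rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
      as.numeric(t(m %*% t(rot)))
    }))
  }
  out <- fit_all(frames, colMeans(frames))
  fit_all(out, colMeans(out))
}

#' Principal component analysis of coordinate frames
#'
#' Eigendecomposition of the covariance of (optionally superposed) frames.
#' Components are unit-norm and ordered by decreasing explained variance;
#' fractions are eigenvalues over the covariance trace.
#'
#' @param frames matrix (n_frames x D); with `align = TRUE`, D must be 3N
#'   flattened coordinates, which are Kabsch-superposed before the covariance
#' @param align superpose frames first (removes rigid-body motion, the
#'   conventional pre-processing for trajectory PCA)
#' @return a `pc_basis`: list with `mean` (D), `components` (D x K, columns
#'   are PCs), `sdev`, `fractions`
#' @export
pca_fit <- function(frames, align = FALSE) {
  frames <- as.matrix(frames)
  if (nrow(frames) < 2L) stop("pca_fit: need at least 2 frames")
  if (align) frames <- kabsch_align(frames)
  pc <- stats::prcomp(frames, center = TRUE, scale. = FALSE)
  keep <- pc$sdev > max(pc$sdev) * 1e-10
  if (!all(keep))
    warning("pca_fit: rank-deficient input; returning ", sum(keep),
            " of ", length(keep), " components")
  structure(list(
    mean = pc$center,
    components = pc$rotation[, keep, drop = FALSE],
    sdev = pc$sdev[keep],
    fractions = pc$sdev[keep]^2 / sum(pc$sdev^2),
    aligned = align
  ), class = "pc_basis")
}

#' @export
print.pc_basis <- function(x, ...) {
  k <- min(5, length(x$fractions))
  cat("<pc_basis> ", ncol(x$components), " components; leading fractions: ",
      paste(sprintf("%.3f", x$fractions[seq_len(k)]), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Project frames onto basis components
#'
#' @param frames matrix (n x D)
#' @param basis a `pc_basis`
#' @param pcs indices of components to project onto
#' @return matrix (n x length(pcs)) of scalar projections of the centred frames
#' @export
project_basis <- function(frames, basis, pcs) {
  frames <- rbind(frames)
  if (ncol(frames) != length(basis$mean))
    stop("project_basis: frame dimensionality does not match basis")
  sweep(frames, 2, basis$mean) %*% basis$components[, pcs, drop = FALSE]
}
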