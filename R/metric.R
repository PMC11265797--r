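#' Entropy-like inter-replicate path-separation metric
#'
#' For a set of replicate paths sharing `n_windows` frames each, and a
#' candidate direction given by weights w over principal components 2..16,
#' the metric is
#'
#'   (2 / (Nrep (Nrep - 1))) * sum_{i<j} sum_{n} log d2(n, i, j)
#'
#' where d2 is the squared separation of frames X(n,i) and X(n,j) along the
#' candidate combination of PCs. Maximizing it over w picks the direction
#' that best separates replicate paths, i.e. the dominant orthogonal degree
#' of freedom not captured by the first PC. Squared distances are floored at
#' `eps` before the log so that coincident frames give a large negative
#' (finite) contribution.
#'
#' Two readings of d2 are supported: `"projection"` (default) takes the
#' scalar projection onto the single combined direction v = sum_k w_k PC_k,
#' d2 = (v . dx)^2; `"per_pc"` takes the weighted per-component sum
#' d2 = sum_k (w_k (PC_k . dx))^2.
#'
#' @param paths a `path_ensemble_set` (see [make_path_ensembles()]) or an
#'   array (n_windows x n_reps x D)
#' @param w weight vector over the selected PCs
#' @param basis a `pc_basis` fitted to the pooled path frames
#' @param pcs which components the weights refer to (default 2..16, clipped
#'   to the available components)
#' @param mode distance interpretation, `"projection"` or `"per_pc"`
#' @param eps floor for squared distances before the log
#' @return the metric value
#' @export
path_separation_metric <- function(paths, w, basis, pcs = NULL,
                                   mode = c("projection", "per_pc"),
                                   eps = 1e-12) {
  mode <- match.arg(mode)
  M <- .pair_projections(paths, basis, pcs)
  .metric_from_projections(M$delta, w, M$n_reps, mode, eps)
}

# projections of inter-replicate frame differences onto the candidate PCs:
# delta is ((npairs * n_windows) x K)
.pair_projections <- function(paths, basis, pcs = NULL) {
  frames <- if (inherits(paths, "path_ensemble_set")) paths$frames else paths
  stopifnot(length(dim(frames)) == 3L)
  n_win <- dim(frames)[1]; n_reps <- dim(frames)[2]; D <- dim(frames)[3]
  if (n_reps < 2L) stop("path_separation_metric: need at least 2 replicates")
  if (is.null(pcs)) pcs <- 2:min(16, ncol(basis$components))
  rows <- list(); ri <- 0L
  comp <- basis$components[, pcs, drop = FALSE]
  for (i in seq_len(n_reps - 1)) {
    xi <- matrix(frames[, i, ], n_win, D)
    for (j in seq(i + 1, n_reps)) {
      ri <- ri + 1L
      rows[[ri]] <- (xi - matrix(frames[, j, ], n_win, D)) %*% comp
    }
  }
  list(delta = do.call(rbind, rows), n_reps = n_reps, pcs = pcs)
}

.metric_from_projections <- function(delta, w, n_reps, mode, eps) {
  w <- as.numeric(w)
  if (length(w) != ncol(delta))
    stop("path_separation_metric: weight length (", length(w),
         ") does not match number of candidate PCs (", ncol(delta), ")")
  d2 <- if (mode == "projection") as.numeric(delta %*% w)^2
        else as.numeric(delta^2 %*% w^2)
  2 / (n_reps * (n_reps - 1)) * sum(log(pmax(d2, eps)))
}

# compact rand/1/bin differential evolution, maximizing fn over a box
.de_maximize <- function(fn, lower, upper, np, maxiter, tol, seed,
                         f_scale = 0.8, cr = 0.9) {
  d <- length(lower)
  set.seed(seed)
  pop <- matrix(runif(np * d, rep(lower, each = np), rep(upper, each = np)), np, d)
  fit <- apply(pop, 1, fn)
  fit[!is.finite(fit)] <- -Inf  # non-finite candidates rejected
  for (it in seq_len(maxiter)) {
    for (m in seq_len(np)) {
      idx <- sample(setdiff(seq_len(np), m), 3)
      trial <- pop[idx[1], ] + f_scale * (pop[idx[2], ] - pop[idx[3], ])
      cross <- runif(d) < cr
      cross[sample.int(d, 1)] <- TRUE
      cand <- ifelse(cross, trial, pop[m, ])
      cand <- pmin(pmax(cand, lower), upper)
      fc <- fn(cand)
      if (is.finite(fc) && fc >= fit[m]) {
        pop[m, ] <- cand
        fit[m] <- fc
      }
    }
    fin <- fit[is.finite(fit)]
    if (length(fin) == np && (max(fin) - min(fin)) < tol * (abs(max(fin)) + tol))
      break
  }
  best <- which.max(fit)
  list(par = pop[best, ], value = fit[best], iterations = it)
}

#' Optimize the orthogonal second collective variable
#'
#' Maximizes [path_separation_metric()] over weights on principal components
#' 2..16 (or all components beyond the first when fewer exist) using
#' differential evolution, then normalizes the weights to unit norm and
#' canonicalizes the sign (the metric is invariant under w -> -w and, in
#' projection mode, shifts only by a constant under rescaling, so the search
#' is effectively over directions). The result is the optimized "PC 2"
#' direction used as the second axis of the 2D CV space.
#'
#' @param paths a `path_ensemble_set`
#' @param basis a `pc_basis` of the pooled frames
#' @param pcs candidate components (default 2..16, clipped to availability)
#' @param mode see [path_separation_metric()]
#' @param bounds per-weight search box
#' @param pop_factor population size = pop_factor x dimension
#' @param maxiter maximum DE generations
#' @param tol relative fitness-spread stopping tolerance
#' @param seed RNG seed for the stochastic search
#' @param eps squared-distance floor
#' @return a `weight_vector`: list with `weights` (unit norm, named by
#'   component), `pcs`, `metric` (achieved value), `mode`, `seed`
#' @export
optimize_pc2 <- function(paths, basis, pcs = NULL, mode = c("projection", "per_pc"),
                         bounds = c(-1, 1), pop_factor = 15, maxiter = 150,
                         tol = 1e-7, seed = 2024L, eps = 1e-12) {
  mode <- match.arg(mode)
  M <- .pair_projections(paths, basis, pcs)
  d <- ncol(M$delta)
  # the metric is scale-covariant (scaling w shifts it by a constant), so the
  # search is over directions: candidates are normalized inside the objective,
  # otherwise the box corners (largest attainable norm) would dominate
  fn <- function(w) {
    nrm2 <- sum(w^2)
    if (nrm2 < 1e-12) return(-Inf)
    .metric_from_projections(M$delta, w / sqrt(nrm2), M$n_reps, mode, eps)
  }
  res <- .de_maximize(fn, rep(bounds[1], d), rep(bounds[2], d),
                      np = max(4L, as.integer(pop_factor * d)),
                      maxiter = maxiter, tol = tol, seed = seed)
  # local polish of the DE winner (the standard finishing step for DE)
  pol <- stats::optim(res$par, function(w) -fn(w), method = "L-BFGS-B",
                      lower = rep(bounds[1], d), upper = rep(bounds[2], d),
                      control = list(factr = 10))
  if (-pol$value >= res$value) res$par <- pol$par
  w <- res$par / sqrt(sum(res$par^2))
  if (w[which.max(abs(w))] < 0) w <- -w  # canonical sign
  names(w) <- paste0("PC", M$pcs)
  structure(list(weights = w, pcs = M$pcs,
                 metric = fn(w), mode = mode, seed = seed,
                 iterations = res$iterations),
            class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat("<weight_vector> over", length(x$weights), "PCs; metric =",
      format(x$metric, digits = 6), "\n")
  top <- order(abs(x$weights), decreasing = TRUE)[seq_len(min(4, length(x$weights)))]
  cat("  leading weights:",
      paste(names(x$weights)[top], sprintf("%+.3f", x$weights[top]), collapse = ", "), "\n")
  invisible(x)
}

#' Project frames into the optimized 2D CV space
#'
#' Column 1 is the projection onto the first principal component (the main
#' transition coordinate); column 2 is the projection onto the optimized
#' orthogonal direction v = sum_k w_k PC_k.
#'
#' @param frames matrix (n x D) of coordinate frames
#' @param basis a `pc_basis`
#' @param pc2 a `weight_vector` from [optimize_pc2()]
#' @param times optional time stamps for the output series
#' @return a [cv_series()] with columns `pc1`, `pc2`
#' @export
project_2d <- function(frames, basis, pc2, times = NULL) {
  stopifnot(inherits(pc2, "weight_vector"))
  frames <- rbind(frames)
  if (ncol(frames) != length(basis$mean))
    stop("project_2d: frame dimensionality does not match basis")
  p1 <- project_basis(frames, basis, 1)
  v <- basis$components[, pc2$pcs, drop = FALSE] %*% pc2$weights
  p2 <- sweep(frames, 2, basis$mean) %*% v
  if (is.null(times)) times <- seq_len(nrow(frames))
  cv_series(c("pc1", "pc2"), times, cbind(p1, p2))
}

#' Serialize a basis + weights to JSON
#'
#' @param basis a `pc_basis`
#' @param pc2 a `weight_vector`
#' @param path output path
#' @export
write_cv_json <- function(basis, pc2, path) {
  jsonlite::write_json(list(
    mean = basis$mean,
    components = basis$components,
    fractions = basis$fractions,
    pcs = pc2$pcs,
    weights = as.numeric(pc2$weights),
    metric = pc2$metric,
    mode = pc2$mode,
    seed = pc2$seed
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
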