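#' Grid specification for PMF estimation
#'
#' @param ranges list of c(lo, hi) per dimension (or a single c(lo, hi) for 1D)
#' @param nbins bins per dimension (recycled). Defaults: 72 (1D), 48 x 48 (2D).
#' @export
pmf_grid_spec <- function(ranges, nbins = NULL) {
  if (!is.list(ranges)) ranges <- list(ranges)
  dim <- length(ranges)
  if (is.null(nbins)) nbins <- if (dim == 1L) 72L else 48L
  nbins <- rep_len(as.integer(nbins), dim)
  for (d in seq_len(dim)) {
    if (length(ranges[[d]]) != 2L || ranges[[d]][1] >= ranges[[d]][2])
      stop("pmf_grid_spec: each range must be c(lo, hi) with lo < hi")
    if (nbins[d] < 2L) stop("pmf_grid_spec: need at least 2 bins per dimension")
  }
  structure(list(dim = dim, ranges = ranges, nbins = nbins),
            class = "pmf_grid_spec")
}

#' Bin edges of a grid spec
#' @param grid a [pmf_grid_spec()]
#' @return list of edge vectors per dimension
#' @export
grid_edges <- function(grid) {
  lapply(seq_len(grid$dim), function(d)
    seq(grid$ranges[[d]][1], grid$ranges[[d]][2], length.out = grid$nbins[d] + 1L))
}

#' Bin centres of a grid spec
#' @param grid a [pmf_grid_spec()]
#' @return list of centre vectors per dimension
#' @export
grid_centers <- function(grid) {
  lapply(grid_edges(grid), function(e) (e[-1] + e[-length(e)]) / 2)
}

#' Binned free-energy surface
#'
#' Free energies are in kcal/mol, zeroed at the minimum over defined bins;
#' undefined bins (no samples) carry NA with +Inf semantics: they contribute
#' zero probability to any reweighting.
#'
#' @param grid the [pmf_grid_spec()] the values live on
#' @param values vector (1D) or matrix (2D) of free energies
#' @param defined logical mask of the same shape; NA values are undefined
#' @param temperature temperature, K
#' @export
pmf_grid <- function(grid, values, defined = NULL, temperature = DEFAULT_TEMPERATURE) {
  stopifnot(inherits(grid, "pmf_grid_spec"))
  values <- if (grid$dim == 1L) as.numeric(values) else as.matrix(values)
  if (is.null(defined)) defined <- is.finite(values) & !is.na(values)
  defined <- if (grid$dim == 1L) as.logical(defined) else
    matrix(as.logical(defined), nrow(values), ncol(values))
  if (!any(defined)) stop("pmf_grid: fully undefined surface")
  values[!defined] <- NA_real_
  values <- values - min(values[defined])
  structure(list(grid = grid, values = values, defined = defined,
                 temperature = temperature),
            class = "pmf_grid")
}

#' @export
print.pmf_grid <- function(x, ...) {
  cat("<pmf_grid> ", x$grid$dim, "D, ", paste(x$grid$nbins, collapse = " x "),
      " bins, ", sum(x$defined), " defined; range 0 .. ",
      format(max(x$values[x$defined]), digits = 4), " kcal/mol\n", sep = "")
  invisible(x)
}

# flat bin index per sample for a grid; NA for out-of-range samples
.bin_index <- function(x, grid) {
  edges <- grid_edges(grid)
  idx <- rep(1L, nrow(x))
  mult <- 1L
  for (d in seq_len(grid$dim)) {
    bd <- findInterval(x[, d], edges[[d]], rightmost.closed = TRUE)
    bd[bd < 1L | bd > grid$nbins[d]] <- NA_integer_
    idx <- idx + (bd - 1L) * mult
    mult <- mult * grid$nbins[d]
  }
  idx
}

# matrix of flat-bin-centre coordinates (nbins_total x dim)
.bin_points <- function(grid) {
  centers <- grid_centers(grid)
  if (grid$dim == 1L) matrix(centers[[1]], ncol = 1)
  else as.matrix(expand.grid(centers[[1]], centers[[2]]))
}

#' WHAM estimation of a PMF from pooled umbrella windows
#'
#' Self-consistent weighted-histogram solution for the unbiased probability:
#'
#'   P(bin) = sum_i n_i(bin) / sum_j N_j exp(beta (f_j - b_j(bin)))
#'   f_j = -kT ln sum_bin P(bin) exp(-beta b_j(bin))
#'
#' iterated until max |beta delta f| < `tol`. Heterogeneous force constants,
#' pooled replicates and force-constant tiers are supported natively: every
#' window enters only through its own harmonic bias. Replica-exchange
#' structure is ignored (samples are treated as window-labelled equilibrium
#' draws). Bins with zero total counts are masked undefined. The result is
#' F = -kT ln P, zeroed at its minimum over defined bins.
#'
#' @param windows list of [umbrella_window()]s (all 1D or all 2D)
#' @param grid a [pmf_grid_spec()]
#' @param temperature temperature, K
#' @param tol convergence tolerance on max |beta delta f|
#' @param max_iter iteration cap
#' @return a [pmf_grid()]; attribute `window_free_energies` carries the
#'   converged per-window f_j (kcal/mol)
#' @export
wham <- function(windows, grid, temperature = DEFAULT_TEMPERATURE,
                 tol = 1e-7, max_iter = 1e5) {
  stopifnot(length(windows) >= 1L, inherits(grid, "pmf_grid_spec"))
  kT <- kT_kcal(temperature)
  nb <- prod(grid$nbins)
  nw <- length(windows)
  counts <- matrix(0, nw, nb)
  for (j in seq_len(nw)) {
    w <- windows[[j]]
    stopifnot(inherits(w, "umbrella_window"))
    if (ncol(w$samples$values) != grid$dim)
      stop("wham: window dimensionality does not match grid")
    idx <- .bin_index(w$samples$values, grid)
    idx <- idx[!is.na(idx)]
    if (length(idx)) counts[j, ] <- tabulate(idx, nbins = nb)
  }
  N <- rowSums(counts)
  if (any(N == 0))
    warning("wham: window(s) ", paste(which(N == 0), collapse = ", "),
            " contribute no in-range samples")
  C_tot <- colSums(counts)
  defined <- C_tot > 0
  if (!any(defined)) stop("wham: no samples fall inside the grid")
  .warn_disconnected(counts)
  pts <- .bin_points(grid)
  B <- t(vapply(windows, function(w) bias_energy(w$bias, pts), numeric(nb)))
  B <- matrix(B, nw, nb)
  expB <- exp(-B / kT)
  f <- rep(0, nw)
  C_def <- C_tot[defined]
  expB_def <- expB[, defined, drop = FALSE]
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    denom <- as.numeric(crossprod(expB_def, N * exp(f / kT)))
    P <- C_def / denom
    P <- P / sum(P)
    z <- as.numeric(expB_def %*% P)
    f_new <- -kT * log(z)
    f_new <- f_new - f_new[1]
    delta <- max(abs(f_new - f)) / kT
    f <- f_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop("wham: not converged after ", max_iter,
         " iterations (residual max|beta df| = ", format(delta, digits = 3), ")")
  F_def <- -kT * log(P)
  vals <- rep(NA_real_, nb)
  vals[defined] <- F_def - min(F_def)
  if (grid$dim == 2L) {
    vals <- matrix(vals, grid$nbins[1], grid$nbins[2])
    defined <- matrix(defined, grid$nbins[1], grid$nbins[2])
  }
  out <- pmf_grid(grid, vals, defined, temperature)
  attr(out, "window_free_energies") <- f
  attr(out, "iterations") <- it
  out
}

# warn if window histograms form disconnected components (WHAM can only pin
# relative offsets within a connected component)
.warn_disconnected <- function(counts) {
  nw <- nrow(counts)
  if (nw < 2L) return(invisible())
  occ <- counts > 0
  adj <- occ %*% t(occ) > 0
  comp <- rep(0L, nw)
  cur <- 0L
  for (s in seq_len(nw)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] != 0L) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  if (cur > 1L) {
    groups <- split(seq_len(nw), comp)
    warning("wham: window histograms form ", cur, " disconnected components: ",
            paste(vapply(groups, function(g) paste0("{", paste(g, collapse = ","), "}"),
                         ""), collapse = " "))
  }
  invisible()
}

#' Boltzmann-reweighted projection of a 2D PMF onto one axis
#'
#' F1(x) = -kT ln sum_y exp(-beta F2(x, y)) dy over defined bins. Columns with
#' no defined bins are undefined; the result is zeroed at its minimum.
#'
#' @param pmf2d a 2D [pmf_grid()]
#' @param axis which axis to keep (1 or 2)
#' @return a 1D [pmf_grid()]
#' @export
project_pmf <- function(pmf2d, axis = 1) {
  stopifnot(inherits(pmf2d, "pmf_grid"), pmf2d$grid$dim == 2L, axis %in% 1:2)
  kT <- kT_kcal(pmf2d$temperature)
  vals <- pmf2d$values
  def <- pmf2d$defined
  if (axis == 2L) { vals <- t(vals); def <- t(def) }
  edges_other <- grid_edges(pmf2d$grid)[[if (axis == 1L) 2L else 1L]]
  dy <- diff(edges_other)[1]
  n1 <- nrow(vals)
  f1 <- rep(NA_real_, n1)
  for (i in seq_len(n1)) {
    ok <- def[i, ]
    if (!any(ok)) next
    v <- vals[i, ok]
    v0 <- min(v)
    f1[i] <- v0 - kT * log(sum(exp(-(v - v0) / kT)) * dy)
  }
  keep_grid <- pmf_grid_spec(pmf2d$grid$ranges[[axis]], pmf2d$grid$nbins[axis])
  pmf_grid(keep_grid, f1, !is.na(f1), pmf2d$temperature)
}

#' Align a 1D PMF to a reference
#'
#' PMFs are defined only up to additive constants; alignment fixes the
#' constant. In curve mode the shift minimizes the squared deviation from a
#' reference PMF over co-defined bins (i.e. the mean difference over the
#' overlap). In state mode the mean over an explicit CV region is zeroed.
#'
#' @param pmf a 1D [pmf_grid()]
#' @param reference a 1D [pmf_grid()] on the same grid (curve mode), or
#'   `NULL` with `region` set (state mode)
#' @param region c(lo, hi) CV interval whose mean is zeroed in state mode
#' @return the shifted [pmf_grid()]; attribute `shift` carries the constant.
#'   Note the values are NOT re-zeroed at the minimum, so the alignment is
#'   preserved.
#' @export
align_pmf <- function(pmf, reference = NULL, region = NULL) {
  stopifnot(inherits(pmf, "pmf_grid"), pmf$grid$dim == 1L)
  x <- grid_centers(pmf$grid)[[1]]
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "pmf_grid"), reference$grid$dim == 1L)
    if (!isTRUE(all.equal(grid_centers(reference$grid)[[1]], x)))
      stop("align_pmf: reference grid does not match")
    both <- pmf$defined & reference$defined
    if (!any(both)) stop("align_pmf: no co-defined bins to align on")
    shift <- mean(reference$values[both] - pmf$values[both])
  } else if (!is.null(region)) {
    sel <- pmf$defined & x >= region[1] & x <= region[2]
    if (!any(sel)) stop("align_pmf: no defined bins in alignment region")
    shift <- -mean(pmf$values[sel])
  } else {
    stop("align_pmf: provide a reference PMF or a region")
  }
  out <- pmf
  out$values <- pmf$values + shift
  attr(out, "shift") <- shift
  out
}

# truncate every window's time series to a sampling fraction
.truncate_windows <- function(windows, fraction = c("first40", "last40", "full")) {
  fraction <- match.arg(fraction)
  if (fraction == "full") return(windows)
  lapply(windows, function(w) {
    n <- n_samples(w$samples)
    keep <- if (fraction == "first40") seq_len(max(1L, floor(0.4 * n)))
            else seq(n - max(1L, floor(0.4 * n)) + 1L, n)
    if (length(keep) == 0L) stop("convergence_band: fraction yields empty window")
    w$samples <- cv_series(w$samples$labels, w$samples$times[keep],
                           w$samples$values[keep, , drop = FALSE])
    w
  })
}

#' Sampling-fraction convergence band of a projected PMF
#'
#' Recomputes the full pipeline (WHAM, then optional projection to 1D, then
#' alignment to the 100% curve) with the first 40%, the last 40% and 100% of
#' each window's samples, and reports the per-bin min/max envelope across the
#' three. A narrow band indicates stationary, converged sampling.
#'
#' @param windows list of [umbrella_window()]s
#' @param grid [pmf_grid_spec()] passed to [wham()]
#' @param axis projection axis when windows are 2D; ignored for 1D
#' @param temperature,tol,max_iter passed to [wham()]
#' @return a `convergence_band`: list with `centers`, `lower`, `upper`,
#'   `curves` (named list of the three aligned 1D PMFs), `median_width`
#' @export
convergence_band <- function(windows, grid, axis = 1,
                             temperature = DEFAULT_TEMPERATURE,
                             tol = 1e-7, max_iter = 1e5) {
  run <- function(fraction) {
    p <- wham(.truncate_windows(windows, fraction), grid, temperature, tol, max_iter)
    if (p$grid$dim == 2L) p <- project_pmf(p, axis) else p
  }
  full <- run("full")
  first40 <- align_pmf(run("first40"), reference = full)
  last40 <- align_pmf(run("last40"), reference = full)
  centers <- grid_centers(full$grid)[[1]]
  stack <- rbind(full$values, first40$values, last40$values)
  lower <- suppressWarnings(apply(stack, 2, min, na.rm = TRUE))
  upper <- suppressWarnings(apply(stack, 2, max, na.rm = TRUE))
  lower[!is.finite(lower)] <- NA_real_
  upper[!is.finite(upper)] <- NA_real_
  width <- upper - lower
  structure(list(centers = centers, lower = lower, upper = upper,
                 curves = list(full = full, first40 = first40, last40 = last40),
                 median_width = stats::median(width, na.rm = TRUE)),
            class = "convergence_band")
}

#' @export
print.convergence_band <- function(x, ...) {
  cat("<convergence_band> median width",
      format(x$median_width, digits = 3), "kcal/mol over",
      sum(!is.na(x$lower)), "bins\n")
  invisible(x)
}

# centred moving average with window length k (odd), edges shrink
.smooth_profile <- function(v, k) {
  if (k <= 1L) return(v)
  n <- length(v)
  half <- floor(k / 2)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(v[lo:hi], na.rm = TRUE)
  }, 0)
}

#' Basin and barrier readout of a 1D PMF
#'
#' Finds local minima of the (optionally smoothed) profile over defined bins
#' and, between each pair of adjacent minima, the intervening maximum. Basin
#' free energies are reported relative to the global minimum; barriers are
#' reported relative to each of the two flanking basins.
#'
#' @param pmf a 1D [pmf_grid()]
#' @param smoothing moving-average window length in bins (1 = none)
#' @param min_prominence discard shallow minima: while any adjacent pair of
#'   minima is separated by a barrier smaller than this (relative to the
#'   shallower of the two), the shallower one is removed. 0 keeps all local
#'   minima, including sampling-noise wiggles at sparse edges.
#' @return list with `minima` (data.frame: position, value) and `barriers`
#'   (data.frame: saddle position/value, barrier_from_left, barrier_from_right,
#'   delta_g = right basin minus left basin). A monotone profile yields an
#'   empty report with a note attribute.
#' @export
basin_barrier_report <- function(pmf, smoothing = 1L, min_prominence = 0) {
  stopifnot(inherits(pmf, "pmf_grid"), pmf$grid$dim == 1L)
  x <- grid_centers(pmf$grid)[[1]]
  ok <- pmf$defined
  v <- .smooth_profile(pmf$values, smoothing)
  xs <- x[ok]; vs <- v[ok]
  n <- length(vs)
  is_min <- logical(n)
  # interior minima only: a monotone profile's boundary bin is not a basin
  for (i in seq_len(n)[-c(1, n)])
    is_min[i] <- vs[i] < vs[i - 1] && vs[i] < vs[i + 1]
  mins <- which(is_min)
  # prune shallow minima by pairwise prominence
  while (min_prominence > 0 && length(mins) > 1L) {
    rel <- vapply(seq_len(length(mins) - 1L), function(b) {
      seg <- seq(mins[b], mins[b + 1])
      max(vs[seg]) - max(vs[mins[b]], vs[mins[b + 1]])
    }, 0)
    worst <- which.min(rel)
    if (rel[worst] >= min_prominence) break
    drop <- if (vs[mins[worst]] > vs[mins[worst + 1]]) worst else worst + 1L
    mins <- mins[-drop]
  }
  if (length(mins) == 0L) {
    out <- list(minima = data.frame(position = numeric(0), value = numeric(0)),
                barriers = data.frame())
    attr(out, "note") <- "monotone or flat profile: no interior minima"
    return(out)
  }
  minima <- data.frame(position = xs[mins], value = vs[mins])
  barriers <- NULL
  if (length(mins) > 1L) {
    barriers <- do.call(rbind, lapply(seq_len(length(mins) - 1L), function(b) {
      seg <- seq(mins[b], mins[b + 1])
      top <- seg[which.max(vs[seg])]
      data.frame(
        saddle_position = xs[top], saddle_value = vs[top],
        barrier_from_left = vs[top] - vs[mins[b]],
        barrier_from_right = vs[top] - vs[mins[b + 1]],
        delta_g = vs[mins[b + 1]] - vs[mins[b]])
    }))
  } else barriers <- data.frame()
  list(minima = minima, barriers = barriers)
}

#' RMSD between a PMF and a reference over co-defined bins
#'
#' Both curves/surfaces are first shifted to their least-squares-optimal
#' offset (PMFs are defined up to constants), then the root-mean-square
#' deviation is taken over co-defined bins.
#'
#' @param pmf,reference [pmf_grid()]s on the same grid
#' @return RMSD in kcal/mol
#' @export
pmf_rmsd <- function(pmf, reference) {
  stopifnot(inherits(pmf, "pmf_grid"), inherits(reference, "pmf_grid"))
  both <- pmf$defined & reference$defined
  if (!any(both)) stop("pmf_rmsd: no co-defined bins")
  d <- pmf$values[both] - reference$values[both]
  d <- d - mean(d)
  sqrt(mean(d^2))
}

#' Write a PMF as a CSV table of bin centres and values
#'
#' @param pmf a [pmf_grid()]
#' @param path output path
#' @export
write_pmf_csv <- function(pmf, path) {
  centers <- grid_centers(pmf$grid)
  if (pmf$grid$dim == 1L) {
    df <- data.frame(cv1 = centers[[1]], free_energy = pmf$values,
                     defined = pmf$defined)
  } else {
    g <- expand.grid(cv1 = centers[[1]], cv2 = centers[[2]])
    df <- data.frame(g, free_energy = as.numeric(pmf$values),
                     defined = as.logical(pmf$defined))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
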