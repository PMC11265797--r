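#' Analytic potential surfaces for synthetic sampling
#'
#' Three named families are available, all with energies in kcal/mol and CV
#' coordinates in nm-like units:
#'
#' * `harmonic`: U(x) = 1/2 sum_d k_d (x_d - c_d)^2
#' * `double_well` (1D): U(x) = h ((x/a)^2 - 1)^2 with minima at +-a and a
#'   barrier of height h at x = 0
#' * `gaussian_basin_mixture`: a sum of negative Gaussian wells plus a weak
#'   harmonic confinement, U(x) = -sum_b A_b exp(-|x-mu_b|^2 / (2 sigma_b^2))
#'   + 1/2 k_c |x - c0|^2
#'
#' @name potential_surface
NULL

.surface <- function(form, dim, params) {
  structure(list(form = form, dim = dim, params = params),
            class = "potential_surface")
}

#' @export
print.potential_surface <- function(x, ...) {
  cat("<potential_surface> family:", x$form, " dim:", x$dim, "\n")
  invisible(x)
}

#' Harmonic potential surface
#' @param center minimum position (length = dimensionality)
#' @param k per-dimension force constants, kcal/mol/unit^2
#' @export
harmonic_surface <- function(center, k) {
  center <- as.numeric(center); k <- as.numeric(k)
  if (length(k) == 1L) k <- rep(k, length(center))
  stopifnot(length(k) == length(center), all(k >= 0), all(is.finite(center)))
  .surface("harmonic", length(center), list(center = center, k = k))
}

#' Symmetric quartic double-well surface (1D)
#' @param barrier barrier height h at x = 0, kcal/mol
#' @param half_width position a of the two minima (at +-a)
#' @export
double_well_surface <- function(barrier, half_width) {
  stopifnot(barrier > 0, half_width > 0)
  .surface("double_well", 1L, list(h = barrier, a = half_width))
}

#' Mixture-of-Gaussian-basins surface with harmonic confinement
#' @param centers matrix of basin centres, one row per basin
#' @param depths well depths A_b > 0, kcal/mol
#' @param widths per-basin Gaussian sigma
#' @param confine_k confinement force constant, kcal/mol/unit^2
#' @param confine_center confinement centre (defaults to the origin)
#' @export
gaussian_basin_surface <- function(centers, depths, widths,
                                   confine_k = 0, confine_center = NULL) {
  centers <- rbind(centers)
  nb <- nrow(centers)
  if (length(widths) == 1L) widths <- rep(widths, nb)
  stopifnot(length(depths) == nb, length(widths) == nb,
            all(depths > 0), all(widths > 0), confine_k >= 0)
  if (is.null(confine_center)) confine_center <- rep(0, ncol(centers))
  .surface("gaussian_basin_mixture", ncol(centers),
           list(centers = centers, depths = as.numeric(depths),
                widths = as.numeric(widths), confine_k = confine_k,
                confine_center = as.numeric(confine_center)))
}

#' Stock three-basin "transporter" surface
#'
#' A 2D fixture mimicking the scale of conformational landscapes of an
#' alternating-access transporter: three basins along the first CV (think
#' OF / OCC / IF) with free-energy offsets of roughly 0, +3 and +2 kcal/mol
#' and barriers of a few kcal/mol, plus a weak confinement that makes the
#' Boltzmann density normalizable. These defaults are fixtures with known
#' ground truth, not claims about any real protein.
#'
#' @return a 2D [gaussian_basin_surface()]
#' @export
stock_transporter_surface <- function() {
  gaussian_basin_surface(
    centers = rbind(c(-1, 0), c(0, 0), c(1, 0)),
    depths = c(6, 3, 4),
    widths = c(0.22, 0.22, 0.22),
    confine_k = 1.5,
    confine_center = c(0, 0)
  )
}

#' Evaluate a potential surface
#' @param surface a `potential_surface`
#' @param x a point (vector) or matrix of points (one row per point)
#' @return energies in kcal/mol (one per point)
#' @export
surface_energy <- function(surface, x) {
  stopifnot(inherits(surface, "potential_surface"))
  x <- if (is.matrix(x)) x else matrix(x, ncol = surface$dim)
  stopifnot(ncol(x) == surface$dim)
  p <- surface$params
  switch(surface$form,
    harmonic = {
      dx <- sweep(x, 2, p$center)
      0.5 * as.numeric(dx^2 %*% p$k)
    },
    double_well = {
      z <- (x[, 1] / p$a)^2 - 1
      p$h * z^2
    },
    gaussian_basin_mixture = {
      u <- rep(0, nrow(x))
      for (b in seq_len(nrow(p$centers))) {
        r2 <- rowSums(sweep(x, 2, p$centers[b, ])^2)
        u <- u - p$depths[b] * exp(-r2 / (2 * p$widths[b]^2))
      }
      u + 0.5 * p$confine_k * rowSums(sweep(x, 2, p$confine_center)^2)
    },
    stop("unknown surface family: ", surface$form)
  )
}

#' Gradient of a potential surface
#' @inheritParams surface_energy
#' @return matrix of gradients, one row per point
#' @export
surface_gradient <- function(surface, x) {
  stopifnot(inherits(surface, "potential_surface"))
  x <- if (is.matrix(x)) x else matrix(x, ncol = surface$dim)
  p <- surface$params
  switch(surface$form,
    harmonic = sweep(sweep(x, 2, p$center), 2, p$k, `*`),
    double_well = {
      g <- 4 * p$h * x[, 1] * (x[, 1]^2 - p$a^2) / p$a^4
      matrix(g, ncol = 1)
    },
    gaussian_basin_mixture = {
      g <- matrix(0, nrow(x), ncol(x))
      for (b in seq_len(nrow(p$centers))) {
        dx <- sweep(x, 2, p$centers[b, ])
        w2 <- p$widths[b]^2
        e <- p$depths[b] * exp(-rowSums(dx^2) / (2 * w2)) / w2
        g <- g + dx * e
      }
      g + p$confine_k * sweep(x, 2, p$confine_center)
    },
    stop("unknown surface family: ", surface$form)
  )
}

# pack a surface into the (family-code, parameter-vector) form the C++
# sampler consumes
.pack_surface <- function(surface) {
  p <- surface$params
  switch(surface$form,
    harmonic = list(code = 1L, par = c(surface$dim, p$center, p$k)),
    double_well = list(code = 2L, par = c(p$h, p$a)),
    gaussian_basin_mixture = list(
      code = 3L,
      par = c(surface$dim, nrow(p$centers), as.numeric(t(p$centers)),
              p$depths, p$widths, p$confine_k, p$confine_center)),
    stop("unknown surface family: ", surface$form)
  )
}

#' Exact (reference) PMF of a surface on a grid
#'
#' Computes F = -kT ln p on the bin centres of a grid, either the full
#' surface restricted to the grid (`marginal = NULL`) or, for 2D surfaces,
#' the exact Boltzmann marginal along one axis obtained by fine-grained
#' numerical integration over the other. Used as the ground-truth oracle for
#' WHAM recovery tests; zeroed at its minimum.
#'
#' @param surface a `potential_surface`
#' @param grid a [pmf_grid_spec()]
#' @param temperature temperature in K
#' @param marginal `NULL`, or the axis (1 or 2) to keep when marginalizing a
#'   2D surface
#' @param n_quad number of quadrature points per integrated dimension
#' @return a [pmf_grid()] of the reference free energy
#' @export
exact_pmf <- function(surface, grid, temperature = DEFAULT_TEMPERATURE,
                      marginal = NULL, n_quad = 2001) {
  kT <- kT_kcal(temperature)
  centers <- grid_centers(grid)
  if (is.null(marginal)) {
    pts <- if (grid$dim == 1L) matrix(centers[[1]], ncol = 1) else
      as.matrix(expand.grid(centers[[1]], centers[[2]]))
    f <- surface_energy(surface, pts)
    vals <- if (grid$dim == 1L) f else matrix(f, length(centers[[1]]), length(centers[[2]]))
    return(pmf_grid(grid, vals - min(vals), defined = array(TRUE, dim(as.array(vals))),
                    temperature = temperature))
  }
  stopifnot(surface$dim == 2L, marginal %in% 1:2, grid$dim == 1L)
  # integrate out the other axis on a wide fine grid
  other_range <- c(-6, 6)
  y <- seq(other_range[1], other_range[2], length.out = n_quad)
  dy <- y[2] - y[1]
  x <- centers[[1]]
  f1 <- vapply(x, function(xi) {
    pts <- if (marginal == 1L) cbind(xi, y) else cbind(y, xi)
    u <- surface_energy(surface, pts)
    u0 <- min(u)
    -kT * (log(sum(exp(-(u - u0) / kT)) * dy) - u0 / kT)
  }, 0)
  pmf_grid(grid, f1 - min(f1), defined = rep(TRUE, length(f1)),
           temperature = temperature)
}
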