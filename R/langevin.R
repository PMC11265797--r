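#' Parameters for the overdamped Langevin sampler
#'
#' The sampler replaces an MD engine for synthetic-data purposes: it draws
#' equilibrium samples of CV-space coordinates from exp(-beta U) by Brownian
#' dynamics. `timestep` is in ps, `friction` in 1/ps (with unit effective
#' mass, so the diffusion constant is D = kT / friction), `temperature` in K.
#' The first `burn_frac` of steps is discarded.
#'
#' @param timestep integration step, ps
#' @param friction friction coefficient, 1/ps
#' @param temperature temperature, K
#' @param n_steps number of integration steps
#' @param stride keep every `stride`-th step
#' @param seed RNG seed (integer); all randomness flows through R's RNG
#' @param burn_frac fraction of initial steps discarded as burn-in
#' @param max_step stability threshold on a single displacement
#' @export
langevin_params <- function(timestep = 0.004, friction = 1, temperature = DEFAULT_TEMPERATURE,
                            n_steps = 100000L, stride = 10L, seed = 1L,
                            burn_frac = 0.1, max_step = 1.0) {
  stopifnot(timestep > 0, friction > 0, temperature > 0, n_steps >= 1,
            stride >= 1, burn_frac >= 0, burn_frac < 1, max_step > 0)
  structure(list(timestep = timestep, friction = friction,
                 temperature = temperature, n_steps = as.integer(n_steps),
                 stride = as.integer(stride), seed = as.integer(seed),
                 burn_frac = burn_frac, max_step = max_step),
            class = "langevin_params")
}

#' Harmonic bias specification for an umbrella window
#'
#' @param center bias centre in CV space
#' @param k per-dimension force constants. Supplied in kJ/mol/unit^2 by
#'   default (the MD-engine convention) and converted internally to kcal;
#'   set `units = "kcal"` to pass kcal/mol/unit^2 directly.
#' @param units `"kJ"` (default) or `"kcal"`
#' @export
bias_spec <- function(center, k, units = c("kJ", "kcal")) {
  units <- match.arg(units)
  center <- as.numeric(center); k <- as.numeric(k)
  if (length(k) == 1L) k <- rep(k, length(center))
  stopifnot(length(k) == length(center), all(k >= 0), all(is.finite(center)))
  if (units == "kJ") k <- kj_to_kcal(k)
  structure(list(center = center, k = k), class = "bias_spec")
}

#' Energy of a harmonic bias at given points
#' @param bias a [bias_spec()]
#' @param x point or matrix of points
#' @return bias energies, kcal/mol
#' @export
bias_energy <- function(bias, x) {
  x <- if (is.matrix(x)) x else matrix(x, ncol = length(bias$center))
  dx <- sweep(x, 2, bias$center)
  0.5 * as.numeric(dx^2 %*% bias$k)
}

#' Sample a potential surface by overdamped Langevin dynamics
#'
#' Brownian-dynamics update x <- x - D beta grad(U + bias) dt + sqrt(2 D dt) xi
#' with D = kT / friction (unit effective mass). Equilibrium-sampling stand-in
#' for biased MD: the strided output is distributed as exp(-beta (U + bias))
#' once equilibrated. Reproducible by seed.
#'
#' @param surface a `potential_surface`
#' @param bias a [bias_spec()] or `NULL` for unbiased sampling
#' @param params a [langevin_params()]
#' @param start starting point in CV space
#' @param labels CV labels for the output series
#' @return a [cv_series()] of strided post-burn-in samples
#' @export
langevin_sample <- function(surface, bias = NULL, params = langevin_params(),
                            start = NULL, labels = NULL) {
  stopifnot(inherits(surface, "potential_surface"), inherits(params, "langevin_params"))
  d <- surface$dim
  if (is.null(start)) start <- if (!is.null(bias)) bias$center else rep(0, d)
  stopifnot(length(start) == d, all(is.finite(surface_energy(surface, start))))
  if (!is.null(bias)) stopifnot(inherits(bias, "bias_spec"), length(bias$center) == d)
  if (is.null(labels)) labels <- paste0("cv", seq_len(d))
  kT <- kT_kcal(params$temperature)
  packed <- .pack_surface(surface)
  set.seed(params$seed)
  mat <- .langevin_run_cpp(
    packed$code, packed$par, d, as.numeric(start),
    if (is.null(bias)) numeric(0) else bias$center,
    if (is.null(bias)) numeric(0) else bias$k,
    params$timestep, kT / params$friction, 1 / kT,
    params$n_steps, params$stride, params$max_step
  )
  keep <- seq_len(nrow(mat)) > floor(params$burn_frac * nrow(mat))
  mat <- mat[keep, , drop = FALSE]
  if (nrow(mat) == 0L) stop("langevin_sample: no samples after burn-in")
  times <- params$timestep * params$stride * seq_len(nrow(mat))
  cv_series(labels, times, mat)
}

#' One umbrella window: samples plus their bias
#'
#' @param samples a [cv_series()]
#' @param bias the [bias_spec()] under which the samples were drawn
#' @param replicate replicate label
#' @param tier force-constant tier label
#' @export
umbrella_window <- function(samples, bias, replicate = "rep1", tier = "tier1") {
  stopifnot(inherits(samples, "cv_series"), inherits(bias, "bias_spec"))
  if (ncol(samples$values) != length(bias$center))
    stop("umbrella_window: sample dimensionality does not match bias dimensionality")
  structure(list(samples = samples, bias = bias,
                 replicate = replicate, tier = tier),
            class = "umbrella_window")
}

#' Generate a full umbrella-sampling campaign on a synthetic surface
#'
#' Runs one biased Langevin simulation per (centre, force-constant tier,
#' replicate). Passing two tiers of force constants at every centre mirrors
#' the pooled two-tier REUS design in which softer windows provide broad
#' basin coverage and stiffer windows bridge transition regions; 24 centres x
#' 2 tiers x 3 replicates gives the canonical 144-window campaign.
#'
#' @param surface a `potential_surface`
#' @param centres matrix of window centres (one row per centre) or vector for 1D
#' @param force_constants list of per-tier force constants (each in
#'   kJ/mol/unit^2, scalar or per-dimension)
#' @param params a [langevin_params()], or a list with one [langevin_params()]
#'   per tier (stiffer tiers need smaller timesteps for the Euler-Maruyama
#'   update to stay accurate); per-window seeds are derived from the seed of
#'   the first entry
#' @param n_replicates number of replicates
#' @param replicate_offsets optional matrix (n_replicates x dim) of CV-space
#'   offsets added to every window centre of the corresponding replicate,
#'   emulating replicate transition paths that are displaced along an
#'   orthogonal degree of freedom
#' @return list of [umbrella_window()]s
#' @export
make_umbrella_campaign <- function(surface, centres, force_constants,
                                   params = langevin_params(), n_replicates = 1L,
                                   replicate_offsets = NULL) {
  centres <- if (is.matrix(centres)) centres else matrix(centres, ncol = surface$dim)
  if (nrow(centres) == 0L) stop("make_umbrella_campaign: centres must be nonempty")
  if (is.null(replicate_offsets))
    replicate_offsets <- matrix(0, n_replicates, surface$dim)
  replicate_offsets <- rbind(replicate_offsets)
  stopifnot(nrow(replicate_offsets) == n_replicates,
            ncol(replicate_offsets) == surface$dim)
  if (!is.list(force_constants)) force_constants <- list(force_constants)
  tier_params <- if (inherits(params, "langevin_params"))
    rep(list(params), length(force_constants)) else params
  if (length(tier_params) != length(force_constants))
    stop("make_umbrella_campaign: need one langevin_params per tier")
  base_seed <- tier_params[[1]]$seed
  windows <- vector("list", nrow(centres) * length(force_constants) * n_replicates)
  idx <- 0L
  for (r in seq_len(n_replicates)) {
    for (t in seq_along(force_constants)) {
      for (ci in seq_len(nrow(centres))) {
        idx <- idx + 1L
        ctr <- centres[ci, ] + replicate_offsets[r, ]
        b <- bias_spec(ctr, force_constants[[t]])
        p <- tier_params[[t]]
        p$seed <- base_seed + 7919L * idx  # distinct stream per window
        windows[[idx]] <- umbrella_window(
          langevin_sample(surface, bias = b, params = p, start = ctr),
          bias = b, replicate = paste0("rep", r), tier = paste0("tier", t))
      }
    }
  }
  windows
}
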