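#' Synthetic per-pH protonation traces with prescribed pKa
#'
#' Generates, for each pH replica, a binary protonation trace from a two-state
#' Markov chain whose stationary deprotonated fraction follows the
#' Henderson-Hasselbalch curve 1 / (1 + 10^(hill (pKa - pH))) and whose
#' per-step autocorrelation decays as exp(-1/correlation_time). This emulates
#' the protonation-state output of constant-pH MD with pH replica windows.
#'
#' @param true_pka ground-truth pKa
#' @param hill Hill coefficient of the generating curve
#' @param pH_values pH of each replica window (default 0..7)
#' @param n_frames frames per trace
#' @param correlation_time autocorrelation time in frames
#' @param frame_period_ns time between frames, ns
#' @param residue residue label
#' @param seed RNG seed
#' @return a [protonation_series()] (trace value 1 = protonated)
#' @export
make_titration_data <- function(true_pka, hill = 1, pH_values = 0:7,
                                n_frames = 10000L, correlation_time = 1,
                                frame_period_ns = 0.01, residue = "E56",
                                seed = 1L) {
  stopifnot(n_frames > 0, correlation_time > 0, hill > 0)
  if (correlation_time >= n_frames)
    warning("make_titration_data: correlation_time >= n_frames; fits will be unstable")
  lambda <- exp(-1 / correlation_time)
  set.seed(seed)
  traces <- lapply(pH_values, function(ph) {
    f_deprot <- 1 / (1 + 10^(hill * (true_pka - ph)))
    .two_state_chain_cpp(as.integer(n_frames), 1 - f_deprot, lambda)
  })
  protonation_series(residue, pH_values, traces, frame_period_ns)
}

#' Replicate path ensembles with a planted separating direction
#'
#' Builds `n_reps` copies of a base path through coordinate space that differ
#' by distinct offsets along a single (unit) direction, plus isotropic
#' Gaussian noise. This reproduces the statistical structure assumed by the
#' orthogonal-CV optimizer: replicates of a morphing path that agree along
#' the main transition coordinate but are displaced along one orthogonal
#' degree of freedom. The planted direction is stored as ground truth.
#'
#' @param n_reps number of replicates (>= 2)
#' @param n_windows frames per path
#' @param base_path matrix (n_windows x D) of base-path coordinates
#' @param separation_direction direction of inter-replicate displacement
#'   (normalized internally)
#' @param separation_scale half-spread of replicate offsets along the direction
#' @param noise isotropic Gaussian noise sd added to every coordinate
#' @param seed RNG seed
#' @return a `path_ensemble_set`: list with `frames` (array n_windows x
#'   n_reps x D), `n_reps`, `n_windows`, `truth` (unit direction)
#' @export
make_path_ensembles <- function(n_reps, n_windows, base_path,
                                separation_direction, separation_scale = 1,
                                noise = 0, seed = 1L) {
  stopifnot(n_reps >= 2)
  base_path <- rbind(base_path)
  stopifnot(nrow(base_path) == n_windows)
  dvec <- as.numeric(separation_direction)
  nrm <- sqrt(sum(dvec^2))
  if (nrm == 0) stop("make_path_ensembles: zero separation direction")
  dvec <- dvec / nrm
  stopifnot(length(dvec) == ncol(base_path))
  offsets <- separation_scale * seq(-1, 1, length.out = n_reps)
  set.seed(seed)
  D <- ncol(base_path)
  frames <- array(0, dim = c(n_windows, n_reps, D))
  for (r in seq_len(n_reps)) {
    shifted <- base_path + matrix(offsets[r] * dvec, n_windows, D, byrow = TRUE)
    if (noise > 0) shifted <- shifted + matrix(rnorm(n_windows * D, sd = noise),
                                               n_windows, D)
    frames[, r, ] <- shifted
  }
  structure(list(frames = frames, n_reps = n_reps, n_windows = n_windows,
                 truth = dvec, offsets = offsets),
            class = "path_ensemble_set")
}

#' Flatten a path ensemble into a frame matrix
#'
#' @param paths a `path_ensemble_set`
#' @return matrix ((n_windows * n_reps) x D), windows fastest
#' @export
path_frames <- function(paths) {
  stopifnot(inherits(paths, "path_ensemble_set"))
  d <- dim(paths$frames)
  matrix(aperm(paths$frames, c(1, 2, 3)), d[1] * d[2], d[3])
}

#' Gaussian forward/reverse work samples with planted free energy
#'
#' Draws forward work W_F ~ N(dG + beta sigma^2 / 2, sigma^2) and reverse work
#' (for the reverse process) W_R ~ N(-dG + beta sigma^2 / 2, sigma^2), the
#' unique Gaussian pair satisfying the Crooks fluctuation relation with target
#' free-energy difference `dG_true`. As sigma -> 0 all work values equal
#' `dG_true`.
#'
#' @param dG_true planted free-energy difference, kcal/mol
#' @param sigma_w work sd, kcal/mol
#' @param n samples per direction (>= 2)
#' @param temperature temperature, K
#' @param seed RNG seed
#' @return a [work_samples()]
#' @export
make_alchemical_samples <- function(dG_true, sigma_w, n, temperature = DEFAULT_TEMPERATURE,
                                    seed = 1L) {
  if (n < 2) stop("make_alchemical_samples: need n >= 2")
  stopifnot(sigma_w >= 0)
  beta <- 1 / kT_kcal(temperature)
  set.seed(seed)
  wf <- rnorm(n, mean = dG_true + beta * sigma_w^2 / 2, sd = sigma_w)
  wr <- rnorm(n, mean = -dG_true + beta * sigma_w^2 / 2, sd = sigma_w)
  work_samples(forward = wf, reverse = wr, temperature = temperature)
}
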