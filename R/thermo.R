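#' Forward/reverse work samples for one alchemical interval
#'
#' @param forward work values of the forward process, kcal/mol
#' @param reverse work values of the reverse process (work to go back),
#'   kcal/mol; may be empty (exponential-averaging fallback)
#' @param temperature temperature, K
#' @export
work_samples <- function(forward = numeric(0), reverse = numeric(0),
                         temperature = DEFAULT_TEMPERATURE) {
  forward <- as.numeric(forward); reverse <- as.numeric(reverse)
  if (length(forward) == 0L && length(reverse) == 0L)
    stop("work_samples: at least one direction must be nonempty")
  structure(list(forward = forward, reverse = reverse, temperature = temperature),
            class = "work_samples")
}

#' Bennett acceptance ratio free-energy estimate
#'
#' Self-consistent Bennett solution for the free-energy difference from
#' forward and reverse work samples, with the analytic (asymptotic) Bennett
#' variance. With only one direction available, falls back to exponential
#' averaging (Zwanzig) with a warning and a bootstrap-free crude SEM.
#'
#' Sign conventions: `forward` holds work for the A -> B process; `reverse`
#' holds work for B -> A; the estimate is dG = G(B) - G(A).
#'
#' @param samples a [work_samples()]
#' @return list with `dG` and `sd`, kcal/mol
#' @export
bar_estimate <- function(samples) {
  stopifnot(inherits(samples, "work_samples"))
  kT <- kT_kcal(samples$temperature)
  wf <- samples$forward; wr <- samples$reverse
  if (length(wf) == 0L || length(wr) == 0L) {
    warning("bar_estimate: one direction empty; falling back to exponential averaging")
    w <- if (length(wf)) wf else -wr
    x <- exp(-(w - min(w)) / kT)
    dG <- min(w) - kT * log(mean(x))
    sem <- kT * stats::sd(x) / (mean(x) * sqrt(length(x)))
    return(list(dG = dG, sd = sem))
  }
  nf <- length(wf); nr <- length(wr)
  M <- log(nf / nr)
  h <- function(dG) {
    sum(1 / (1 + exp(M + (wf - dG) / kT))) -
      sum(1 / (1 + exp(-M + (wr + dG) / kT)))
  }
  span <- range(c(wf, -wr))
  lo <- span[1] - 50 * kT; hi <- span[2] + 50 * kT
  if (!is.finite(h(lo)) || !is.finite(h(hi)) || h(lo) * h(hi) > 0)
    stop("bar_estimate: no overlap between forward and reverse work distributions")
  dG <- stats::uniroot(h, c(lo, hi), tol = 1e-10)$root
  # Bennett asymptotic variance from the Fermi weights at the solution; when
  # the weights all collapse to 0 or 1 the distributions do not overlap and
  # the solution carries no information
  ff <- 1 / (1 + exp(M + (wf - dG) / kT))
  fr <- 1 / (1 + exp(-M + (wr + dG) / kT))
  if (mean(ff) < 1e-10 || mean(fr) < 1e-10 ||
      mean(1 - ff) < 1e-10 || mean(1 - fr) < 1e-10)
    stop("bar_estimate: no overlap between forward and reverse work distributions")
  var_beta <- (mean(ff^2) / mean(ff)^2 - 1) / nf +
              (mean(fr^2) / mean(fr)^2 - 1) / nr
  list(dG = dG, sd = kT * sqrt(max(var_beta, 0)))
}

#' Thermodynamic-integration estimate from mean dH/dlambda values
#'
#' Trapezoidal quadrature of the mean gradient over the lambda schedule; the
#' SD propagates per-lambda standard errors through the trapezoid weights.
#'
#' @param lambdas ordered lambda values (must start at 0 and end at 1)
#' @param dhdl_mean mean dH/dlambda at each lambda, kcal/mol
#' @param dhdl_sem standard error of each mean (0 if omitted)
#' @return list with `dG` and `sd`, kcal/mol
#' @export
ti_estimate <- function(lambdas, dhdl_mean, dhdl_sem = NULL) {
  lambdas <- as.numeric(lambdas)
  n <- length(lambdas)
  if (n < 2L) stop("ti_estimate: need at least two lambda points")
  if (any(diff(lambdas) <= 0)) stop("ti_estimate: lambdas must be strictly increasing")
  if (abs(lambdas[1]) > 1e-12 || abs(lambdas[n] - 1) > 1e-12)
    stop("ti_estimate: lambda schedule must start at 0 and end at 1")
  if (length(dhdl_mean) != n) stop("ti_estimate: missing lambda point in dhdl_mean")
  if (anyNA(dhdl_mean)) stop("ti_estimate: missing lambda point (NA in dhdl_mean)")
  if (is.null(dhdl_sem)) dhdl_sem <- rep(0, n)
  stopifnot(length(dhdl_sem) == n)
  h <- diff(lambdas)
  wts <- c(h / 2, 0) + c(0, h / 2)  # trapezoid coefficient per node
  list(dG = sum(wts * dhdl_mean), sd = sqrt(sum((wts * dhdl_sem)^2)))
}

#' Boresch restraint specification
#'
#' One distance, two angles and three dihedrals restrained harmonically
#' between ligand and receptor anchor atoms. Force constants follow the MD
#' convention: kJ/mol/nm^2 for the distance, kJ/mol/rad^2 for angles and
#' dihedrals (converted internally to kcal).
#'
#' @param r0 reference anchor distance, nm (> 0)
#' @param theta_a,theta_b reference angles, rad, in (0, pi)
#' @param k six force constants in order (distance, angle A, angle B,
#'   dihedral A, dihedral B, dihedral C), kJ/mol/unit^2
#' @param temperature temperature, K
#' @param v0 standard-state volume per molecule, nm^3
#' @export
boresch_spec <- function(r0, theta_a, theta_b, k,
                         temperature = DEFAULT_TEMPERATURE,
                         v0 = STANDARD_VOLUME_NM3) {
  stopifnot(r0 > 0, length(k) == 6, all(k > 0), v0 > 0)
  if (theta_a <= 0 || theta_a >= pi || theta_b <= 0 || theta_b >= pi)
    stop("boresch_spec: reference angles must lie strictly inside (0, pi)")
  structure(list(r0 = r0, theta_a = theta_a, theta_b = theta_b,
                 k = as.numeric(k), temperature = temperature, v0 = v0),
            class = "boresch_spec")
}

#' Analytic standard-state term for Boresch restraints
#'
#' Closed-form free energy of the ligand-side leg: releasing the six
#' harmonic restraints on a noninteracting ligand into the standard-state
#' volume, in the stiff-spring (Gaussian) limit:
#'
#'   dG = -kT ln[ 8 pi^2 V0 / (r0^2 sin(thA) sin(thB))
#'                * sqrt(k_r k_thA k_thB k_phiA k_phiB k_phiC) / (2 pi kT)^3 ]
#'
#' The value is negative for stiff restraints (releasing confinement is
#' favourable); its negative is the cost of imposing the restraints.
#'
#' @param spec a [boresch_spec()]
#' @return dG_restraint in kcal/mol
#' @export
boresch_analytic <- function(spec) {
  stopifnot(inherits(spec, "boresch_spec"))
  kT <- kT_kcal(spec$temperature)
  k <- kj_to_kcal(spec$k)
  arg <- 8 * pi^2 * spec$v0 / (spec$r0^2 * sin(spec$theta_a) * sin(spec$theta_b)) *
    sqrt(prod(k)) / (2 * pi * kT)^3
  -kT * log(arg)
}

#' One alchemical leg of an ABFE calculation
#'
#' @param label one of "restraint", "coulomb", "vdw"
#' @param lambdas lambda schedule: ordered in [0, 1], starting 0, ending 1
#' @param dG leg free energy, kcal/mol
#' @param sd its standard deviation
#' @export
alchemical_leg <- function(label, lambdas, dG, sd = 0) {
  lambdas <- as.numeric(lambdas)
  if (length(lambdas) < 2L || abs(lambdas[1]) > 1e-12 ||
      abs(lambdas[length(lambdas)] - 1) > 1e-12 || any(diff(lambdas) <= 0))
    stop("alchemical_leg: schedule must be strictly increasing from 0 to 1")
  stopifnot(sd >= 0)
  structure(list(label = label, lambdas = lambdas, dG = dG, sd = sd),
            class = "alchemical_leg")
}

#' The canonical ABFE lambda schedules
#'
#' Named preset: Boresch-restraint switching through 13 unevenly spaced
#' points concentrated near 0, coulomb annihilation on even 0.1 spacings and
#' van der Waals annihilation on even 0.05 spacings.
#'
#' @return named list of lambda schedules
#' @export
abfe_lambda_presets <- function() {
  list(
    restraint = c(0, 0.01, 0.025, 0.05, 0.075, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.8, 1.0),
    coulomb = seq(0, 1, by = 0.1),
    vdw = seq(0, 1, by = 0.05)
  )
}

#' Assemble an absolute binding free energy from its legs
#'
#' Double-decoupling sign table (all dG in kcal/mol):
#'
#'   + complex legs:  restrain ligand in complex, then annihilate its coulomb
#'                    and vdw interactions (bound, interacting -> bound,
#'                    restrained dummy)
#'   - ligand legs:   annihilate coulomb and vdw of the free ligand in
#'                    solution (subtracted: traversed in reverse)
#'   + boresch_dG:    analytic release of the restrained dummy into the
#'                    standard-state volume ([boresch_analytic()], negative)
#'
#' The sum is dG_unbind(standard state); the affinity is reported as that
#' positive magnitude, with dG_bind = -affinity. SD is the root-sum-square
#' of leg SDs.
#'
#' @param complex_legs list of [alchemical_leg()]s: restraint, coulomb, vdw
#' @param ligand_legs list of [alchemical_leg()]s: coulomb, vdw
#' @param boresch_dG analytic ligand-side restraint term, kcal/mol
#' @return list with `affinity`, `dG_bind`, `sd`
#' @export
assemble_abfe <- function(complex_legs, ligand_legs, boresch_dG) {
  need_c <- c("restraint", "coulomb", "vdw")
  need_l <- c("coulomb", "vdw")
  have_c <- vapply(complex_legs, `[[`, "", "label")
  have_l <- vapply(ligand_legs, `[[`, "", "label")
  missing <- c(paste0("complex:", setdiff(need_c, have_c)),
               paste0("ligand:", setdiff(need_l, have_l)))
  missing <- missing[!grepl(":$", missing)]
  if (length(missing))
    stop("assemble_abfe: missing leg(s): ", paste(missing, collapse = ", "))
  dG_unbind <- sum(vapply(complex_legs, `[[`, 0, "dG")) -
    sum(vapply(ligand_legs, `[[`, 0, "dG")) + boresch_dG
  sd <- sqrt(sum(vapply(c(complex_legs, ligand_legs), `[[`, 0, "sd")^2))
  list(affinity = dG_unbind, dG_bind = -dG_unbind, sd = sd)
}

#' Signed free-energy edge of a thermodynamic cycle
#'
#' @param label edge label
#' @param from,to state labels the edge connects
#' @param dG free-energy change from -> to, kcal/mol
#' @param sd standard deviation (>= 0)
#' @param orientation +1 to traverse from -> to within the cycle, -1 to
#'   traverse against the edge
#' @export
free_energy_edge <- function(label, from, to, dG, sd = 0, orientation = 1L) {
  stopifnot(sd >= 0, orientation %in% c(-1L, 1L))
  structure(list(label = label, from = from, to = to, dG = dG, sd = sd,
                 orientation = as.integer(orientation)),
            class = "free_energy_edge")
}

#' Closed thermodynamic cycle of free-energy edges
#'
#' Edges must be given in loop order: the effective head of each edge (its
#' `to` for orientation +1, `from` for -1) must equal the effective tail of
#' the next, and the loop must close back on the first state with every
#' state entered and left exactly once.
#'
#' @param edges list of [free_energy_edge()]s
#' @export
thermodynamic_cycle <- function(edges) {
  stopifnot(length(edges) >= 2L, all(vapply(edges, inherits, NA, "free_energy_edge")))
  tails <- vapply(edges, function(e) if (e$orientation == 1L) e$from else e$to, "")
  heads <- vapply(edges, function(e) if (e$orientation == 1L) e$to else e$from, "")
  nxt <- c(tails[-1], tails[1])
  bad <- which(heads != nxt)
  if (length(bad))
    stop("thermodynamic_cycle: open loop; edge '", edges[[bad[1]]]$label,
         "' ends at '", heads[bad[1]], "' but the next edge starts at '",
         nxt[bad[1]], "'")
  if (anyDuplicated(tails))
    stop("thermodynamic_cycle: state visited more than once: ",
         tails[duplicated(tails)][1])
  structure(list(edges = edges), class = "thermodynamic_cycle")
}

#' Cycle-closure residual with propagated error
#'
#' The residual is the oriented sum of edge free energies around the loop;
#' for a thermodynamically consistent cycle it is zero within error. The
#' propagated SD is the root-sum-square of edge SDs.
#'
#' @param cycle a [thermodynamic_cycle()]
#' @return list with `residual` and `sd`, kcal/mol
#' @export
cycle_closure <- function(cycle) {
  stopifnot(inherits(cycle, "thermodynamic_cycle"))
  residual <- sum(vapply(cycle$edges, function(e) e$orientation * e$dG, 0))
  sd <- sqrt(sum(vapply(cycle$edges, `[[`, 0, "sd")^2))
  list(residual = residual, sd = sd)
}

#' Protonation edge of a cycle from a pKa estimate
#'
#' dG_protonation at a given pH is RT ln(10) (pH - pKa): protonation is
#' favourable (negative) when the pKa exceeds the pH. The SD scales the pKa
#' SD by RT ln 10.
#'
#' @param pka pKa estimate
#' @param pH pH at which the edge is evaluated
#' @param sd standard deviation of the pKa estimate
#' @param temperature temperature, K
#' @param from,to,label edge metadata (deprotonated state -> protonated state)
#' @param orientation edge orientation within a cycle
#' @return a [free_energy_edge()]
#' @export
protonation_edge_from_pka <- function(pka, pH, sd = 0,
                                      temperature = DEFAULT_TEMPERATURE,
                                      from = "deprotonated", to = "protonated",
                                      label = "protonation", orientation = 1L) {
  r <- rt_ln10(temperature)
  free_energy_edge(label, from, to, dG = r * (pH - pka), sd = r * sd,
                   orientation = orientation)
}
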