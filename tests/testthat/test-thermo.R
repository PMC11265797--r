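test_that("BAR matches the Crooks-Gaussian closed form", {
  # mirrored distributions: dG = 0
  set.seed(1)
  w <- rnorm(2000, 1, 0.8)
  sym <- work_samples(forward = w, reverse = w, temperature = 310)
  est0 <- bar_estimate(sym)
  expect_lt(abs(est0$dG), 3 * est0$sd + 1e-3)

  # Gaussian forward work N(mu, sigma) with beta-consistent reverse:
  # dG = mu - beta sigma^2 / 2
  kT <- kT_kcal(310)  # 0.6160 kcal/mol
  for (case in list(c(2, 1, 11), c(-1.5, 0.5, 12), c(7, 2, 13))) {
    mu <- case[1]; sig <- case[2]
    truth <- mu - sig^2 / (2 * kT)
    set.seed(case[3])
    ws <- work_samples(forward = rnorm(4000, mu, sig),
                       reverse = rnorm(4000, -truth + sig^2 / (2 * kT), sig),
                       temperature = 310)
    est <- bar_estimate(ws)
    expect_lt(abs(est$dG - truth), 3 * est$sd)
  }

  # sigma -> 0: dG = mu exactly
  exact <- bar_estimate(work_samples(rep(2.5, 10), rep(-2.5, 10)))
  expect_equal(exact$dG, 2.5, tolerance = 1e-9)

  # one-sided input falls back to exponential averaging with a warning
  expect_warning(one <- bar_estimate(work_samples(forward = rep(1.2, 50))),
                 "exponential")
  expect_equal(one$dG, 1.2, tolerance = 1e-9)

  # degenerate non-overlapping distributions abort
  expect_error(
    bar_estimate(work_samples(forward = rep(1e6, 5), reverse = rep(1e6, 5))),
    "overlap")
})

test_that("TI quadrature matches constants, lines and a dense-grid oracle", {
  lam <- seq(0, 1, 0.1)
  expect_equal(ti_estimate(lam, rep(3.3, 11))$dG, 3.3)
  expect_equal(ti_estimate(lam, lam)$dG, 0.5, tolerance = 1e-12)

  # cubic integrand: compare the coarse schedule against a dense trapezoid
  f <- function(l) 4 * l^3 - 2 * l + 1
  coarse <- ti_estimate(seq(0, 1, 0.05), f(seq(0, 1, 0.05)))$dG
  dense_l <- seq(0, 1, length.out = 20001)
  dense <- sum(diff(dense_l) * (f(dense_l[-1]) + f(dense_l[-20001])) / 2)
  expect_equal(coarse, dense, tolerance = 5e-3)

  # SD propagation through trapezoid weights
  sem <- rep(0.1, 11)
  wts <- c(0.05, rep(0.1, 9), 0.05)
  expect_equal(ti_estimate(lam, lam, sem)$sd, sqrt(sum((wts * sem)^2)))

  expect_error(ti_estimate(c(0, 0.5), c(1, 1)), "start at 0 and end at 1")
  expect_error(ti_estimate(lam, c(lam[-1], NA)), "missing lambda")
})

test_that("Boresch analytic term matches the numerical configurational integral", {
  kT <- kT_kcal(310)
  for (case in list(list(r0 = 0.5, th = c(1.4, 1.4), k = rep(4184, 6)),
                    list(r0 = 0.3, th = c(1.0, 2.0), k = c(8368, 4184, 2092,
                                                           4184, 6276, 3000)))) {
    spec <- boresch_spec(case$r0, case$th[1], case$th[2], case$k, 310)
    ana <- boresch_analytic(spec)
    kk <- kj_to_kcal(case$k)
    zr <- stats::integrate(function(r) r^2 * exp(-kk[1] * (r - case$r0)^2 / (2 * kT)),
                           0, Inf, rel.tol = 1e-10)$value
    za <- stats::integrate(function(th) sin(th) *
                             exp(-kk[2] * (th - case$th[1])^2 / (2 * kT)),
                           0, pi, rel.tol = 1e-10)$value
    zb <- stats::integrate(function(th) sin(th) *
                             exp(-kk[3] * (th - case$th[2])^2 / (2 * kT)),
                           0, pi, rel.tol = 1e-10)$value
    zd <- vapply(4:6, function(i)
      stats::integrate(function(x) exp(-kk[i] * x^2 / (2 * kT)),
                       -pi, pi, rel.tol = 1e-10)$value, 0)
    z <- zr * za * zb * prod(zd)
    numeric_dg <- -kT * log(8 * pi^2 * STANDARD_VOLUME_NM3 / z)
    expect_lt(abs(ana - numeric_dg), 0.02)
  }

  # scaling law: doubling all six force constants shifts dG by -3 kT ln 2
  s1 <- boresch_spec(0.5, 1.4, 1.4, rep(4184, 6), 310)
  s2 <- boresch_spec(0.5, 1.4, 1.4, rep(8368, 6), 310)
  expect_equal(boresch_analytic(s2) - boresch_analytic(s1),
               -3 * kT * log(2), tolerance = 1e-10)

  expect_error(boresch_spec(0.5, 0, 1.4, rep(4184, 6)), "inside")

  # regression pin after oracle validation
  expect_equal(boresch_analytic(s1), -14.14083, tolerance = 1e-4)
})

test_that("ABFE assembly recovers planted totals with RSS errors", {
  zero <- assemble_abfe(
    list(alchemical_leg("restraint", c(0, 1), 0),
         alchemical_leg("coulomb", c(0, 1), 0),
         alchemical_leg("vdw", c(0, 1), 0)),
    list(alchemical_leg("coulomb", c(0, 1), 0),
         alchemical_leg("vdw", c(0, 1), 0)),
    boresch_dG = 0)
  expect_equal(zero$affinity, 0)

  # SD rule: legs (0.2, 0.2, 0.1) -> 0.3
  sds <- assemble_abfe(
    list(alchemical_leg("restraint", c(0, 1), 1, 0.2),
         alchemical_leg("coulomb", c(0, 1), 1, 0.2),
         alchemical_leg("vdw", c(0, 1), 1, 0.1)),
    list(alchemical_leg("coulomb", c(0, 1), 1),
         alchemical_leg("vdw", c(0, 1), 1)),
    boresch_dG = 0)
  expect_equal(sds$sd, 0.3)

  # planted affinity 7.0 recovered from BAR-estimated synthetic legs
  sched <- abfe_lambda_presets()
  bor <- boresch_analytic(boresch_spec(0.5, 1.4, 1.4, rep(4184, 6), 310))
  lig_true <- c(coulomb = 45.2, vdw = 12.3)
  cpx_total <- 7 - bor + sum(lig_true)
  cpx_true <- c(restraint = 1.5, coulomb = 49.2,
                vdw = cpx_total - 1.5 - 49.2)
  mk <- function(lbl, truth, lam, seed) {
    e <- bar_estimate(make_alchemical_samples(truth, 0.5, 400, seed = seed))
    alchemical_leg(lbl, lam, e$dG, e$sd)
  }
  res <- assemble_abfe(
    list(mk("restraint", cpx_true[1], sched$restraint, 101),
         mk("coulomb", cpx_true[2], sched$coulomb, 102),
         mk("vdw", cpx_true[3], sched$vdw, 103)),
    list(mk("coulomb", lig_true[1], sched$coulomb, 104),
         mk("vdw", lig_true[2], sched$vdw, 105)),
    boresch_dG = bor)
  expect_lt(abs(res$affinity - 7.0), 3 * res$sd)
  expect_equal(res$dG_bind, -res$affinity)

  expect_error(assemble_abfe(
    list(alchemical_leg("coulomb", c(0, 1), 0),
         alchemical_leg("vdw", c(0, 1), 0)),
    list(alchemical_leg("coulomb", c(0, 1), 0),
         alchemical_leg("vdw", c(0, 1), 0)), 0),
    "missing leg")

  # leg-order invariance
  legs_c <- list(mk("vdw", cpx_true[3], sched$vdw, 103),
                 mk("restraint", cpx_true[1], sched$restraint, 101),
                 mk("coulomb", cpx_true[2], sched$coulomb, 102))
  res2 <- assemble_abfe(legs_c,
                        list(mk("vdw", lig_true[2], sched$vdw, 105),
                             mk("coulomb", lig_true[1], sched$coulomb, 104)), bor)
  expect_equal(res2$affinity, res$affinity)
})

test_that("BAR and TI agree on dense-lambda Gaussian synthetic legs", {
  # decompose dG = 4 kcal/mol across 20 even lambda intervals; each interval
  # has Gaussian work, so TI's integrand is linear within intervals
  lam <- seq(0, 1, 0.05)
  truths <- diff(lam) * 4
  bar_total <- 0; var_total <- 0
  for (i in seq_along(truths)) {
    e <- bar_estimate(make_alchemical_samples(truths[i], 0.15, 500, seed = 200 + i))
    bar_total <- bar_total + e$dG
    var_total <- var_total + e$sd^2
  }
  ti <- ti_estimate(lam, rep(4, 21))  # exact integrand for the planted line
  expect_lt(abs(bar_total - ti$dG), 3 * sqrt(var_total))
})

test_that("cycle closure validates loops and propagates errors", {
  e1 <- free_energy_edge("a", "S1", "S2", 1.2, 0.3)
  e2 <- free_energy_edge("b", "S2", "S3", -0.7, 0.4)
  e3 <- free_energy_edge("c", "S3", "S4", 2.0, 0.2)
  e4 <- free_energy_edge("d", "S4", "S1", -2.5, 0.1)
  cyc <- thermodynamic_cycle(list(e1, e2, e3, e4))
  cc <- cycle_closure(cyc)
  expect_equal(cc$residual, 0)
  expect_equal(cc$sd, sqrt(0.30), tolerance = 1e-12)  # 0.5477

  # reversing every orientation flips the residual sign, SD unchanged
  e2b <- free_energy_edge("b", "S2", "S3", -0.6, 0.4)  # open by 0.1
  cyc_open <- thermodynamic_cycle(list(e1, e2b, e3, e4))
  cc_open <- cycle_closure(cyc_open)
  flip <- lapply(rev(list(e1, e2b, e3, e4)), function(e) {
    e$orientation <- -e$orientation; e
  })
  cc_flip <- cycle_closure(thermodynamic_cycle(flip))
  expect_equal(cc_flip$residual, -cc_open$residual)
  expect_equal(cc_flip$sd, cc_open$sd)

  expect_error(thermodynamic_cycle(list(e1, e3)), "open loop")
})

test_that("protonation edges convert pKa to free energy at a given pH", {
  ed0 <- protonation_edge_from_pka(7, 7)
  expect_equal(ed0$dG, 0)
  ed <- protonation_edge_from_pka(8, 7, sd = 0.2, temperature = 310)
  expect_equal(ed$dG, -1.4186, tolerance = 1e-4)
  expect_equal(ed$sd, 0.2838, tolerance = 1e-3)
})

test_that("titration-derived and ABFE edges close a consistent cycle", {
  # ground truth: binding raises the residue pKa by 0.6 units; affinities are
  # planted consistently so the true cycle closes exactly. Each edge is then
  # *estimated* from synthetic data and the measured residual must vanish
  # within 2x the propagated SD.
  pka_apo_true <- 6.2; pka_holo_true <- 6.8; aff_deprot_true <- 8.0
  aff_prot_true <- aff_deprot_true + rt_ln10(310) * (pka_holo_true - pka_apo_true)

  fit_pka <- function(truth, seed) {
    reps <- vapply(1:3, function(r) {
      s <- make_titration_data(truth, pH_values = 2:9, n_frames = 4e4,
                               correlation_time = 5, seed = seed + r)
      fit_titration(deprotonated_fractions(s))$pKa
    }, 0)
    replicate_stats(reps)
  }
  apo <- fit_pka(pka_apo_true, 300)
  holo <- fit_pka(pka_holo_true, 400)

  est_aff <- function(truth, seed) {
    e <- bar_estimate(make_alchemical_samples(truth, 0.4, 600, seed = seed))
    list(mean = e$dG, sd = e$sd)
  }
  bd <- est_aff(aff_deprot_true, 500)
  bp <- est_aff(aff_prot_true, 600)

  cyc <- thermodynamic_cycle(list(
    protonation_edge_from_pka(apo$mean, 7, apo$sd,
                              from = "apo_deprot", to = "apo_prot",
                              label = "protonation (apo)"),
    free_energy_edge("binding (prot)", "apo_prot", "holo_prot", -bp$mean, bp$sd),
    protonation_edge_from_pka(holo$mean, 7, holo$sd,
                              from = "holo_deprot", to = "holo_prot",
                              label = "protonation (holo)", orientation = -1L),
    free_energy_edge("binding (deprot)", "apo_deprot", "holo_deprot",
                     -bd$mean, bd$sd, orientation = -1L)))
  cc <- cycle_closure(cyc)
  expect_lt(abs(cc$residual), 2 * cc$sd)
})
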