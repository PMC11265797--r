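test_that("langevin sampler satisfies equipartition on a harmonic well", {
  k_kcal <- kj_to_kcal(100)  # 100 kJ/mol/nm^2 at 310 K
  surf <- harmonic_surface(0, k_kcal)
  p <- langevin_params(timestep = 5e-4, n_steps = 1e6, stride = 50, seed = 42)
  s <- langevin_sample(surf, params = p, start = 0)
  truth <- kT_kcal(310) / k_kcal
  expect_lt(abs(var(s$values[, 1]) - truth) / truth, 0.03)
})

test_that("langevin sampler is seed-deterministic and descends as T -> 0", {
  surf <- double_well_surface(3, 0.5)
  p <- langevin_params(timestep = 1e-3, n_steps = 5000, stride = 5, seed = 9)
  a <- langevin_sample(surf, params = p, start = 0.2)
  b <- langevin_sample(surf, params = p, start = 0.2)
  expect_identical(a$values, b$values)

  cold <- langevin_params(timestep = 1e-3, temperature = 1e-6,
                          n_steps = 20000, stride = 20, seed = 1)
  s <- langevin_sample(surf, params = cold, start = 0.2)
  expect_equal(unname(s$values[n_samples(s), 1]), 0.5, tolerance = 1e-3)
})

test_that("divergent steps abort with a stability error", {
  stiff <- harmonic_surface(0, kj_to_kcal(4e6))
  p <- langevin_params(timestep = 0.01, n_steps = 1000, stride = 1, seed = 1)
  expect_error(langevin_sample(stiff, params = p, start = 0.5),
               "smaller timestep")
})

test_that("unbiased and biased sampling match their Boltzmann densities", {
  # chi-square comparison of histograms against exp(-beta(U+bias)); this is
  # the premise WHAM relies on
  check_boltzmann <- function(surface, bias, seed) {
    p <- langevin_params(timestep = 5e-4, n_steps = 4e5, stride = 40, seed = seed)
    s <- langevin_sample(surface, bias = bias, params = p,
                         start = if (is.null(bias)) 0 else bias$center)
    edges <- seq(-1.2, 1.2, length.out = 31)
    counts <- table(cut(s$values[, 1], edges))
    mid <- (edges[-1] + edges[-31]) / 2
    u <- surface_energy(surface, matrix(mid, ncol = 1))
    if (!is.null(bias)) u <- u + bias_energy(bias, matrix(mid, ncol = 1))
    prob <- exp(-u / kT_kcal(310)); prob <- prob / sum(prob)
    keep <- prob * sum(counts) > 10
    chi2 <- sum((counts[keep] - sum(counts) * prob[keep])^2 /
                  (sum(counts) * prob[keep]))
    # generous threshold: samples are autocorrelated, so chi2 is inflated
    # relative to its nominal df by roughly the correlation time
    chi2 / sum(keep)
  }
  dw <- double_well_surface(2, 0.5)
  expect_lt(check_boltzmann(dw, NULL, 21), 12)
  expect_lt(check_boltzmann(dw, bias_spec(0.2, 500), 22), 12)
})

test_that("umbrella campaigns deliver the pooled two-tier window design", {
  surf <- double_well_surface(2, 0.5)
  p <- langevin_params(timestep = 5e-4, n_steps = 2000, stride = 10, seed = 3)
  wins <- make_umbrella_campaign(surf, seq(-0.6, 0.6, length.out = 24),
                                 list(1000, 4000), list(p, p), n_replicates = 3)
  expect_length(wins, 144L)  # 24 centres x 2 tiers x 3 replicates
  expect_setequal(unique(vapply(wins, `[[`, "", "tier")), c("tier1", "tier2"))
  expect_setequal(unique(vapply(wins, `[[`, "", "replicate")),
                  c("rep1", "rep2", "rep3"))

  # zero force constant = unbiased run
  w0 <- make_umbrella_campaign(surf, 0, list(0), p)
  expect_equal(w0[[1]]$bias$k, 0)

  # adjacent windows overlap on the double-well defaults
  tier1 <- Filter(function(w) w$tier == "tier1" && w$replicate == "rep1", wins)
  p2 <- langevin_params(timestep = 5e-4, n_steps = 2e4, stride = 10, seed = 3)
  wins2 <- make_umbrella_campaign(surf, seq(-0.6, 0.6, length.out = 12),
                                  list(2000), p2)
  edges <- seq(-0.8, 0.8, length.out = 81)
  hists <- lapply(wins2, function(w) table(cut(w$samples$values[, 1], edges)))
  overlaps <- vapply(seq_len(length(hists) - 1), function(i)
    sum(pmin(hists[[i]], hists[[i + 1]])), 0)
  expect_true(all(overlaps > 0))
})

test_that("titration traces have the prescribed stationary fractions", {
  s <- make_titration_data(3.5, pH_values = 3.5, n_frames = 50000,
                           correlation_time = 1, seed = 4)
  # at pH = pKa the deprotonated fraction is 1/2 within binomial 3 sigma
  fr <- deprotonated_fractions(s)$fraction
  expect_lt(abs(fr - 0.5), 3 * sqrt(0.25 / 50000) + 0.01)

  s2 <- make_titration_data(2, pH_values = c(1, 3), n_frames = 40000,
                            correlation_time = 1, seed = 5)
  fr2 <- deprotonated_fractions(s2)$fraction
  truth <- 1 / (1 + 10^(2 - c(1, 3)))
  expect_true(all(abs(fr2 - truth) < 3 * sqrt(truth * (1 - truth) / 40000) + 0.005))

  a <- make_titration_data(3, n_frames = 1000, seed = 11)
  b <- make_titration_data(3, n_frames = 1000, seed = 11)
  expect_identical(a$traces, b$traces)
  expect_warning(make_titration_data(3, n_frames = 10, correlation_time = 50),
                 "unstable")
})

test_that("path ensembles plant the separation direction they report", {
  base <- matrix(0, 5, 8); base[, 1] <- 1:5
  pe <- make_path_ensembles(2, 5, base, c(0, 0, 2, 0, 0, 0, 0, 0),
                            separation_scale = 0.7, noise = 0, seed = 2)
  expect_equal(pe$truth, c(0, 0, 1, 0, 0, 0, 0, 0))  # normalized
  d <- pe$frames[, 1, ] - pe$frames[, 2, ]
  # all inter-replicate frame differences parallel to the planted direction
  expect_true(all(abs(d[, -3]) < 1e-12))
  expect_true(all(abs(abs(d[, 3]) - 1.4) < 1e-12))
  expect_error(make_path_ensembles(2, 5, base, rep(0, 8)), "zero")
})

test_that("alchemical work samples satisfy the Crooks-Gaussian construction", {
  exact <- make_alchemical_samples(3.0, 0, 10, seed = 1)
  expect_true(all(exact$forward == 3.0))
  expect_true(all(exact$reverse == -3.0))

  ws <- make_alchemical_samples(2.0, 1.0, 4000, seed = 7)
  est <- bar_estimate(ws)
  expect_lt(abs(est$dG - 2.0), 3 * est$sd)
  expect_error(make_alchemical_samples(1, 0.1, 1), "n >= 2")
  a <- make_alchemical_samples(1, 0.5, 50, seed = 3)
  b <- make_alchemical_samples(1, 0.5, 50, seed = 3)
  expect_identical(a$forward, b$forward)
})
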