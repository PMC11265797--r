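# shared small campaign for several tests (built once; fixed seeds)
dw_surface <- double_well_surface(3, 0.45)
dw_grid <- pmf_grid_spec(c(-0.7, 0.7), 72)
dw_windows <- make_umbrella_campaign(
  dw_surface, seq(-0.65, 0.65, length.out = 24), list(4e3),
  langevin_params(timestep = 4e-5, n_steps = 2e5, stride = 5, seed = 1))

test_that("single unbiased window reduces WHAM to a histogram estimate", {
  surf <- harmonic_surface(0, kj_to_kcal(400))
  p <- langevin_params(timestep = 5e-4, n_steps = 2e5, stride = 10, seed = 2)
  s <- langevin_sample(surf, params = p, start = 0)
  w <- umbrella_window(s, bias_spec(0, 0))
  grid <- pmf_grid_spec(c(-0.5, 0.5), 40)
  pmf <- wham(list(w), grid)
  # reference: -kT ln(histogram), zeroed
  idx <- findInterval(s$values[, 1], grid_edges(grid)[[1]], rightmost.closed = TRUE)
  h <- tabulate(idx[idx >= 1 & idx <= 40], 40)
  ref <- -kT_kcal(310) * log(h / sum(h))
  ref[!is.finite(ref)] <- NA
  ref <- ref - min(ref, na.rm = TRUE)
  expect_equal(pmf$values[pmf$defined], ref[!is.na(ref)], tolerance = 1e-6)
})

test_that("WHAM recovers a harmonic surface from pooled windows", {
  k <- kj_to_kcal(400)
  surf <- harmonic_surface(0, k)
  p <- langevin_params(timestep = 2e-4, n_steps = 4e4, stride = 5, seed = 5)
  wins <- make_umbrella_campaign(surf, seq(-0.5, 0.5, length.out = 12),
                                 list(2000), p)
  grid <- pmf_grid_spec(c(-0.55, 0.55), 60)
  pmf <- wham(wins, grid)
  expect_lt(pmf_rmsd(pmf, exact_pmf(surf, grid)), 0.1)
})

test_that("WHAM recovers the planted double-well barrier", {
  pmf <- wham(dw_windows, dw_grid)
  truth <- exact_pmf(dw_surface, dw_grid)
  expect_lt(pmf_rmsd(pmf, truth), 0.2)
  rep <- basin_barrier_report(pmf, min_prominence = 0.5)
  expect_equal(nrow(rep$minima), 2L)
  expect_equal(rep$barriers$barrier_from_left[1], 3, tolerance = 0.2)
})

test_that("WHAM free energies are window-order and tier-duplication invariant", {
  sub <- dw_windows[seq(1, 24, by = 2)]
  grid <- pmf_grid_spec(c(-0.7, 0.7), 36)
  a <- wham(sub, grid)
  b <- wham(rev(sub), grid)
  expect_equal(a$values, b$values, tolerance = 1e-6)

  # splitting one window's samples across two tier labels changes nothing
  w <- sub[[5]]
  n <- n_samples(w$samples)
  h1 <- umbrella_window(cv_series(w$samples$labels, w$samples$times[1:(n %/% 2)],
                                  w$samples$values[1:(n %/% 2), , drop = FALSE]),
                        w$bias, w$replicate, "tierA")
  h2 <- umbrella_window(cv_series(w$samples$labels, w$samples$times[(n %/% 2 + 1):n],
                                  w$samples$values[(n %/% 2 + 1):n, , drop = FALSE]),
                        w$bias, w$replicate, "tierB")
  split <- wham(c(sub[-5], list(h1, h2)), grid)
  expect_equal(split$values, a$values, tolerance = 1e-6)
})

test_that("non-overlapping window histograms raise a disconnection warning", {
  surf <- harmonic_surface(0, 0.01)
  p <- langevin_params(timestep = 2e-4, n_steps = 5000, stride = 5, seed = 7)
  far <- make_umbrella_campaign(surf, c(-8, 8), list(2e3), p)
  expect_warning(wham(far, pmf_grid_spec(c(-9, 9), 120)), "disconnected")
})

test_that("Boltzmann projection matches separable and Gaussian closed forms", {
  # separable surface: F2 = f(x) + g(y)  ->  F1(x) = f(x) + const
  grid2 <- pmf_grid_spec(list(c(-1, 1), c(-1, 1)), 40)
  cx <- grid_centers(grid2)[[1]]; cy <- grid_centers(grid2)[[2]]
  fx <- 2 * cx^2; gy <- cos(3 * cy)
  f2 <- outer(fx, gy, `+`)
  p2 <- pmf_grid(grid2, f2, temperature = 310)
  p1 <- project_pmf(p2, 1)
  expect_lt(pmf_rmsd(p1, pmf_grid(pmf_grid_spec(c(-1, 1), 40), fx)), 1e-9)

  # F2 = (x^2 + y^2)/2 at kT = 1  ->  F1 = x^2/2 + const
  kT1 <- 1 / KB_KCAL  # temperature with kT = 1 kcal/mol
  gridg <- pmf_grid_spec(list(c(-3, 3), c(-8, 8)), c(40, 400))
  gx <- grid_centers(gridg)[[1]]; gyy <- grid_centers(gridg)[[2]]
  pg <- pmf_grid(gridg, outer(gx^2 / 2, gyy^2 / 2, `+`), temperature = kT1)
  pg1 <- project_pmf(pg, 1)
  expect_lt(pmf_rmsd(pg1, pmf_grid(pmf_grid_spec(c(-3, 3), 40), gx^2 / 2)), 1e-4)

  # a surface defined on a single row reproduces that row
  vals <- matrix(NA_real_, 40, 40); vals[17, ] <- gy - min(gy)
  single <- pmf_grid(grid2, vals, !is.na(vals))
  ps <- project_pmf(single, 2)
  expect_equal(ps$values, gy - min(gy), tolerance = 1e-9)
})

test_that("alignment shifts are least-squares optimal and region-zeroing works", {
  grid <- pmf_grid_spec(c(0, 1), 20)
  x <- grid_centers(grid)[[1]]
  base <- pmf_grid(grid, (x - 0.4)^2 * 5)
  self <- align_pmf(base, base)
  expect_equal(attr(self, "shift"), 0, tolerance = 1e-12)

  shifted <- base; shifted$values <- shifted$values + 5
  back <- align_pmf(shifted, base)
  expect_equal(attr(back, "shift"), -5)
  expect_equal(back$values, base$values)

  # partial overlap: shift equals the mean difference over co-defined bins
  part <- base
  part$defined[1:8] <- FALSE; part$values[1:8] <- NA
  part$values <- part$values + 2.3
  al <- align_pmf(part, base)
  expect_equal(attr(al, "shift"), -2.3, tolerance = 1e-12)

  reg <- align_pmf(base, region = c(0.3, 0.5))
  sel <- x >= 0.3 & x <= 0.5
  expect_equal(mean(reg$values[sel]), 0, tolerance = 1e-12)

  disjoint <- base
  disjoint$defined[] <- FALSE; disjoint$defined[1:3] <- TRUE
  other <- base
  other$defined[] <- FALSE; other$defined[10:12] <- TRUE
  expect_error(align_pmf(disjoint, other), "co-defined")
})

test_that("convergence band brackets the full curve and is narrow when stationary", {
  cb <- convergence_band(dw_windows, dw_grid)
  full <- cb$curves$full$values
  ok <- !is.na(full) & !is.na(cb$lower)
  expect_true(all(cb$lower[ok] <= full[ok] + 1e-9))
  expect_true(all(cb$upper[ok] >= full[ok] - 1e-9))
  expect_lt(cb$median_width, 0.15)

  # windows built by tiling one block five times have identical first-40%,
  # last-40% and full empirical distributions, so the band collapses to the
  # alignment residual (~0)
  sym <- lapply(dw_windows[1:6], function(w) {
    n5 <- 5 * (n_samples(w$samples) %/% 5)
    block <- w$samples$values[1:(n5 %/% 5), , drop = FALSE]
    tiled <- do.call(rbind, rep(list(block), 5))
    umbrella_window(cv_series(w$samples$labels, seq_len(nrow(tiled)), tiled),
                    w$bias)
  })
  cbs <- suppressWarnings(convergence_band(sym, pmf_grid_spec(c(-0.7, 0), 24)))
  expect_lt(max(cbs$upper - cbs$lower, na.rm = TRUE), 1e-6)
})

test_that("basin/barrier readout matches constructed profiles", {
  grid <- pmf_grid_spec(c(-2, 2), 81)
  x <- grid_centers(grid)[[1]]
  # constructed profile: minima at (-1, 0) and (+1, 3), saddle 6 at x = 0
  prof <- ifelse(x < 0, 6 * (x + 1)^2, 3 + 3 * (x - 1)^2)
  pmf <- pmf_grid(grid, prof)
  rep <- basin_barrier_report(pmf)
  expect_equal(rep$minima$position, c(-1, 1), tolerance = 0.06)
  expect_equal(rep$barriers$delta_g, 3, tolerance = 0.05)
  expect_equal(rep$barriers$barrier_from_left, 6, tolerance = 0.05)

  # single well: one minimum, no barriers
  single <- pmf_grid(grid, x^2)
  rs <- basin_barrier_report(single)
  expect_equal(nrow(rs$minima), 1L)
  expect_equal(nrow(rs$barriers), 0L)

  # symmetric double well: equal basin energies
  symm <- pmf_grid(grid, 3 * ((x / 1)^2 - 1)^2)
  rsym <- basin_barrier_report(symm)
  expect_equal(rsym$minima$value[1], rsym$minima$value[2], tolerance = 1e-9)

  # monotone profile: empty report with a note
  mono <- basin_barrier_report(pmf_grid(grid, 2 * x))
  expect_equal(nrow(mono$minima), 0L)
  expect_match(attr(mono, "note"), "monotone")
})

test_that("projection then alignment commutes with constant offsets", {
  grid2 <- pmf_grid_spec(list(c(-1, 1), c(-1, 1)), 30)
  cx <- grid_centers(grid2)[[1]]; cy <- grid_centers(grid2)[[2]]
  f2 <- outer(2 * cx^2, 0.5 * cy^2, `+`)
  a <- project_pmf(pmf_grid(grid2, f2), 1)
  b <- project_pmf(pmf_grid(grid2, f2 + 4), 1)
  al <- align_pmf(b, a)
  expect_equal(al$values, a$values, tolerance = 1e-9)
})
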