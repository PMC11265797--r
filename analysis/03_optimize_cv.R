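#!/usr/bin/env Rscript
# Orthogonal-CV derivation: build replicate path ensembles with a planted
# inter-replicate separation direction, fit a PCA basis to the pooled frames,
# and maximize the entropy-like separation metric over combinations of
# PCs 2-16 by differential evolution. The optimized direction ("PC 2") is
# the second axis of the 2D CV space; projections are written as COLVAR.
#
# Findings: with three replicate paths of 24 windows in a 20-dimensional
# coordinate space, default noise, the optimizer recovers the planted
# orthogonal direction with cosine > 0.99; the 2D projection places the main
# transition along PC 1 and the replicate spread along the optimized PC 2.

library(feltools)
dir.create("results", showWarnings = FALSE)

D <- 20; n_windows <- 24
base <- matrix(0, n_windows, D)
base[, 1] <- seq(-3, 3, length.out = n_windows)       # main transition
base[, 4] <- 0.4 * sin(seq(0, pi, length.out = n_windows))  # path curvature
planted <- c(0, 0, 1, rep(0, D - 3))                  # orthogonal separation

paths <- make_path_ensembles(3, n_windows, base, planted,
                             separation_scale = 0.5, noise = 0.05, seed = 11)
frames <- path_frames(paths)
basis <- pca_fit(frames)
pc2 <- optimize_pc2(paths, basis, seed = 2024)
v <- basis$components[, pc2$pcs, drop = FALSE] %*% pc2$weights
cosine <- abs(sum(v * paths$truth))

write_cv_json(basis, pc2, "results/optimized_cv.json")
proj <- project_2d(frames, basis, pc2)
write_colvar(proj, "results/path_projections.colvar")

summary_tab <- data.frame(
  pc1_variance_fraction = basis$fractions[1],
  achieved_metric = pc2$metric,
  planted_direction_cosine = cosine)
write.csv(summary_tab, "results/cv_optimization.csv", row.names = FALSE)

cat("PC 1 explains", round(100 * basis$fractions[1], 1), "% of variance\n")
cat("entropy-like metric at optimum:", round(pc2$metric, 4), "\n")
cat("cosine between optimized PC 2 and planted direction:",
    round(cosine, 4), "\n")
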