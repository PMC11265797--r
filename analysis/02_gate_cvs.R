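#!/usr/bin/env Rscript
# Gate collective variables: evaluate the built-in tip/base inter-bundle
# centre-of-mass distance CVs on a synthetic two-bundle trajectory, write the
# series in COLVAR format, and measure salt-bridge contact fractions on
# frames with planted contact statistics.
#
# Findings: on a toy trajectory whose bundles breathe by +-0.25 nm around a
# 2.8 nm separation, the tip-CV tracks the planted distance exactly; planted
# contact occupancies of 72% and 22% are recovered exactly by
# contact_fraction at the 0.4 nm salt-bridge cutoff.

library(feltools)
set.seed(20260901)
dir.create("results", showWarnings = FALSE)

cvs <- builtin_gate_cvs()
ranges_tab <- do.call(rbind, lapply(names(cvs), function(nm) {
  def <- cvs[[nm]]
  do.call(rbind, lapply(list(def$group_a, def$group_b), function(g)
    data.frame(cv = nm, group = g$label,
               interval = apply(g$ranges, 1, paste, collapse = "-"),
               n_residues = length(group_residues(g)))))
}))
write.csv(ranges_tab, "results/gate_cv_definitions.csv", row.names = FALSE)

# synthetic "trajectory": two 4-atom bundles, planted COM separations
separations <- 2.8 + 0.25 * sin(seq(0, 4 * pi, length.out = 60))
toy_def <- gate_cv_definition("tip",
  residue_group("N-bundle", c(1, 4)), residue_group("C-bundle", c(101, 104)))
frames <- lapply(separations, function(d) {
  posA <- matrix(rnorm(12, 0, 0.1), 4, 3)
  posA <- sweep(posA, 2, colMeans(posA))
  posB <- matrix(rnorm(12, 0, 0.1), 4, 3)
  posB <- sweep(posB, 2, colMeans(posB))
  posB[, 1] <- posB[, 1] + d
  synthetic_frame(rbind(posA, posB), resid = c(1:4, 101:104))
})
series <- gate_cv_series(frames, toy_def, times = seq_along(frames) * 100)
write_colvar(series, "results/tip_cv_toy.colvar")
stopifnot(max(abs(series$values[, 1] - separations)) < 1e-9)

# planted contact statistics: an extracellular salt bridge formed in 72% of
# frames and an intracellular one in 22%
mk_pair <- function(d) synthetic_frame(rbind(c(0, 0, 0), c(d, 0, 0)),
                                       resid = c(1, 2))
spec <- contact_spec(residue_group("K", c(1, 1), atom_filter = "*"),
                     residue_group("D", c(2, 2), atom_filter = "*"),
                     cutoff = 0.4)
extracellular <- lapply(c(rep(0.32, 72), rep(0.75, 28)), mk_pair)
intracellular <- lapply(c(rep(0.35, 22), rep(0.9, 78)), mk_pair)
contacts <- data.frame(
  contact = c("extracellular K-D (planted 0.72)", "intracellular D-K (planted 0.22)"),
  fraction = c(contact_fraction(extracellular, spec),
               contact_fraction(intracellular, spec)))
write.csv(contacts, "results/contact_fractions.csv", row.names = FALSE)

cat("tip-CV on toy trajectory: planted separations recovered to <1e-9 nm\n")
print(contacts, row.names = FALSE)
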