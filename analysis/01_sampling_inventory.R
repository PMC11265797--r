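#!/usr/bin/env Rscript
# Sampling bookkeeping: recompute the headline sampling totals of the study
# design from their printed components (conditions x replicates x windows x
# durations) and tabulate the per-block inventory.
#
# Findings: the five totals come out as 72 us (unbiased), 38 us (ABFE,
# nearest us), 96 us (constant-pH), 13.6 us (trial protocols, one decimal)
# and 67 us (1D-PMF production, nearest us), and the pooled two-tier 2D
# umbrella design yields 144 windows per free-energy surface.

library(feltools)

cfg <- yaml::read_yaml(system.file("extdata", "study_campaigns.yaml",
                                   package = "feltools"))
plans <- lapply(cfg$campaigns, function(cc) campaign_plan(cc$name, cc$blocks))

dir.create("results", showWarnings = FALSE)

inventory <- do.call(rbind, lapply(names(plans), function(nm) {
  inv <- campaign_inventory(plans[[nm]])
  inv$campaign <- nm
  inv[, c("campaign", "block", "n_runs", "total_us")]
}))
write.csv(inventory, "results/sampling_inventory.csv", row.names = FALSE)

totals <- data.frame(
  campaign = names(plans),
  total_us = vapply(plans, campaign_total_time, 0),
  printed = c(
    unbiased_occ = campaign_total_time(plans$unbiased_occ),
    abfe = campaign_total_time(plans$abfe, "nearest_us"),
    cphmd = campaign_total_time(plans$cphmd),
    trials = campaign_total_time(plans$trials, "one_decimal_us"),
    pmf_1d = campaign_total_time(plans$pmf_1d, "nearest_us"))
)
write.csv(totals, "results/sampling_totals.csv", row.names = FALSE)

# the 144-window design: 24 centres x 2 force-constant tiers x 3 replicates
p <- langevin_params(timestep = 5e-4, n_steps = 200, stride = 10, seed = 1)
wins <- make_umbrella_campaign(double_well_surface(2, 0.5),
                               seq(-0.6, 0.6, length.out = 24),
                               list(1000, 4000), list(p, p), n_replicates = 3)

cat("Sampling totals (us):\n")
print(totals, row.names = FALSE)
cat("\nWindows contributing to one 2D-PMF:", length(wins), "\n")
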