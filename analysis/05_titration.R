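#!/usr/bin/env Rscript
# Constant-pH titration analysis on synthetic protonation traces: full-data
# titration-curve fits in triplicate (mean +- SD), 10 ns-chunk pKa estimates
# with histograms, a two-regime mixture to exercise the bimodality screen,
# and conversion of the apo->holo pKa shift into a protonation free-energy
# change at 310 K.
#
# Findings (fixed seeds): triplicate fits recover planted pKa values of 6.2
# (apo) and 6.8 (holo) to ~0.01 with replicate SDs of ~0.01-0.03; the
# planted 0.6-unit shift converts to ~0.85 kcal/mol; chunk histograms are
# unimodal for stationary traces and flagged bimodal for the concatenated
# two-regime trace.

library(feltools)
dir.create("results", showWarnings = FALSE)

pH <- 0:7
conditions <- list(apo = 6.2, holo = 6.8)  # planted E56-like pKa values

fits <- lapply(names(conditions), function(cond) {
  reps <- lapply(1:3, function(r)
    make_titration_data(conditions[[cond]], pH_values = pH, n_frames = 1e5,
                        correlation_time = 10, frame_period_ns = 0.01,
                        residue = "E56", seed = 1000 * match(cond, names(conditions)) + r))
  pkas <- vapply(reps, function(s)
    fit_titration(deprotonated_fractions(s))$pKa, 0)
  st <- replicate_stats(pkas)
  data.frame(condition = cond, pka_true = conditions[[cond]],
             pka_mean = st$mean, pka_sd = st$sd)
})
fits <- do.call(rbind, fits)
write.csv(fits, "results/pka_triplicates.csv", row.names = FALSE)

shift <- fits$pka_mean[fits$condition == "holo"] -
  fits$pka_mean[fits$condition == "apo"]
ddg <- pka_shift_to_ddg(shift, 310)
write.csv(data.frame(pka_shift = shift, ddg_kcal = ddg),
          "results/pka_shift_ddg.csv", row.names = FALSE)

# chunked estimates: stationary trace vs concatenated two-regime trace
stat <- make_titration_data(6.2, pH_values = pH, n_frames = 4e4,
                            correlation_time = 5, frame_period_ns = 0.01,
                            seed = 7)
ck <- chunked_pka(stat, chunk_ns = 10)
mixA <- make_titration_data(5.5, pH_values = pH, n_frames = 2e4,
                            correlation_time = 5, seed = 8)
mixB <- make_titration_data(7.0, pH_values = pH, n_frames = 2e4,
                            correlation_time = 5, seed = 9)
mix <- protonation_series("E56", pH, Map(c, mixA$traces, mixB$traces), 0.01)
ckm <- chunked_pka(mix, chunk_ns = 10)

write.csv(rbind(
  data.frame(series = "stationary", pka = ck$estimates),
  data.frame(series = "two_regime", pka = ckm$estimates)),
  "results/pka_chunks.csv", row.names = FALSE)

cat("Triplicate titration fits:\n")
print(fits, row.names = FALSE)
cat(sprintf("\npKa shift %.3f units -> ddG = %.3f kcal/mol at 310 K\n",
            shift, ddg))
cat(sprintf("chunked estimates: stationary mean %.2f (bimodal: %s); ",
            mean(ck$estimates), ck$bimodality$bimodal))
cat(sprintf("two-regime flagged bimodal: %s (cluster means %.2f / %.2f)\n",
            ckm$bimodality$bimodal, ckm$bimodality$means[1],
            ckm$bimodality$means[2]))
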