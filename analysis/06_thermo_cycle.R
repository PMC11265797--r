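#!/usr/bin/env Rscript
# Absolute binding free energies and the protonation/binding thermodynamic
# cycle. Synthetic alchemical legs are generated at the canonical lambda
# schedules with planted totals anchored to the study's reported affinities
# (OF 8.0, IF 7.0, IF with the substrate-coordinating glutamate protonated
# 2.9 kcal/mol), estimated per leg by BAR, and assembled with the analytic
# Boresch standard-state term. A four-state cycle of substrate binding and
# glutamate protonation is closed from titration-derived and ABFE-derived
# edges with root-sum-square error propagation.
#
# Findings (fixed seeds): BAR assembly recovers each planted affinity within
# its propagated SD (~0.04 kcal/mol at these sample sizes); the cycle
# residual is statistically zero (|residual| < propagated SD).

library(feltools)
dir.create("results", showWarnings = FALSE)

sched <- abfe_lambda_presets()
bspec <- boresch_spec(r0 = 0.5, theta_a = 1.4, theta_b = 1.4,
                      k = rep(4184, 6), temperature = 310)
bor <- boresch_analytic(bspec)

# planted affinities (kcal/mol) by protein state
planted <- c(OF = 8.0, IF = 7.0, IF_E622_prot = 2.9)
lig_true <- c(coulomb = 45.2, vdw = 12.3)

estimate_affinity <- function(aff_true, seed0) {
  cpx_total <- unname(aff_true) - bor + sum(lig_true)
  cpx_true <- c(restraint = 1.5, coulomb = lig_true[["coulomb"]] + 4.0,
                vdw = cpx_total - 1.5 - lig_true[["coulomb"]] - 4.0)
  mk <- function(lbl, truth, lam, seed) {
    e <- bar_estimate(make_alchemical_samples(truth, 0.5, 400, seed = seed))
    alchemical_leg(lbl, lam, e$dG, e$sd)
  }
  assemble_abfe(
    list(mk("restraint", cpx_true[["restraint"]], sched$restraint, seed0 + 1),
         mk("coulomb", cpx_true[["coulomb"]], sched$coulomb, seed0 + 2),
         mk("vdw", cpx_true[["vdw"]], sched$vdw, seed0 + 3)),
    list(mk("coulomb", lig_true[["coulomb"]], sched$coulomb, seed0 + 4),
         mk("vdw", lig_true[["vdw"]], sched$vdw, seed0 + 5)),
    boresch_dG = bor)
}

aff <- do.call(rbind, lapply(seq_along(planted), function(i) {
  est <- estimate_affinity(planted[i], 100 * i)
  data.frame(state = names(planted)[i], planted = planted[i],
             affinity = est$affinity, sd = est$sd)
}))
write.csv(aff, "results/abfe_affinities.csv", row.names = FALSE)

## thermodynamic cycle: E56-like protonation x Ala-Phe-like binding at pH 7.
## Ground truth is built self-consistently: binding raises the pKa by 0.6
## units, so the protonated-state affinity exceeds the deprotonated one by
## RT ln10 x 0.6.
pka_apo <- 6.2; pka_holo <- 6.8; aff_deprot <- 8.0
aff_prot <- aff_deprot + rt_ln10(310) * (pka_holo - pka_apo)

fit_pka <- function(truth, seed) replicate_stats(vapply(1:3, function(r)
  fit_titration(deprotonated_fractions(make_titration_data(
    truth, pH_values = 2:9, n_frames = 4e4, correlation_time = 5,
    seed = seed + r)))$pKa, 0))
apo <- fit_pka(pka_apo, 300)
holo <- fit_pka(pka_holo, 400)
bind_deprot <- estimate_affinity(aff_deprot, 500)
bind_prot <- estimate_affinity(aff_prot, 600)

cyc <- thermodynamic_cycle(list(
  protonation_edge_from_pka(apo$mean, 7, apo$sd, from = "apo_deprot",
                            to = "apo_prot", label = "protonation (apo)"),
  free_energy_edge("binding (protonated)", "apo_prot", "holo_prot",
                   -bind_prot$affinity, bind_prot$sd),
  protonation_edge_from_pka(holo$mean, 7, holo$sd, from = "holo_deprot",
                            to = "holo_prot", label = "protonation (holo)",
                            orientation = -1L),
  free_energy_edge("binding (deprotonated)", "apo_deprot", "holo_deprot",
                   -bind_deprot$affinity, bind_deprot$sd, orientation = -1L)))
cc <- cycle_closure(cyc)

edges_tab <- do.call(rbind, lapply(cyc$edges, function(e)
  data.frame(edge = e$label, from = e$from, to = e$to,
             dG = e$dG, sd = e$sd, orientation = e$orientation)))
write.csv(edges_tab, "results/cycle_edges.csv", row.names = FALSE)
write.csv(data.frame(residual = cc$residual, sd = cc$sd),
          "results/cycle_closure.csv", row.names = FALSE)

cat("Boresch analytic term:", round(bor, 3), "kcal/mol\n")
cat("Assembled affinities (planted -> estimated +- SD):\n")
print(aff, row.names = FALSE)
cat(sprintf("\nCycle closure: residual = %.4f +- %.4f kcal/mol\n",
            cc$residual, cc$sd))
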