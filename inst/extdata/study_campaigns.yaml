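# Sampling bookkeeping for the study design: every block records the printed
# components (conditions x replicates x windows x per-window durations in ns)
# from which the headline sampling totals are recomputed.
campaigns:
  unbiased_occ:
    name: unbiased MD of the OCC state
    blocks:
      - label: OCC unbiased conditions
        n_conditions: 24
        n_replicates: 3
        n_windows: 1
        durations_ns: [1000]
  abfe:
    name: absolute binding free energies
    blocks:
      - label: ABFE production
        n_conditions: 4
        n_replicates: 7
        n_windows: 44
        durations_ns: [31.2]
  cphmd:
    name: constant-pH MD
    blocks:
      - label: pH replica windows
        n_conditions: 4
        n_replicates: 3
        n_windows: 8
        durations_ns: [1000]
  trials:
    name: enhanced-sampling trial protocols
    blocks:
      - label: metadynamics walkers from OF
        n_conditions: 1
        n_replicates: 8
        n_windows: 1
        durations_ns: [108]
      - label: metadynamics walkers from OCC
        n_conditions: 1
        n_replicates: 8
        n_windows: 1
        durations_ns: [213]
      - label: steered MD (both directions, pull + switch-off + unbiased)
        n_conditions: 2
        n_replicates: 1
        n_windows: 1
        durations_ns: [200, 2, 48]
      - label: trial 1D-REUS forward
        n_conditions: 1
        n_replicates: 1
        n_windows: 48
        durations_ns: [92]
      - label: trial 1D-REUS reverse
        n_conditions: 1
        n_replicates: 1
        n_windows: 48
        durations_ns: [127]
  pmf_1d:
    name: 1D-PMF production sampling
    blocks:
      - label: OCC-OF standard protonation
        n_conditions: 1
        n_replicates: 1
        n_windows: 24
        durations_ns: [266, 244, 244]
      - label: OCC-OF H87 & D342 protonated
        n_conditions: 1
        n_replicates: 1
        n_windows: 24
        durations_ns: [327, 244, 244]
      - label: OCC-IF standard protonation
        n_conditions: 1
        n_replicates: 1
        n_windows: 24
        durations_ns: [242, 248, 246]
      - label: OCC-IF E53 protonated
        n_conditions: 1
        n_replicates: 1
        n_windows: 24
        durations_ns: [158, 155, 154]
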