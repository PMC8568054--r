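# Study-scale preset for the synthetic generators.
#
# Anchored values (reported family/stress-survey figures): the 335-protein
# family total with 214 RING-H2, 3 RING-HCb and 1 RING-G; per-stress
# responsive totals cold 128, salt 134, drought 121, MeJA 82; the all-four
# intersection 53; single-stress exclusives salt 26, cold 5, drought 0,
# MeJA 0; and the qPCR salt-12h fold 3.28.
#
# Free choices (not published, fixed once here): the HCa/C2/v split of the
# remaining 117 proteins; every Venn cell not listed above (chosen to
# satisfy all anchored marginals exactly); the qPCR folds at 6 h and 24 h.
proteome:
  counts:
    RING-H2: 214
    RING-HCa: 104
    RING-HCb: 3
    RING-C2: 7
    RING-v: 6
    RING-G: 1
  n_decoys: 500
  near_miss_fraction: 0.2
  background: clean
  flank_range: [30, 80]
expression:
  n_genes: 214            # RING-H2 genes enter the stress screen
  stresses: [cold, salt, drought, MeJA]
  noise_sd: 0.1
  cells:                  # exact-membership Venn cells; union = 175
    cold: 5
    salt: 26
    drought: 0
    MeJA: 0
    cold&salt: 3
    cold&drought: 17
    cold&MeJA: 10
    salt&drought: 2
    salt&MeJA: 10
    drought&MeJA: 9
    cold&salt&drought: 40
    cold&salt&MeJA: 0
    cold&drought&MeJA: 0
    salt&drought&MeJA: 0
    cold&salt&drought&MeJA: 53
qpcr:
  target_gene: TEA031033
  housekeeping: GAPDH
  calibrator: control
  n_bio: 3
  n_tech: 3
  folds:
    control: 1
    NaCl-6h: 1.62
    NaCl-12h: 3.28
    NaCl-24h: 2.40
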